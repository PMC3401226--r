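# trapbias

Simulation study of how **seasonal variation in detectability** combined
with **unequal sample sizes** (lost pitfall traps) biases count-data
abundance estimates — and which analyses survive it.

Many trapping studies standardize each replicate's catch to a fixed effort
(e.g. individuals per 100 trap-days) and compare treatments with a Gaussian
model on log-transformed totals. For a spring-active species, most of the
catch arrives early in the season; if traps are lost unevenly in time, the
surviving trap-days are no longer comparable and the standardized analysis
can severely mis-estimate treatment effects. `trapbias` quantifies this by
simulation: it generates clumped seasonal trap catches with known treatment
effects, removes observations under controlled trap-loss scenarios, fits
five competing analyses, and measures each one's log-scale bias.

## The model

Counts follow a Poisson log-normal process on a 3 treatments × 5
replicates × 4 traps × 5 twenty-day-interval design (300 trapping events):

```
y_trji ~ Poisson( m · k_t · p_i · exp(a_tr + b_trj) )
a_tr  ~ N(0, σ_s²)    one persistent effect per replicate plot
b_trj ~ N(0, σ_t²)    one persistent effect per trap
```

with baseline per-trap season catch `m = 1.47`, treatment multipliers
`k = (1, 2, 4)`, seasonal activity profile
`p = (0.25, 0.49, 0.13, 0.09, 0.04)` and field-estimated random-effect SDs
`σ_s = 0.14`, `σ_t = 0.30` (parameters of *Pterostichus oblongopunctatus*
pitfall catches). Trap loss removes exactly 15/30/45/60 of the 80 points in
targeted design cells (high-abundance × high-activity, or low-abundance ×
low-activity), i.e. 5–20% of the design.

The five analyses: (M1) traditional standardization to 100 trap-days with
Gaussian `ln(y+1) ~ Treatment`; Gaussian models with seasonality as a known
offset (M2) or a free factor (M3); and negative binomial GLMs with
seasonality as a known offset (M4) or a free factor (M5) — all of M2–M5
with `offset(ln(surviving traps))`. Bias is
`mean over simulations of Σ_t [log(estimate_t) − log(truth_t)]`.

## Worked example

```r
library(trapbias)
params <- parameter_sets()[["field"]]

d    <- simulate_dataset(params, seed = 1)               # 300 trapping events
lost <- apply_loss(d, loss_scenario("high_catch", 0.75), seed = 2)  # 20% loss
fits <- fit_all_models(lost)

print(fits$M1_trad_normal)
#> <model_fit M1_trad_normal> converged: TRUE
#>   predicted catch per 100 trap-days: T1 1.182, T2 1.404, T3 4.227
print(fits$M4_offset_negbin)
#> <model_fit M4_offset_negbin> converged: TRUE
#>   predicted catch per 100 trap-days: T1 1.252, T2 2.893, T3 7.077
#>   NB size (theta): 39.18

treatment_truth(params)   # true catch per 100 trap-days: 1.55, 3.11, 6.21
model_bias(fits$M1_trad_normal, params)$summed   # -1.451
model_bias(fits$M4_offset_negbin, params)$summed # -0.155
```

With a fifth of the design lost during peak activity in the high-abundance
treatments, the traditional analysis (M1) sees Treatment 2 as barely above
Treatment 1 (1.40 vs 1.18 — the true effect is 2×) while the negative
binomial offset model (M4) stays close to the truth. Averaged over 100
simulations (`run_grid()`), M1's summed bias reaches −1.0 log units at 20%
high-catch loss and +0.3 at 20% low-catch loss, while M4/M5 hold a small
negative bias (≈ −0.04) that does not move with the loss level.

## Analysis workflow

Numbered drivers under `analysis/` reproduce the full study and write
tables under `results/`:

1. `01_expected_catches.R` — expected catch per design cell, design arithmetic
2. `02_simulate_example.R` — example dataset; Monte Carlo check of the
   generator against closed-form means
3. `03_trap_loss_bias.R` — the main experiment: 5 models × 3 loss
   scenarios × 5 loss levels × 100 simulations (field parameters)
4. `04_parameter_sweep.R` — the six perturbed parameter sets
5. `05_figures.R` — box-whisker and mean-bias figures from the summaries

Each takes an optional master seed argument (default 1). The methods
vignette (`vignettes/trap-loss-bias-methods.Rmd`) documents the model,
conventions and limitations.

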