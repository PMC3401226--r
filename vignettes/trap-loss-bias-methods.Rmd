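---
title: "Methods: simulating seasonal trap catches and evaluating estimator bias under trap loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating seasonal trap catches and evaluating estimator bias under trap loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapbias)
```

## The problem

Pitfall-trap counts of a spring-active ground beetle such as *Pterostichus
oblongopunctatus* measure activity-density: a compound of abundance and
movement activity, and hence of detectability. Detectability is strongly
seasonal — most individuals are caught early in the season — so when traps
are lost unevenly across the season (vandalism, flooding, animals), the
surviving effort is no longer comparable between treatments. The common
remedy in the trapping literature, standardizing each replicate's total
catch to 100 trap-days, ignores *when* the surviving trap-days occurred and
can be badly misled.

`trapbias` is a simulation framework for quantifying that bias. It
generates realistic clumped seasonal catch data with known treatment
effects, deletes observations under controlled trap-loss scenarios, fits
five competing analyses, and measures how far each analysis lands from the
known truth.

## The data-generating model

The design is 3 treatments x 5 replicate plots x 4 traps, observed over
five 20-day intervals (a 100-day season; 300 trapping events). Treatment
$t$ scales a baseline per-trap season catch $m$ (default 1.47
individuals/trap) by multipliers $k_t \in \{1, 2, 4\}$. A seasonal profile
$p_i$ (default $0.25, 0.49, 0.13, 0.09, 0.04$) divides the season's catch
among the intervals. The count of trap $j$ in replicate $r$ of treatment
$t$ during interval $i$ is

$$y_{trji} \sim \mathrm{Poisson}\!\left(m\, k_t\, p_i\,
  e^{a_{tr} + b_{trj}}\right),\qquad
  a_{tr} \sim N(0, \sigma_s^2),\quad b_{trj} \sim N(0, \sigma_t^2),$$

a Poisson log-normal process whose log-normal random effects make the
counts clumped (over-dispersed). The default SDs, $\sigma_s = 0.14$ (site)
and $\sigma_t = 0.30$ (trap), come from a quasi-Poisson mixed-model fit to
field catches; that field fit is taken as given here, not refit. Seven
named parameter sets (`parameter_sets()`) perturb the baseline: mean
divided or multiplied by 5, and each *variance* ($\sigma^2$, not
$\sigma$) divided or multiplied by 5 in the four combinations.

Three modelling choices in the generator deserve note:

* **Random effects are persistent.** One deviate per replicate plot and one
  per trap, held constant across the five intervals: a physical site or
  trap has one lasting peculiarity (shading, soil moisture, placement).
  Redrawing per interval would be an alternative reading; we chose
  persistence as the physically sensible one.
* **No log-normal mean correction.** The linear predictor carries no
  $-\sigma^2/2$ term, matching the standard GLMM formulation. The realized
  process mean therefore exceeds the design-table expectation by
  $e^{(\sigma_s^2 + \sigma_t^2)/2}$, about 5.6% at the default SDs.
  `expected_cell_catch()` deliberately reports the pre-random-effect
  expectation (the design-table numbers); `treatment_truth()` defaults to
  the realized process mean, because bias should be measured against what
  the process actually generates (see *Bias* below). Both quantities are
  asserted in the test suite.
* **No interval-level random effect.** Seasonality enters only through the
  fixed profile; interval-to-interval noise beyond Poisson variation is a
  feature of real years that this generator does not emulate.

### What the generator does and does not emulate

It reproduces clumping, a realistic seasonal catch decline, persistent
site/trap heterogeneity, and exact design balance. It does **not** emulate
weather- or diel-driven detectability, spatial autocorrelation among traps,
between-year profile variation, or species interactions. Conclusions from
these simulations are therefore about the statistical machinery under a
known, well-behaved seasonal process — a best case for every model
compared. A method that fails here will not do better on real data.

## Trap loss

Two targeted scenarios bracket the bias directions: `high_catch` loses
traps in treatments 2–3 during intervals 1–2 (high abundance, high
activity) and `low_catch` in treatments 1–2 during intervals 4–5. Either
pool holds 80 of the 300 points, and the within-pool severities 18.75%,
37.5%, 56.25% and 75% remove exactly 15, 30, 45 and 60 points — 5–20% of
the whole design. Removal is exact sampling without replacement of a fixed
number of points, not per-point Bernoulli coin-flips, because the exact
totals are part of the experimental definition. A `random` scenario removes
the same four absolute totals, drawn uniformly from all 300 points — the
natural no-structure control against the two targeted scenarios. Lost observations are flagged rather than
deleted, so writers can emit either representation; every downstream
computation treats flagged rows as absent from both counts and trap-days.

## The five analyses

M1 standardizes each replicate's catch to 100 trap-days and fits Gaussian
`ln(catch + 1) ~ Treatment` on the 15 replicate values. M2–M5 work at the
replicate x interval grain (abundance summed over surviving traps, at most
75 rows), all carrying `offset(ln(surviving traps))`:

| id | distribution | seasonality |
|----|--------------|-------------|
| M1 | Gaussian on ln(y+1) | ignored |
| M2 | Gaussian on ln(y+1) | known, `offset(ln %)` |
| M3 | Gaussian on ln(y+1) | free 5-level factor |
| M4 | negative binomial | known, `offset(ln %)` |
| M5 | negative binomial | free 5-level factor |

The grain choice follows from the model formulas: a per-row
`offset(ln(no. traps))` is only meaningful if rows aggregate traps. Rows in
which all four traps were lost have an undefined offset and are dropped
(the count of dropped rows is recorded); if a treatment loses all its rows
the whole simulation replicate is recorded as failed rather than silently
skipped. The seasonal offset uses percentages as printed (25, 49, …); the
factor-of-100 difference from proportions is absorbed by the intercept and
provably leaves treatment contrasts unchanged (asserted in tests).

The Gaussian fits use ordinary least squares. The negative binomial fits
use the standard alternating scheme — regression coefficients at fixed
dispersion, then maximum-likelihood dispersion (size, $\theta$) at fixed
coefficients, to convergence — as implemented in `MASS::glm.nb`. Two
numerical escapes are handled explicitly: when data are effectively Poisson
the alternation can diverge as $\theta \to \infty$, in which case a bounded
profile-likelihood maximization over $\log\theta$ is used and $\theta$ is
capped at $10^6$ and flagged; genuinely failed fits are returned as
non-converged with diagnostics, never silently dropped.

### A common prediction scale

The five models predict on different scales, so every fit is normalized to
an expected per-replicate season total at full effort before comparison:
the linear predictor is evaluated per interval at 4 traps with the
interval's own offset or factor level, back-transformed per interval
(Gaussian: $e^\mu - 1$, floored at the smallest positive double; negative
binomial: $e^\mu$), summed over the five intervals, and divided by 4 traps.
For a 100-day season this lands every model on M1's catch-per-100-trap-days
scale. How to collapse a 5-level interval factor into one season prediction
is not dictated by the model; this per-interval-back-transform-then-sum
convention was chosen because it makes every model answer the same
question ("expected season catch of a full replicate") and keeps bias
well-defined. The `ln(e^\mu - 1)` back-transformation for the `+1`
Gaussian models is read the same way: back-transform to the abundance
scale, then compare on the log scale.

## Bias

For each fit, per-treatment bias is
$\log(\hat\mu_t) - \log(\mu_t^{\mathrm{true}})$; the headline metric is the
mean over simulations of the sum over the three treatments. The truth
$\mu_t^{\mathrm{true}}$ is the realized process mean
$m\,k_t\,e^{(\sigma_s^2+\sigma_t^2)/2}$ — what an unbiased method should
recover from this generator. Using the nominal $m\,k_t$ instead would
charge every model the 5.6% generator inflation as "bias"; the nominal
convention remains available (`treatment_truth(..., inflated = FALSE)`).
Monte Carlo standard errors accompany every summary, so invariance claims
("negative binomial bias does not change with loss level") are tested
against the run's own uncertainty rather than fixed tolerances.
Non-converged fits are excluded from means and counted; a cell with more
than 10% failures is flagged unreliable. In the test suite "small bias" for
the negative binomial models means within 0.1 log units summed over three
treatments (about 3% per treatment mean) — an order of magnitude below the
smallest treatment effect, $\ln 2 \approx 0.69$.

## Problem sizes and reproducibility

The experiments use 100 simulated datasets per condition, the study's
Monte Carlo size; the unit tests use 40–600 datasets depending on how sharp
the oracle comparison must be (600 to separate the 5.6% mean inflation from
the nominal expectation by more than 3 SEs; 40 for self-calibrating
contrast equivalences). Within a batch, dataset $i$ gets seed
$(\text{master} + 48271\,i) \bmod (2^{31}-1)$, so any single dataset can be
replayed without regenerating the batch, and a master seed fixes the entire
grid bitwise. Loss draws use the same scheme with an independent master
seed per grid cell.

## Known limitations

* The generator's truth is a best case: real seasonal profiles are not
  known exactly, so M2/M4 here receive the exact profile the data were
  generated from. The gap between M4 and M5 therefore understates the
  advantage of *not* needing prior seasonal knowledge.
* The negative binomial is not the generating distribution (Poisson
  log-normal); its good performance here is robustness, not correctness,
  and parallels the common field situation where the mean–variance
  relationship is only approximately known.
* Treatment effects are multiplicative and constant over the season;
  treatment-by-season interactions would defeat M2–M5 as formulated.
* With 100 simulations, comparisons of |bias| between models with similar
  bias (e.g. M4 vs M5) are at the edge of Monte Carlo resolution; the
  reported SEs should be consulted before reading anything into such gaps.
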