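# Independent oracles and small fixture builders shared across test files.

# Brute-force ML for a 2-treatment negative binomial GLM with a fixed offset:
# nested grid refinement over (intercept, treatment-2 effect, log theta),
# maximizing the NB log-likelihood directly. Deliberately independent of
# glm.nb / glm: the only shared ingredient is dnbinom.
nb_grid_oracle <- function(y, is_t2, off,
                           b0_range = c(-5, 5), b1_range = c(-5, 5),
                           lth_range = log(c(1e-2, 1e4)),
                           n_grid = 21L, n_refine = 4L) {
  best <- NULL
  ranges <- list(b0 = b0_range, b1 = b1_range, lth = lth_range)
  for (r in seq_len(n_refine)) {
    g <- expand.grid(
      b0 = seq(ranges$b0[1], ranges$b0[2], length.out = n_grid),
      b1 = seq(ranges$b1[1], ranges$b1[2], length.out = n_grid),
      lth = seq(ranges$lth[1], ranges$lth[2], length.out = n_grid)
    )
    ll <- vapply(seq_len(nrow(g)), function(i) {
      mu <- exp(g$b0[i] + g$b1[i] * is_t2 + off)
      sum(dnbinom(y, size = exp(g$lth[i]), mu = mu, log = TRUE))
    }, numeric(1))
    best <- g[which.max(ll), ]
    step <- vapply(ranges, function(rg) diff(rg) / (n_grid - 1), numeric(1))
    ranges <- list(
      b0 = best$b0 + c(-1, 1) * step[1],
      b1 = best$b1 + c(-1, 1) * step[2],
      lth = best$lth + c(-1, 1) * step[3]
    )
  }
  list(b0 = best$b0, b1 = best$b1, theta = exp(best$lth))
}

# A tiny two-treatment analysis table (1 replicate x 5 intervals each) plus
# the matching design parameters, for the grid-search oracle checks.
tiny_nb_fixture <- function(seed = 42) {
  params <- simulation_params(
    mean_catch_t1 = 4, site_sd = 0, trap_sd = 0,
    treatment_multipliers = c(1, 2), n_treatments = 2L,
    n_replicates = 1L
  )
  set.seed(seed)
  tab <- expand.grid(treatment = 1:2, replicate = 1L, interval = 1:5)
  tab <- tab[order(tab$treatment, tab$interval), ]
  tab$n_traps <- 4L
  tab$seasonal_pct <- unclass(params$profile)[tab$interval] * 100
  lambda <- 4 * tab$treatment * unclass(params$profile)[tab$interval] * tab$n_traps
  tab$abundance <- rnbinom(nrow(tab), size = 2, mu = lambda)
  rownames(tab) <- NULL
  list(table = tab, params = params)
}

# A complete default-design dataset with all counts set by `fill`
# (a function of the row, or a constant), bypassing the simulator.
constant_dataset <- function(fill = 0L, params = simulation_params()) {
  des <- expand.grid(
    interval = seq_len(params$n_intervals),
    trap = seq_len(params$n_traps),
    replicate = seq_len(params$n_replicates),
    treatment = seq_len(params$n_treatments)
  )[, c("treatment", "replicate", "trap", "interval")]
  des <- des[order(des$treatment, des$replicate, des$trap, des$interval), ]
  rownames(des) <- NULL
  des$count <- if (is.function(fill)) fill(des) else rep(as.integer(fill), nrow(des))
  des$trap_days <- params$interval_days
  des$lost <- FALSE
  structure(des, params = params, class = c("trap_dataset", "data.frame"))
}

# Treatment contrasts (T2-T1, T3-T1, ...) of a model fit on the log scale.
fit_contrasts <- function(fit) {
  lp <- fit$treatment_log_predictions
  lp[-1] - lp[1]
}
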