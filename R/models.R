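#' Replicate x interval analysis table
#'
#' Collapses a (possibly loss-manipulated) dataset to the grain at which the
#' offset models are fitted: abundance summed over the surviving traps of
#' each replicate in each interval, together with the number of surviving
#' traps (the effort offset) and the seasonal percentage of the interval (the
#' known-detectability offset, on the percent scale as printed: 25, 49, 13,
#' 9, 4). Cells in which every trap was lost have an undefined `log(n_traps)`
#' offset and are dropped; the number dropped is recorded in the `n_dropped`
#' attribute.
#'
#' @param dataset A `trap_dataset` with losses applied (possibly none).
#' @param profile A [seasonal_profile()]; defaults to the profile of the
#'   dataset's simulation parameters.
#' @return A data frame with columns `treatment`, `replicate`, `interval`,
#'   `abundance`, `n_traps`, `seasonal_pct` (at most 75 rows for the default
#'   design) and attribute `n_dropped`.
#' @export
build_analysis_table <- function(dataset, profile = NULL) {
  stopifnot(inherits(dataset, "trap_dataset"))
  params <- attr(dataset, "params") %||% simulation_params()
  if (is.null(profile)) profile <- params$profile
  if (!inherits(profile, "seasonal_profile")) profile <- seasonal_profile(profile)

  alive <- surviving(dataset)
  agg <- stats::aggregate(
    cbind(abundance = count, n_traps = rep(1L, nrow(alive))) ~
      treatment + replicate + interval,
    data = alive, FUN = sum
  )
  full <- params$n_replicates * params$n_treatments * params$n_intervals
  agg <- agg[order(agg$treatment, agg$replicate, agg$interval), ]
  rownames(agg) <- NULL
  agg$seasonal_pct <- unclass(profile)[agg$interval] * 100

  structure(agg, n_dropped = full - nrow(agg))
}

new_model_fit <- function(model_id, log_pred, converged = TRUE,
                          dispersion = NA_real_, notes = character(),
                          fit = NULL) {
  structure(
    list(
      model_id = model_id,
      treatment_log_predictions = log_pred,
      converged = converged,
      dispersion = dispersion,
      notes = notes,
      fit = fit
    ),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit %s> converged: %s\n", x$model_id, x$converged))
  if (x$converged) {
    pred <- exp(x$treatment_log_predictions)
    cat("  predicted catch per 100 trap-days:",
        paste(sprintf("T%d %.3f", seq_along(pred), pred), collapse = ", "), "\n")
  }
  if (!is.na(x$dispersion)) cat(sprintf("  NB size (theta): %.4g\n", x$dispersion))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Back-transform a Gaussian log(y + 1) fitted mean to the abundance scale,
# flooring at the smallest positive double when exp(mu) - 1 <= 0.
back_transform_plus1 <- function(mu) {
  pred <- exp(mu) - 1
  floored <- pred <= 0
  pred[floored] <- .Machine$double.xmin
  list(pred = pred, floored = any(floored))
}

# Sum per-interval predicted replicate abundances to a season total and
# rescale to catch per 100 trap-days (divide by the 4 traps of a full
# replicate, whose season is exactly 100 days).
season_scale <- function(per_interval_pred, params) {
  sum(per_interval_pred) / params$n_traps
}

#' Model 1: traditional standardization, Gaussian
#'
#' The conventional analysis: replicate-level catches standardized to 100
#' trap-days ([summarize_replicates()]), then
#' `ln(standardized catch + 1) ~ Treatment` with Gaussian errors. Seasonality
#' is ignored entirely. Treatment predictions are back-transformed as
#' `exp(mu) - 1` and reported on the log scale.
#'
#' @param replicates Output of [summarize_replicates()].
#' @param params A [simulation_params()] (for design constants).
#' @return A `model_fit` with `treatment_log_predictions` on the log catch
#'   per 100 trap-days scale.
#' @export
fit_m1 <- function(replicates, params = simulation_params()) {
  stopifnot(all(c("treatment", "standardized_catch") %in% names(replicates)))
  d <- replicates
  d$trt <- factor(d$treatment, levels = seq_len(params$n_treatments))
  if (!all(seq_len(params$n_treatments) %in% d$treatment)) {
    stop("a treatment has no replicates; cannot fit M1")
  }

  fit <- stats::lm(log(standardized_catch + 1) ~ trt, data = d)
  mu <- as.numeric(stats::predict(
    fit,
    newdata = data.frame(trt = factor(seq_len(params$n_treatments),
                                      levels = levels(d$trt)))
  ))
  bt <- back_transform_plus1(mu)
  new_model_fit(
    "M1_trad_normal", log(bt$pred),
    notes = if (bt$floored) "back-transform floored at machine minimum" else character(),
    fit = fit
  )
}

# Shared Gaussian machinery for M2 (known seasonality as offset) and M3
# (seasonality as a free 5-level factor). Both carry the surviving-trap
# offset log(n_traps); rows with n_traps = 0 never reach here.
fit_gaussian_offset <- function(table, params, model_id,
                                seasonality = c("offset", "factor")) {
  seasonality <- match.arg(seasonality)
  d <- table
  d$trt <- factor(d$treatment, levels = seq_len(params$n_treatments))
  if (!all(seq_len(params$n_treatments) %in% d$treatment)) {
    stop("a treatment has no surviving rows; cannot fit ", model_id)
  }

  if (seasonality == "offset") {
    d$off <- log(d$seasonal_pct) + log(d$n_traps)
    fit <- stats::lm(log(abundance + 1) ~ trt + offset(off), data = d)
  } else {
    d$ivl <- factor(d$interval, levels = seq_len(params$n_intervals))
    if (!all(seq_len(params$n_intervals) %in% d$interval)) {
      return(new_model_fit(model_id, rep(NA_real_, params$n_treatments),
                           converged = FALSE,
                           notes = "an interval has no surviving rows"))
    }
    d$off <- log(d$n_traps)
    fit <- stats::lm(log(abundance + 1) ~ trt + ivl + offset(off), data = d)
  }

  # Predict each treatment x interval cell at full effort (4 traps), with the
  # interval's own offset or factor level; back-transform per interval, sum
  # to a replicate season total, rescale to per 100 trap-days.
  newd <- expand.grid(
    trt = factor(seq_len(params$n_treatments)),
    interval = seq_len(params$n_intervals)
  )
  if (seasonality == "offset") {
    newd$off <- log(unclass(params$profile)[newd$interval] * 100) + log(params$n_traps)
  } else {
    newd$ivl <- factor(newd$interval, levels = seq_len(params$n_intervals))
    newd$off <- log(params$n_traps)
  }
  mu <- matrix(stats::predict(fit, newdata = newd),
               nrow = params$n_treatments)
  bt <- back_transform_plus1(mu)
  log_pred <- log(apply(matrix(bt$pred, nrow = params$n_treatments), 1,
                        function(p) season_scale(p, params)))
  new_model_fit(
    model_id, log_pred,
    notes = if (bt$floored) "back-transform floored at machine minimum" else character(),
    fit = fit
  )
}

#' Model 2: known seasonality, Gaussian with offsets
#'
#' `ln(Abundance + 1) ~ Treatment + offset(ln(seasonal %)) +
#' offset(ln(surviving traps))` at the replicate x interval grain. The two
#' offsets enter with coefficient fixed at 1, so doubling an offset variable
#' doubles the implied predicted catch.
#'
#' @param table Output of [build_analysis_table()] (with `seasonal_pct` from
#'   the known activity profile).
#' @param params A [simulation_params()].
#' @return A `model_fit`; predictions are per-interval back-transformed,
#'   summed to the season, and scaled to catch per 100 trap-days.
#' @export
fit_m2 <- function(table, params = simulation_params()) {
  fit_gaussian_offset(table, params, "M2_offset_normal", "offset")
}

#' Model 3: unknown seasonality, Gaussian with interval factor
#'
#' As [fit_m2()] but seasonality enters as a free 5-level fixed factor
#' instead of a known offset: `ln(Abundance + 1) ~ Treatment + Interval +
#' offset(ln(surviving traps))`.
#'
#' @inheritParams fit_m2
#' @return A `model_fit`.
#' @export
fit_m3 <- function(table, params = simulation_params()) {
  fit_gaussian_offset(table, params, "M3_factor_normal", "factor")
}

# Negative binomial GLM wrapper: log link, ML theta via the alternating
# coefficient/theta scheme of MASS::glm.nb (outer iteration capped), with
# near-Poisson fits capped at theta = 1e6 and flagged rather than failed.
# When the alternation itself diverges (theta running to infinity makes its
# convergence test NaN), one more alternation round is done by hand: Poisson
# coefficients, then theta.ml at those means, then a refit at that theta.
fit_nb_glm <- function(formula, data, model_id, params, newd) {
  warns <- character()
  quietly <- function(expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }
  fit <- quietly(MASS::glm.nb(formula, data = data,
                              control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  notes <- character()
  if (inherits(fit, "error")) {
    prof_ll <- function(log_th) {
      th <- exp(log_th)
      f <- tryCatch(
        suppressWarnings(stats::glm(formula, data = data,
                                    family = MASS::negative.binomial(theta = th))),
        error = function(e) NULL
      )
      if (is.null(f)) return(-Inf)
      y <- stats::model.response(stats::model.frame(f))
      sum(stats::dnbinom(y, size = th, mu = stats::fitted(f), log = TRUE))
    }
    opt <- quietly(stats::optimize(prof_ll, c(log(1e-3), log(1e6)), maximum = TRUE))
    if (inherits(opt, "error") || !is.finite(opt$objective)) {
      return(new_model_fit(model_id, rep(NA_real_, params$n_treatments),
                           converged = FALSE,
                           notes = "theta profile likelihood maximization failed"))
    }
    th <- min(exp(opt$maximum), 1e6)
    fit <- quietly(stats::glm(formula, data = data,
                              family = MASS::negative.binomial(theta = th)))
    if (inherits(fit, "error")) {
      return(new_model_fit(model_id, rep(NA_real_, params$n_treatments),
                           converged = FALSE, notes = conditionMessage(fit)))
    }
    fit$theta <- th
    notes <- "theta alternation diverged: profile-likelihood theta"
  }
  theta <- fit$theta
  if (theta > 1e6) {
    theta <- 1e6
    notes <- c(notes, "near-Poisson data: theta capped at 1e6")
  }
  mu <- matrix(stats::predict(fit, newdata = newd, type = "link"),
               nrow = params$n_treatments)
  log_pred <- log(apply(exp(mu), 1, function(p) season_scale(p, params)))
  if (any(!is.finite(log_pred))) {
    return(new_model_fit(model_id, log_pred, converged = FALSE,
                         dispersion = theta, notes = c(notes, warns, "non-finite prediction")))
  }
  new_model_fit(model_id, log_pred, converged = TRUE, dispersion = theta,
                notes = c(notes, warns), fit = fit)
}

#' Model 4: known seasonality, negative binomial with offsets
#'
#' As [fit_m2()] but the abundance is modeled directly as negative binomial
#' with a log link (no `+1` transformation): `Abundance ~ Treatment +
#' offset(ln(seasonal %)) + offset(ln(surviving traps))`, dispersion (size,
#' theta) estimated by maximum likelihood.
#'
#' @inheritParams fit_m2
#' @return A `model_fit` with `dispersion` set to the estimated theta.
#' @export
fit_m4 <- function(table, params = simulation_params()) {
  d <- table
  d$trt <- factor(d$treatment, levels = seq_len(params$n_treatments))
  if (!all(seq_len(params$n_treatments) %in% d$treatment)) {
    stop("a treatment has no surviving rows; cannot fit M4")
  }
  d$off <- log(d$seasonal_pct) + log(d$n_traps)

  newd <- expand.grid(
    trt = factor(seq_len(params$n_treatments)),
    interval = seq_len(params$n_intervals)
  )
  newd$off <- log(unclass(params$profile)[newd$interval] * 100) + log(params$n_traps)

  fit_nb_glm(abundance ~ trt + offset(off), d, "M4_offset_negbin", params, newd)
}

#' Model 5: unknown seasonality, negative binomial with interval factor
#'
#' As [fit_m4()] but seasonality enters as a free 5-level factor:
#' `Abundance ~ Treatment + Interval + offset(ln(surviving traps))`.
#'
#' @inheritParams fit_m2
#' @return A `model_fit` with `dispersion` set to the estimated theta.
#' @export
fit_m5 <- function(table, params = simulation_params()) {
  d <- table
  d$trt <- factor(d$treatment, levels = seq_len(params$n_treatments))
  if (!all(seq_len(params$n_treatments) %in% d$treatment)) {
    stop("a treatment has no surviving rows; cannot fit M5")
  }
  d$ivl <- factor(d$interval, levels = seq_len(params$n_intervals))
  if (!all(seq_len(params$n_intervals) %in% d$interval)) {
    return(new_model_fit("M5_factor_negbin", rep(NA_real_, params$n_treatments),
                         converged = FALSE, notes = "an interval has no surviving rows"))
  }
  d$off <- log(d$n_traps)

  newd <- expand.grid(
    trt = factor(seq_len(params$n_treatments)),
    interval = seq_len(params$n_intervals)
  )
  newd$ivl <- factor(newd$interval, levels = seq_len(params$n_intervals))
  newd$off <- log(params$n_traps)

  fit_nb_glm(abundance ~ trt + ivl + offset(off), d, "M5_factor_negbin", params, newd)
}

#' Fit all five competing analyses to one dataset
#'
#' Convenience wrapper: builds the replicate summary and the replicate x
#' interval table, then fits M1-M5. Errors in any single fit (e.g. a
#' treatment with no surviving rows) are captured as non-converged
#' `model_fit`s so a simulation grid can continue.
#'
#' @param dataset A `trap_dataset` with losses applied (possibly none).
#' @param profile Seasonal profile used for M2/M4 offsets; defaults to the
#'   dataset's generating profile (the "known seasonality" assumption).
#' @return A named list of five `model_fit` objects.
#' @export
fit_all_models <- function(dataset, profile = NULL) {
  params <- attr(dataset, "params") %||% simulation_params()
  tab <- build_analysis_table(dataset, profile)
  safely <- function(id, expr) {
    tryCatch(expr, error = function(e) {
      new_model_fit(id, rep(NA_real_, params$n_treatments),
                    converged = FALSE, notes = conditionMessage(e))
    })
  }
  list(
    M1_trad_normal = safely("M1_trad_normal", fit_m1(summarize_replicates(dataset), params)),
    M2_offset_normal = safely("M2_offset_normal", fit_m2(tab, params)),
    M3_factor_normal = safely("M3_factor_normal", fit_m3(tab, params)),
    M4_offset_negbin = safely("M4_offset_negbin", fit_m4(tab, params)),
    M5_factor_negbin = safely("M5_factor_negbin", fit_m5(tab, params))
  )
}
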