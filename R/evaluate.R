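#' True per-treatment catch on the prediction scale
#'
#' All five models report predictions as catch per 100 trap-days, which for a
#' 100-day season equals the per-trap season total. The generator draws its
#' log-normal random effects without a mean correction, so the true expected
#' catch of the simulated process is the design-table value
#' `mean_catch_t1 * multiplier` inflated by
#' `exp((site_sd^2 + trap_sd^2) / 2)` (about 5.6% at the field SDs). Bias is
#' measured against this realized process mean — the "simulated (i.e. true)
#' abundance" an unbiased method should recover — by default; set
#' `inflated = FALSE` for the nominal pre-random-effect values (1.47, 2.94,
#' 5.88 for the field parameters).
#'
#' @param params A [simulation_params()].
#' @param inflated Include the log-normal mean inflation (default `TRUE`).
#' @return Named numeric vector of true values, one per treatment.
#' @export
treatment_truth <- function(params, inflated = TRUE) {
  stopifnot(inherits(params, "simulation_params"))
  infl <- if (inflated) exp((params$site_sd^2 + params$trap_sd^2) / 2) else 1
  stats::setNames(
    params$mean_catch_t1 * params$treatment_multipliers * infl,
    paste0("T", seq_len(params$n_treatments))
  )
}

#' Log-scale bias of a model fit
#'
#' Per-treatment bias is `log(prediction) - log(truth)`; the study's summary
#' metric sums these over the three treatments. Zero means the method
#' recovers the true treatment means on average; positive values
#' overestimate, negative underestimate.
#'
#' @param fit A `model_fit`.
#' @param params The [simulation_params()] that generated the data.
#' @return A list with `per_treatment` (named numeric) and `summed` (scalar),
#'   or `NULL` for a non-converged fit (callers count these as failed).
#' @examples
#' f <- new_fit <- structure(list(model_id = "demo",
#'   treatment_log_predictions = log(c(1.47, 2.94, 5.88)),
#'   converged = TRUE, dispersion = NA, notes = character()),
#'   class = "model_fit")
#' model_bias(f, simulation_params())$summed # 0
#' @export
model_bias <- function(fit, params) {
  stopifnot(inherits(fit, "model_fit"))
  if (!isTRUE(fit$converged)) return(NULL)
  per <- fit$treatment_log_predictions - log(treatment_truth(params))
  list(per_treatment = per, summed = sum(per))
}

#' Run one grid cell: a batch of simulations under one loss condition
#'
#' Applies the scenario to each dataset (fresh loss draw per dataset, seeds
#' derived from `master_seed`), fits the five models, and records predictions
#' and biases per simulation.
#'
#' @param datasets A list of `trap_dataset`s from [simulate_batch()].
#' @param scenario A [loss_scenario()].
#' @param master_seed Integer seed for the loss draws.
#' @param profile Seasonal profile passed to the known-seasonality models;
#'   default the datasets' own generating profile.
#' @return A data frame of per-simulation records: `sim`, `model_id`,
#'   `scenario`, `loss_pct`, `treatment`, `log_prediction`, `converged`,
#'   `dispersion`, `bias`, `summed_bias`.
#' @export
run_cell <- function(datasets, scenario, master_seed = 1L, profile = NULL) {
  stopifnot(inherits(scenario, "loss_scenario"))
  params <- attr(datasets[[1]], "params") %||% simulation_params()
  truth <- treatment_truth(params)

  recs <- lapply(seq_along(datasets), function(i) {
    lost <- apply_loss(datasets[[i]], scenario, derive_seed(master_seed, i))
    fits <- fit_all_models(lost, profile)
    do.call(rbind, lapply(fits, function(f) {
      b <- model_bias(f, params)
      data.frame(
        sim = i,
        model_id = f$model_id,
        scenario = scenario$kind,
        loss_pct = overall_loss_pct(scenario),
        treatment = seq_along(truth),
        log_prediction = f$treatment_log_predictions,
        converged = f$converged,
        dispersion = f$dispersion,
        bias = if (is.null(b)) NA_real_ else unname(b$per_treatment),
        summed_bias = if (is.null(b)) NA_real_ else b$summed,
        row.names = NULL
      )
    }))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Summarize per-simulation records into mean-bias tables
#'
#' Aggregates [run_cell()] (or [run_grid()]) records to the study's headline
#' metric: the mean over simulations of the summed (over treatments)
#' log-scale bias, with its Monte Carlo standard error, per model x scenario
#' x loss level. Failed (non-converged) simulations are excluded from the
#' mean and counted; cells where more than 10% of simulations failed are
#' flagged unreliable.
#'
#' @param records Per-simulation record data frame.
#' @return A data frame with one row per (`param_set` if present, `scenario`,
#'   `loss_pct`, `model_id`): `mean_bias`, `se_bias`, `n_sims`, `n_failed`,
#'   `unreliable`.
#' @export
summarize_bias <- function(records) {
  keys <- intersect(c("param_set", "scenario", "loss_pct", "model_id"), names(records))
  one <- records[records$treatment == 1L, , drop = FALSE] # one row per sim x model
  split_keys <- interaction(one[keys], drop = TRUE)
  parts <- split(one, split_keys)
  out <- do.call(rbind, lapply(parts, function(p) {
    ok <- p$converged & is.finite(p$summed_bias)
    b <- p$summed_bias[ok]
    cbind(
      p[1, keys, drop = FALSE],
      data.frame(
        mean_bias = mean(b),
        se_bias = stats::sd(b) / sqrt(length(b)),
        n_sims = nrow(p),
        n_failed = sum(!ok),
        unreliable = sum(!ok) > 0.1 * nrow(p)
      )
    )
  }))
  rownames(out) <- NULL
  out[order(interaction(out[keys], drop = TRUE)), , drop = FALSE]
}

#' Box-whisker quantiles of predicted catch per treatment
#'
#' Distribution of back-transformed treatment predictions across simulations:
#' median, quartiles and whiskers at 1.5 IQR (clamped to the observed range),
#' the ingredients of the study's box-and-whisker figures.
#'
#' @param records Per-simulation record data frame.
#' @return A data frame keyed by (`param_set` if present, `scenario`,
#'   `loss_pct`, `model_id`, `treatment`) with columns `q25`, `median`,
#'   `q75`, `lower_whisker`, `upper_whisker`, `n`.
#' @export
prediction_quantiles <- function(records) {
  keys <- intersect(c("param_set", "scenario", "loss_pct", "model_id", "treatment"),
                    names(records))
  ok <- records[records$converged & is.finite(records$log_prediction), , drop = FALSE]
  parts <- split(ok, interaction(ok[keys], drop = TRUE))
  out <- do.call(rbind, lapply(parts, function(p) {
    pred <- exp(p$log_prediction)
    q <- stats::quantile(pred, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    cbind(
      p[1, keys, drop = FALSE],
      data.frame(
        q25 = q[1], median = q[2], q75 = q[3],
        lower_whisker = max(min(pred), q[1] - 1.5 * iqr),
        upper_whisker = min(max(pred), q[3] + 1.5 * iqr),
        n = nrow(p)
      )
    )
  }))
  rownames(out) <- NULL
  out[order(interaction(out[keys], drop = TRUE)), , drop = FALSE]
}

#' Run the full simulation grid
#'
#' For each requested parameter set, simulates one batch of datasets and
#' evaluates every scenario x loss level on the *same* batch (the study's
#' design: the datasets are manipulated to mimic trap loss, not resimulated),
#' fitting all five models throughout.
#'
#' @param param_sets Named list of [simulation_params()] (e.g. a subset of
#'   [parameter_sets()]).
#' @param scenarios Character vector of scenario kinds.
#' @param loss_pcts Overall loss percentages (subset of 0/5/10/15/20).
#' @param n_sims Simulations per parameter set (default 100).
#' @param master_seed Integer master seed driving both simulation and loss.
#' @return A list with `records` (per-simulation) and `summary`
#'   ([summarize_bias()] output), each carrying a `param_set` column.
#' @export
run_grid <- function(param_sets,
                     scenarios = c("high_catch", "low_catch"),
                     loss_pcts = c(0, 5, 10, 15, 20),
                     n_sims = 100L,
                     master_seed = 1L) {
  if (is.null(names(param_sets))) stop("param_sets must be a named list")
  all_records <- list()
  for (pi in seq_along(param_sets)) {
    pname <- names(param_sets)[pi]
    datasets <- simulate_batch(param_sets[[pi]], n_sims,
                               master_seed = derive_seed(master_seed, pi))
    for (sc in scenarios) {
      for (lp in loss_pcts) {
        scen <- loss_scenario(sc, loss_fraction_from_overall(lp))
        loss_seed <- derive_seed(master_seed, pi * 10000 + match(sc, scenarios) * 100 + lp)
        rec <- run_cell(datasets, scen, master_seed = loss_seed)
        rec <- cbind(param_set = pname, rec)
        all_records[[length(all_records) + 1L]] <- rec
      }
    }
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  list(records = records, summary = summarize_bias(records))
}

#' Mean estimated percent increase of a treatment over Treatment 1
#'
#' For one model's records, computes per simulation the percent increase of
#' the back-transformed prediction for `treatment` over Treatment 1, and
#' averages over simulations. The true values are 100% (Treatment 2) and
#' 400% (Treatment 3) under the default multipliers.
#'
#' @param records Per-simulation records filtered as desired.
#' @param model_id Model to evaluate.
#' @param treatment Treatment compared to Treatment 1.
#' @return Mean percent increase across converged simulations.
#' @export
percent_increase <- function(records, model_id, treatment) {
  r <- records[records$model_id == model_id & records$converged, , drop = FALSE]
  ref <- r[r$treatment == 1L, c("sim", "log_prediction")]
  cmp <- r[r$treatment == treatment, c("sim", "log_prediction")]
  m <- merge(ref, cmp, by = "sim", suffixes = c("_1", "_t"))
  mean((exp(m$log_prediction_t - m$log_prediction_1) - 1) * 100)
}
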