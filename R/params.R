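#' Seasonal activity profile
#'
#' Fixed fractions of a species' season-total catch expected in each of the
#' five 20-day trapping intervals. The default is the activity pattern of a
#' spring-active carabid beetle: most individuals are caught early in the
#' season and captures tail off sharply afterwards.
#'
#' @param proportions Numeric vector of 5 fractions, each in (0, 1), summing
#'   to 1 (within 1e-9).
#' @return A `seasonal_profile` object (a numeric vector of length 5).
#' @examples
#' seasonal_profile()
#' seasonal_profile(rep(0.2, 5)) # flat activity
#' @export
seasonal_profile <- function(proportions = c(0.25, 0.49, 0.13, 0.09, 0.04)) {
  proportions <- as.numeric(proportions)
  if (length(proportions) != 5L) {
    stop("a seasonal profile must have exactly 5 interval proportions")
  }
  if (any(!is.finite(proportions)) || any(proportions <= 0) || any(proportions >= 1)) {
    stop("each seasonal proportion must lie strictly in (0, 1)")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("seasonal proportions must sum to 1 (tolerance 1e-9)")
  }
  structure(proportions, class = "seasonal_profile")
}

#' Simulation parameters for seasonal trap-catch data
#'
#' Bundles the design dimensions and stochastic-process parameters of the
#' Poisson log-normal trap-catch generator. The default design is 3 treatments
#' x 5 replicate plots x 4 pitfall traps x 5 twenty-day intervals (300
#' trapping events over a 100-day season). `mean_catch_t1` is the expected
#' season-total catch of one trap in Treatment 1; treatments 2 and 3 scale it
#' by the `treatment_multipliers`. `site_sd` and `trap_sd` are standard
#' deviations of log-normal random effects (log scale) acting at the
#' replicate-plot and trap level respectively.
#'
#' @param mean_catch_t1 Expected per-trap season-total catch for Treatment 1
#'   (individuals/trap); must be positive. Default 1.47, a field estimate for
#'   *Pterostichus oblongopunctatus*.
#' @param site_sd,trap_sd Standard deviations (log scale) of the replicate-
#'   and trap-level random effects; non-negative. Defaults 0.14 and 0.30.
#' @param treatment_multipliers Multipliers applied to `mean_catch_t1` per
#'   treatment. Default `c(1, 2, 4)`.
#' @param n_treatments,n_replicates,n_traps,n_intervals Design dimensions.
#' @param interval_days Length of one trapping interval in days (default 20).
#' @param profile A [seasonal_profile()].
#' @return A `simulation_params` list.
#' @examples
#' simulation_params()
#' simulation_params(mean_catch_t1 = 1.47 * 5) # "High Mean" condition
#' @export
simulation_params <- function(mean_catch_t1 = 1.47,
                              site_sd = 0.14,
                              trap_sd = 0.30,
                              treatment_multipliers = c(1, 2, 4),
                              n_treatments = 3L,
                              n_replicates = 5L,
                              n_traps = 4L,
                              n_intervals = 5L,
                              interval_days = 20,
                              profile = seasonal_profile()) {
  if (!is.numeric(mean_catch_t1) || length(mean_catch_t1) != 1L || mean_catch_t1 <= 0) {
    stop("mean_catch_t1 must be a single positive number")
  }
  if (site_sd < 0 || trap_sd < 0) {
    stop("site_sd and trap_sd must be non-negative")
  }
  if (length(treatment_multipliers) != n_treatments ||
      any(treatment_multipliers <= 0)) {
    stop("treatment_multipliers must give one positive multiplier per treatment")
  }
  if (!inherits(profile, "seasonal_profile")) profile <- seasonal_profile(profile)
  if (length(profile) != n_intervals) {
    stop("seasonal profile length must equal n_intervals")
  }
  structure(
    list(
      mean_catch_t1 = mean_catch_t1,
      site_sd = site_sd,
      trap_sd = trap_sd,
      treatment_multipliers = as.numeric(treatment_multipliers),
      n_treatments = as.integer(n_treatments),
      n_replicates = as.integer(n_replicates),
      n_traps = as.integer(n_traps),
      n_intervals = as.integer(n_intervals),
      interval_days = as.numeric(interval_days),
      profile = profile
    ),
    class = "simulation_params"
  )
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Trap-catch simulation parameters\n")
  cat(sprintf("  design: %d treatments x %d replicates x %d traps x %d intervals (%g days each)\n",
              x$n_treatments, x$n_replicates, x$n_traps, x$n_intervals, x$interval_days))
  cat(sprintf("  per-trap season mean (Treatment 1): %g; multipliers: %s\n",
              x$mean_catch_t1, paste(x$treatment_multipliers, collapse = ", ")))
  cat(sprintf("  random-effect SDs (log scale): site %g, trap %g\n", x$site_sd, x$trap_sd))
  cat(sprintf("  seasonal profile: %s\n", paste(format(unclass(x$profile)), collapse = ", ")))
  invisible(x)
}

#' Named parameter sets of the simulation study
#'
#' The seven conditions evaluated: the field-estimated baseline and six
#' perturbations obtained by multiplying or dividing the Treatment 1 mean by
#' 5, and each random-effect *variance* (squared SD) by 5.
#'
#' @return A named list of [simulation_params()] objects with names `field`,
#'   `low_mean`, `high_mean`, `lo_site_lo_trap`, `lo_site_hi_trap`,
#'   `hi_site_lo_trap`, `hi_site_hi_trap`.
#' @examples
#' names(parameter_sets())
#' parameter_sets()[["high_mean"]]$mean_catch_t1 # 7.35
#' @export
parameter_sets <- function() {
  base_mean <- 1.47
  site <- 0.14
  trap <- 0.30
  lo <- function(sd) sd / sqrt(5) # variance / 5
  hi <- function(sd) sd * sqrt(5) # variance x 5
  list(
    field           = simulation_params(base_mean,     site,     trap),
    low_mean        = simulation_params(base_mean / 5, site,     trap),
    high_mean       = simulation_params(base_mean * 5, site,     trap),
    lo_site_lo_trap = simulation_params(base_mean,     lo(site), lo(trap)),
    lo_site_hi_trap = simulation_params(base_mean,     lo(site), hi(trap)),
    hi_site_lo_trap = simulation_params(base_mean,     hi(site), lo(trap)),
    hi_site_hi_trap = simulation_params(base_mean,     hi(site), hi(trap))
  )
}

#' Load parameter sets from a YAML config file
#'
#' Reads a config keyed by the parameter-set names understood by
#' [parameter_sets()]. Each entry may override `mean_catch_t1`, `site_sd`,
#' `trap_sd`, `treatment_multipliers` or `profile`; omitted fields take the
#' defaults of [simulation_params()].
#'
#' @param path Path to a YAML file.
#' @return A named list of `simulation_params`.
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg))) {
    stop("config must be a named mapping of parameter sets")
  }
  lapply(cfg, function(entry) {
    do.call(simulation_params, entry[intersect(
      names(entry),
      names(formals(simulation_params))
    )])
  })
}

#' Expected catch of a treatment x interval design cell
#'
#' Expected total catch, summed over all traps of one treatment, in one time
#' interval, before random effects are applied:
#' `mean_catch_t1 * multiplier * n_replicates * n_traps * profile[interval]`.
#' With the default field parameters these are the printed average catches of
#' the design table (7.35, 14.4, ... per treatment and interval).
#'
#' @param params A [simulation_params()].
#' @param treatment Treatment index (1-based); may be a vector.
#' @param interval Interval index (1-based); may be a vector.
#' @return Numeric expected catch, recycled over `treatment`/`interval`.
#' @examples
#' expected_cell_catch(simulation_params(), treatment = 2, interval = 2) # 28.8
#' @export
expected_cell_catch <- function(params, treatment, interval) {
  stopifnot(inherits(params, "simulation_params"))
  if (any(treatment < 1 | treatment > params$n_treatments) ||
      any(treatment != as.integer(treatment))) {
    stop("treatment index out of range")
  }
  if (any(interval < 1 | interval > params$n_intervals) ||
      any(interval != as.integer(interval))) {
    stop("interval index out of range")
  }
  params$mean_catch_t1 *
    params$treatment_multipliers[treatment] *
    params$n_replicates * params$n_traps *
    unclass(params$profile)[interval]
}

#' Expected-catch table over the whole design
#'
#' @param params A [simulation_params()].
#' @return A matrix (`n_intervals` rows x `n_treatments` columns) of expected
#'   cell catches, with a `"total"` attribute giving the per-treatment season
#'   totals.
#' @export
expected_catch_table <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  tab <- outer(
    seq_len(params$n_intervals),
    seq_len(params$n_treatments),
    function(i, t) expected_cell_catch(params, t, i)
  )
  dimnames(tab) <- list(
    interval = seq_len(params$n_intervals),
    treatment = seq_len(params$n_treatments)
  )
  attr(tab, "total") <- colSums(tab)
  tab
}
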