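#' Simulate one seasonal trap-catch dataset
#'
#' Generates the full crossed design (every treatment x replicate x trap x
#' interval combination once) from a Poisson log-normal process. One normal
#' deviate is drawn per replicate plot (SD `site_sd`) and one per trap
#' (SD `trap_sd`), on the log scale, and both are held constant across the
#' season: a physical plot or trap has a single persistent effect. The count
#' of trap j in interval i is then
#' `Poisson(mean_catch_t1 * multiplier * profile[i] * exp(site + trap))`.
#'
#' No log-normal mean correction is applied, so realized expectations exceed
#' [expected_cell_catch()] by the factor `exp((site_sd^2 + trap_sd^2) / 2)`
#' (about 5.6% at the default SDs); the design-table expectations are the
#' pre-random-effect means.
#'
#' @param params A [simulation_params()].
#' @param seed Integer seed; identical `(params, seed)` give bitwise-identical
#'   datasets.
#' @return A `trap_dataset`: a data frame with one row per trapping event and
#'   columns `treatment`, `replicate`, `trap`, `interval`, `count`,
#'   `trap_days`, `lost` (all `FALSE` here), plus `params` and `seed`
#'   attributes.
#' @examples
#' d <- simulate_dataset(simulation_params(), seed = 1)
#' nrow(d)      # 300
#' sum(d$count) # one realization of the ~205.8 expected season total
#' @export
simulate_dataset <- function(params, seed) {
  stopifnot(inherits(params, "simulation_params"))
  seed <- as.integer(seed)

  des <- expand.grid(
    interval = seq_len(params$n_intervals),
    trap = seq_len(params$n_traps),
    replicate = seq_len(params$n_replicates),
    treatment = seq_len(params$n_treatments),
    KEEP.OUT.ATTRS = FALSE
  )
  des <- des[, c("treatment", "replicate", "trap", "interval")]
  des <- des[order(des$treatment, des$replicate, des$trap, des$interval), ]
  rownames(des) <- NULL

  n_sites <- params$n_treatments * params$n_replicates
  n_trap_units <- n_sites * params$n_traps

  set.seed(seed)
  site_eff <- stats::rnorm(n_sites, 0, params$site_sd)
  trap_eff <- stats::rnorm(n_trap_units, 0, params$trap_sd)

  site_id <- (des$treatment - 1L) * params$n_replicates + des$replicate
  trap_id <- (site_id - 1L) * params$n_traps + des$trap

  lambda <- params$mean_catch_t1 *
    params$treatment_multipliers[des$treatment] *
    unclass(params$profile)[des$interval] *
    exp(site_eff[site_id] + trap_eff[trap_id])
  if (any(!is.finite(lambda))) stop("non-finite Poisson rate in simulation")

  des$count <- stats::rpois(nrow(des), lambda)
  des$trap_days <- params$interval_days
  des$lost <- FALSE

  structure(des,
    params = params, seed = seed,
    class = c("trap_dataset", "data.frame")
  )
}

#' Derive a per-dataset seed from a master seed
#'
#' Lehmer-style stable hash: `(master_seed + index * 48271) mod (2^31 - 1)`,
#' mapped away from zero. Distinct indices give distinct seeds and every seed
#' fits in a 32-bit integer, so individual datasets of a batch can be replayed
#' without regenerating the whole batch.
#'
#' @param master_seed Integer master seed.
#' @param index 1-based dataset index (vectorized).
#' @return Integer seed(s) in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master_seed) %% m + as.numeric(index) * 48271) %% m
  as.integer(s + (s == 0))
}

#' Simulate a batch of datasets
#'
#' @param params A [simulation_params()].
#' @param n_sims Number of datasets (default 100, the study's Monte Carlo
#'   size).
#' @param master_seed Integer; per-dataset seeds are derived with
#'   [derive_seed()].
#' @return A list of `n_sims` [simulate_dataset()] results.
#' @export
simulate_batch <- function(params, n_sims = 100L, master_seed = 1L) {
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1L) stop("n_sims must be at least 1")
  lapply(seq_len(n_sims), function(i) {
    simulate_dataset(params, derive_seed(master_seed, i))
  })
}

#' Write / read a trap-catch dataset as long-format CSV
#'
#' One row per trapping event with header
#' `treatment,replicate,trap,interval,count,trap_days,lost`. Lost
#' observations are written with their flag so either representation
#' (flagged or deleted) can be reconstructed downstream.
#'
#' @param dataset A `trap_dataset`.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns a
#'   `trap_dataset` (without `params`/`seed` attributes, which are not stored
#'   in the CSV).
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "trap_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("treatment", "replicate", "trap", "interval", "count", "trap_days", "lost")
  if (!all(needed %in% names(d))) {
    stop("dataset CSV must have columns: ", paste(needed, collapse = ", "))
  }
  d$lost <- as.logical(d$lost)
  structure(d[, needed], class = c("trap_dataset", "data.frame"))
}

#' Surviving (non-lost) observations of a dataset
#'
#' @param dataset A `trap_dataset`.
#' @return The subset of rows with `lost == FALSE`. Lost observations
#'   contribute neither counts nor trap-days to any downstream computation.
#' @export
surviving <- function(dataset) {
  dataset[!dataset$lost, , drop = FALSE]
}
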