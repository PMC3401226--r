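#' Replicate-level catch standardized to 100 trap-days
#'
#' The traditional standardization used in the pitfall-trapping literature:
#' catches are summed over the traps and intervals of each replicate plot and
#' divided by the trap-days those traps actually operated, times 100. With no
#' losses each replicate of the default design ran 400 trap-days (4 traps x
#' 5 intervals x 20 days), so the standardized catch equals the per-trap
#' season total. Seasonal activity is deliberately not taken into account —
#' that is the point of the method being evaluated.
#'
#' Lost observations are excluded from both the catch (numerator) and the
#' trap-days (denominator).
#'
#' @param dataset A `trap_dataset`, possibly with losses applied.
#' @return A data frame with one row per treatment x replicate and columns
#'   `treatment`, `replicate`, `total_count`, `trap_days`,
#'   `standardized_catch` (individuals per 100 trap-days).
#' @examples
#' d <- simulate_dataset(simulation_params(), seed = 1)
#' summarize_replicates(d)
#' @export
summarize_replicates <- function(dataset) {
  stopifnot(inherits(dataset, "trap_dataset"))
  params <- attr(dataset, "params") %||% simulation_params()
  alive <- surviving(dataset)

  grid <- expand.grid(
    replicate = seq_len(params$n_replicates),
    treatment = seq_len(params$n_treatments)
  )[, c("treatment", "replicate")]

  agg <- stats::aggregate(
    cbind(total_count = count, trap_days = trap_days) ~ treatment + replicate,
    data = alive, FUN = sum
  )
  out <- merge(grid, agg, by = c("treatment", "replicate"), all.x = TRUE, sort = FALSE)
  out <- out[order(out$treatment, out$replicate), ]
  rownames(out) <- NULL

  if (any(is.na(out$trap_days)) || any(out$trap_days <= 0)) {
    stop("a replicate has zero surviving trap-days; cannot standardize")
  }
  out$standardized_catch <- out$total_count / out$trap_days * 100
  out
}
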