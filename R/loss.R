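#' Trap-loss scenario
#'
#' Describes which design cells are eligible for trap loss and how severely
#' they are hit. The two targeted scenarios bracket the bias directions:
#' `high_catch` loses traps where expected catch is highest (treatments 2-3 x
#' intervals 1-2, the high-abundance treatments during peak activity) and
#' `low_catch` where it is lowest (treatments 1-2 x intervals 4-5). Either
#' pool holds 80 of the 300 trapping events, so the within-cell severities
#' 0.1875/0.375/0.5625/0.75 remove exactly 15/30/45/60 points — 5/10/15/20%
#' of the whole design. `random` removes the same four totals from the whole
#' design; `none` removes nothing.
#'
#' @param kind One of `"high_catch"`, `"low_catch"`, `"random"`, `"none"`.
#' @param within_cell_fraction One of 0, 0.1875, 0.375, 0.5625, 0.75: the
#'   fraction of the eligible pool to lose. Forced to 0 for `kind = "none"`.
#' @return A `loss_scenario` list.
#' @examples
#' loss_scenario("high_catch", 0.75)     # 20% of the whole design
#' loss_scenario("low_catch", 0.1875)    # 5%
#' @export
loss_scenario <- function(kind = c("high_catch", "low_catch", "random", "none"),
                          within_cell_fraction = 0) {
  kind <- match.arg(kind)
  allowed <- c(0, 0.1875, 0.375, 0.5625, 0.75)
  if (kind == "none") within_cell_fraction <- 0
  ok <- any(abs(within_cell_fraction - allowed) < 1e-12)
  if (length(within_cell_fraction) != 1L || !ok) {
    stop("within_cell_fraction must be one of ", paste(allowed, collapse = ", "))
  }
  structure(
    list(kind = kind, within_cell_fraction = within_cell_fraction),
    class = "loss_scenario"
  )
}

#' Map an overall design loss percentage to a within-cell fraction
#'
#' The study reports loss as a percentage of the whole 300-point design
#' (0/5/10/15/20%); within the 80-point eligible pool these correspond to
#' fractions 0/0.1875/0.375/0.5625/0.75.
#'
#' @param pct Overall loss percent: 0, 5, 10, 15 or 20.
#' @return The matching within-cell fraction.
#' @export
loss_fraction_from_overall <- function(pct) {
  map <- c(`0` = 0, `5` = 0.1875, `10` = 0.375, `15` = 0.5625, `20` = 0.75)
  key <- as.character(pct)
  if (!key %in% names(map)) stop("overall loss percent must be 0, 5, 10, 15 or 20")
  unname(map[key])
}

#' Overall design loss percentage of a scenario
#'
#' @param scenario A [loss_scenario()].
#' @return Percent of the 300-point default design lost (0, 5, 10, 15 or 20).
#' @export
overall_loss_pct <- function(scenario) {
  stopifnot(inherits(scenario, "loss_scenario"))
  scenario$within_cell_fraction * 80 / 300 * 100
}

#' Design cells eligible for loss under a scenario
#'
#' @param scenario A [loss_scenario()].
#' @param params A [simulation_params()] (defines the design dimensions).
#' @return A data frame of eligible `(treatment, interval)` pairs; all cells
#'   for `random`, none for `none`.
#' @export
eligible_cells <- function(scenario, params = simulation_params()) {
  stopifnot(inherits(scenario, "loss_scenario"))
  switch(scenario$kind,
    high_catch = expand.grid(treatment = c(2L, 3L), interval = c(1L, 2L)),
    low_catch = expand.grid(treatment = c(1L, 2L), interval = c(4L, 5L)),
    random = expand.grid(
      treatment = seq_len(params$n_treatments),
      interval = seq_len(params$n_intervals)
    ),
    none = data.frame(treatment = integer(), interval = integer())
  )
}

#' Number of observations removed by a scenario
#'
#' Exact totals, not per-observation Bernoulli trials: the four severities
#' remove 15, 30, 45 and 60 of the 80 eligible points for the targeted
#' scenarios, and the same absolute totals from the whole design for
#' `random`.
#'
#' @param scenario A [loss_scenario()].
#' @return Integer number of observations to flag as lost.
#' @examples
#' n_lost(loss_scenario("high_catch", 0.75)) # 60
#' @export
n_lost <- function(scenario) {
  stopifnot(inherits(scenario, "loss_scenario"))
  if (scenario$kind == "none") return(0L)
  as.integer(round(scenario$within_cell_fraction * 80))
}

#' Apply trap loss to a complete dataset
#'
#' Samples exactly [n_lost()] observations uniformly without replacement from
#' the scenario's eligible pool and flags them `lost = TRUE`. Counts of
#' surviving observations are untouched; flagged rows are treated as absent
#' by every downstream computation (see [surviving()]).
#'
#' @param dataset A complete `trap_dataset` (no prior losses).
#' @param scenario A [loss_scenario()].
#' @param seed Integer seed; the same `(dataset, scenario, seed)` always flags
#'   the same rows.
#' @return The dataset with `lost` updated and a `loss_scenario` attribute.
#' @export
apply_loss <- function(dataset, scenario, seed) {
  stopifnot(inherits(dataset, "trap_dataset"), inherits(scenario, "loss_scenario"))
  if (any(dataset$lost)) stop("dataset already has losses applied")
  n <- n_lost(scenario)
  if (n == 0L) {
    attr(dataset, "loss_scenario") <- scenario
    return(dataset)
  }
  cells <- eligible_cells(scenario, attr(dataset, "params") %||% simulation_params())
  pool <- which(interaction(dataset$treatment, dataset$interval) %in%
    interaction(cells$treatment, cells$interval))
  if (n > length(pool)) {
    stop(sprintf("cannot lose %d observations from a pool of %d", n, length(pool)))
  }
  set.seed(as.integer(seed))
  dataset$lost[sample(pool, n)] <- TRUE
  attr(dataset, "loss_scenario") <- scenario
  dataset
}

`%||%` <- function(a, b) if (is.null(a)) b else a
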