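test_that("seasonal profile validates its invariants", {
  p <- seasonal_profile()
  expect_equal(unclass(p), c(0.25, 0.49, 0.13, 0.09, 0.04))
  expect_equal(sum(p), 1)
  expect_error(seasonal_profile(c(0.5, 0.5)), "exactly 5")
  expect_error(seasonal_profile(c(0.5, 0.2, 0.2, 0.05, 0.1)), "sum to 1")
  expect_error(seasonal_profile(c(1, 0, 0, 0, 0)), "strictly")
})

test_that("the seven named parameter sets are constructible with the stated perturbations", {
  ps <- parameter_sets()
  expect_named(ps, c("field", "low_mean", "high_mean", "lo_site_lo_trap",
                     "lo_site_hi_trap", "hi_site_lo_trap", "hi_site_hi_trap"))
  expect_equal(ps$field$mean_catch_t1, 1.47)
  expect_equal(ps$field$site_sd, 0.14)
  expect_equal(ps$field$trap_sd, 0.30)
  expect_equal(ps$low_mean$mean_catch_t1, 1.47 / 5)
  expect_equal(ps$high_mean$mean_catch_t1, 1.47 * 5)
  # variance (squared SD) scaled by 5, not the SD itself
  expect_equal(ps$hi_site_lo_trap$site_sd^2, 5 * 0.14^2)
  expect_equal(ps$hi_site_lo_trap$trap_sd^2, 0.30^2 / 5)
  expect_equal(ps$lo_site_hi_trap$site_sd^2, 0.14^2 / 5)
  expect_equal(ps$lo_site_hi_trap$trap_sd^2, 5 * 0.30^2)
})

test_that("expected cell catch follows the design formula and rejects bad indices", {
  p <- simulation_params()
  # mean * multiplier * 20 traps * interval share
  expect_equal(expected_cell_catch(p, 2, 2), 1.47 * 2 * 20 * 0.49)
  expect_equal(expected_cell_catch(p, 1, 5), 1.47 * 20 * 0.04)
  expect_error(expected_cell_catch(p, 4, 1), "out of range")
  expect_error(expected_cell_catch(p, 1, 6), "out of range")
  expect_error(expected_cell_catch(p, 1.5, 1), "out of range")

  # conservation: grand total = mean * sum(multipliers) * 20 traps
  tab <- expected_catch_table(p)
  expect_equal(sum(tab), 1.47 * (1 + 2 + 4) * 20)
  expect_equal(unname(attr(tab, "total")), c(29.4, 58.8, 117.6))

  # near-degenerate profile: almost all activity in interval 1
  eps <- 2.5e-10
  pd <- simulation_params(profile = seasonal_profile(c(1 - 4 * eps, rep(eps, 4))))
  expect_equal(expected_cell_catch(pd, 3, 1), 1.47 * 4 * 20, tolerance = 1e-8)
  expect_lt(expected_cell_catch(pd, 3, 2), 1e-6)
})

test_that("simulated datasets cover the full design exactly once and are reproducible", {
  p <- simulation_params()
  d <- simulate_dataset(p, 7)
  expect_s3_class(d, "trap_dataset")
  expect_equal(nrow(d), 300L)
  expect_equal(anyDuplicated(d[c("treatment", "replicate", "trap", "interval")]), 0L)
  expect_true(all(d$count >= 0) && all(d$count == floor(d$count)))
  expect_true(all(d$trap_days == 20))
  expect_false(any(d$lost))

  expect_identical(
    as.data.frame(simulate_dataset(p, 7)),
    as.data.frame(simulate_dataset(p, 7))
  )
  expect_false(identical(
    simulate_dataset(p, 7)$count,
    simulate_dataset(p, 8)$count
  ))
})

test_that("variance-free high-mean limit recovers the expected cell catches", {
  p <- simulation_params(mean_catch_t1 = 500, site_sd = 0, trap_sd = 0)
  d <- simulate_dataset(p, 11)
  for (tr in 1:3) {
    for (iv in c(1, 2, 5)) {
      got <- sum(d$count[d$treatment == tr & d$interval == iv])
      exp_catch <- expected_cell_catch(p, tr, iv)
      # cell total is Poisson(exp_catch): allow 4 SDs
      expect_lt(abs(got - exp_catch), 4 * sqrt(exp_catch))
    }
  }
})

test_that("Monte Carlo mean matches the closed-form log-normal inflation oracle", {
  p <- simulation_params() # field parameters
  n <- 600
  totals <- vapply(
    simulate_batch(p, n, master_seed = 20),
    function(d) sum(d$count[d$treatment == 1]), numeric(1)
  )
  target <- 29.4 * exp((0.14^2 + 0.30^2) / 2) # ~31.06
  se <- sd(totals) / sqrt(n)
  expect_lt(abs(mean(totals) - target), 3 * se)
  # ... and 3 SEs distinguishes the inflated from the uninflated expectation
  expect_gt(abs(target - 29.4), 3 * se)
})

test_that("random effects make counts over-dispersed relative to Poisson", {
  p_disp <- simulation_params(mean_catch_t1 = 50)
  p_pois <- simulation_params(mean_catch_t1 = 50, site_sd = 0, trap_sd = 0)
  # counts of treatment 3 traps in interval 2 (per-trap mean 98) across datasets
  pick <- function(d) d$count[d$treatment == 3 & d$interval == 2]
  x_disp <- unlist(lapply(simulate_batch(p_disp, 100, 31), pick))
  x_pois <- unlist(lapply(simulate_batch(p_pois, 100, 31), pick))
  expect_gt(var(x_disp) / mean(x_disp), 2)
  expect_lt(var(x_pois) / mean(x_pois), 1.3)
})

test_that("batch seeds are derived deterministically and give distinct datasets", {
  expect_true(all(derive_seed(1, 1:1000) >= 1))
  expect_true(all(derive_seed(1, 1:1000) < 2^31))
  expect_equal(anyDuplicated(derive_seed(123, 1:1000)), 0L)

  p <- simulation_params()
  b <- simulate_batch(p, 5, master_seed = 99)
  expect_length(b, 5)
  counts <- lapply(b, `[[`, "count")
  expect_equal(anyDuplicated(counts), 0L)
  # singleton batch equals a direct call with the derived seed
  expect_identical(
    as.data.frame(simulate_batch(p, 1, master_seed = 99)[[1]]),
    as.data.frame(simulate_dataset(p, derive_seed(99, 1)))
  )
  expect_error(simulate_batch(p, 0, 1), "at least 1")
})

test_that("datasets round-trip through long-format CSV", {
  d <- simulate_dataset(simulation_params(), 3)
  d <- apply_loss(d, loss_scenario("low_catch", 0.375), 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(d), ignore_attr = TRUE)
  header <- readLines(path, n = 1)
  expect_equal(header, "\"treatment\",\"replicate\",\"trap\",\"interval\",\"count\",\"trap_days\",\"lost\"")
})

test_that("parameter sets load from a YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "field:",
    "  mean_catch_t1: 1.47",
    "  site_sd: 0.14",
    "  trap_sd: 0.30",
    "high_mean:",
    "  mean_catch_t1: 7.35"
  ), path)
  cfg <- read_params_config(path)
  expect_named(cfg, c("field", "high_mean"))
  expect_equal(cfg$field$trap_sd, 0.30)
  expect_equal(cfg$high_mean$mean_catch_t1, 7.35)
  expect_equal(cfg$high_mean$site_sd, 0.14) # default filled in
})
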