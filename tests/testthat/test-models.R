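params_field <- simulation_params()

test_that("analysis table aggregates surviving traps at replicate x interval grain", {
  d <- simulate_dataset(params_field, 21)
  tab <- build_analysis_table(d)
  expect_equal(nrow(tab), 75L)
  expect_true(all(tab$n_traps == 4L))
  expect_equal(attr(tab, "n_dropped"), 0L)
  expect_equal(sum(tab$abundance), sum(d$count))
  expect_equal(unique(tab$seasonal_pct[tab$interval == 2]), 49)

  dl <- apply_loss(d, loss_scenario("high_catch", 0.75), 13)
  tl <- build_analysis_table(dl)
  expect_equal(sum(tl$abundance), sum(surviving(dl)$count))
  hit <- tl$treatment %in% c(2, 3) & tl$interval %in% c(1, 2)
  expect_true(any(tl$n_traps[hit] < 4))
  expect_true(all(tl$n_traps[!hit] == 4))
  expect_true(all(tl$n_traps >= 1)) # zero-trap cells are dropped, not kept
  expect_equal(nrow(tl) + attr(tl, "n_dropped"), 75L)
})

test_that("M1 reproduces exact and closed-form OLS solutions", {
  # identical standardized catches -> prediction is that value, exactly
  rs <- data.frame(
    treatment = rep(1:3, each = 5), replicate = rep(1:5, 3),
    standardized_catch = 7
  )
  f <- fit_m1(rs, params_field)
  expect_equal(unname(f$treatment_log_predictions), rep(log(7), 3))

  # balanced values: group mean of ln(x+1), back-transformed exp(mu) - 1
  set.seed(1)
  rs$standardized_catch <- rexp(15, 1 / 3)
  f <- fit_m1(rs, params_field)
  mu <- as.numeric(tapply(log(rs$standardized_catch + 1), rs$treatment, mean))
  expect_equal(unname(f$treatment_log_predictions), log(exp(mu) - 1))

  # fitted mean below ln(1): guarded at machine floor and flagged
  rs$standardized_catch <- 0
  f0 <- fit_m1(rs, params_field)
  expect_match(f0$notes, "floored")
  expect_true(all(is.finite(f0$treatment_log_predictions)))
})

test_that("Gaussian offset model matches the shifted-response closed form", {
  d <- simulate_dataset(params_field, 30)
  tab <- build_analysis_table(d)
  f2 <- fit_m2(tab, params_field)

  sh <- tab
  sh$z <- log(sh$abundance + 1) - (log(sh$seasonal_pct) + log(sh$n_traps))
  sh$trt <- factor(sh$treatment, 1:3)
  oracle <- stats::lm(z ~ trt, data = sh)
  expect_equal(unname(coef(f2$fit)), unname(coef(oracle)), tolerance = 1e-10)
})

test_that("doubling the trap offset doubles the implied predicted catch", {
  d <- simulate_dataset(params_field, 30)
  tab <- build_analysis_table(d)
  f2 <- fit_m2(tab, params_field)
  newd <- data.frame(trt = factor(2, 1:3), off = log(49) + log(c(4, 8)))
  mu <- predict(f2$fit, newdata = newd)
  # exp(mu) is the predicted (catch + 1) scale quantity; offset coefficient is 1
  expect_equal(exp(mu[2]) / exp(mu[1]), 2, ignore_attr = TRUE)
})

test_that("offsets shift the intercept only: treatment contrasts are unit-invariant", {
  d <- simulate_dataset(params_field, 33)
  tab <- build_analysis_table(d)
  tab_prop <- tab
  tab_prop$seasonal_pct <- tab$seasonal_pct / 100 # proportions instead of percent

  f2a <- fit_m2(tab, params_field)
  f2b <- fit_m2(tab_prop, params_field)
  expect_equal(coef(f2b$fit)[1] - coef(f2a$fit)[1], log(100),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(coef(f2a$fit)[-1], coef(f2b$fit)[-1], tolerance = 1e-10)

  f4a <- fit_m4(tab, params_field)
  f4b <- fit_m4(tab_prop, params_field)
  expect_equal(coef(f4b$fit)[1] - coef(f4a$fit)[1], log(100),
               ignore_attr = TRUE, tolerance = 1e-5)
  expect_equal(coef(f4a$fit)[-1], coef(f4b$fit)[-1], tolerance = 1e-5)
})

test_that("the interval factor absorbs a known profile: M3 matches M2 at coefficient level", {
  # balanced no-loss design: treatment estimates are orthogonal to the
  # interval terms, so M2 (known offsets) and M3 (free factor) agree exactly
  for (seed in c(40, 41)) {
    tab <- build_analysis_table(simulate_dataset(params_field, seed))
    f2 <- fit_m2(tab, params_field)
    f3 <- fit_m3(tab, params_field)
    expect_equal(coef(f2$fit)[c("trt2", "trt3")], coef(f3$fit)[c("trt2", "trt3")],
                 tolerance = 1e-10)
  }
})

test_that("with a flat activity profile the estimated interval effects vanish", {
  p_flat <- simulation_params(mean_catch_t1 = 20, profile = seasonal_profile(rep(0.2, 5)))
  tab <- build_analysis_table(simulate_dataset(p_flat, 50))
  f3 <- fit_m3(tab, p_flat)
  f5 <- fit_m5(tab, p_flat)
  expect_lt(max(abs(coef(f3$fit)[grep("^ivl", names(coef(f3$fit)))])), 0.4)
  expect_lt(max(abs(coef(f5$fit)[grep("^ivl", names(coef(f5$fit)))])), 0.4)
})

test_that("M3 season-scale treatment 2 contrast tracks ln(2) across simulations", {
  n <- 40
  c3 <- vapply(seq_len(n), function(i) {
    tab <- build_analysis_table(simulate_dataset(params_field, derive_seed(55, i)))
    fit_contrasts(fit_m3(tab, params_field))[1]
  }, numeric(1))
  se <- sd(c3) / sqrt(n)
  # magnitude near ln 2, allowing the known downward transformation bias
  expect_gt(mean(c3), 0.3)
  expect_lt(mean(c3), log(2) + 3 * se)
})

test_that("NB saturated-mean identity: perfectly fitting counts give exact season totals", {
  # M4: counts proportional to the known profile saturate the offset model;
  # each trap catches pct_i per interval -> per-trap season total 100
  pct <- c(25L, 49L, 13L, 9L, 4L)
  mult <- c(1L, 2L, 4L)
  d4 <- constant_dataset(fill = function(des) mult[des$treatment] * pct[des$interval])
  f4 <- fit_m4(build_analysis_table(d4), params_field)
  expect_equal(unname(exp(f4$treatment_log_predictions)), 100 * mult,
               tolerance = 1e-6)

  # M5: constant counts saturate the free-factor model (flat interval effects);
  # per-trap season total is 5 * per-trap catch
  per_trap <- c(2L, 3L, 5L)
  d5 <- constant_dataset(fill = function(des) per_trap[des$treatment])
  f5 <- fit_m5(build_analysis_table(d5), params_field)
  expect_equal(unname(exp(f5$treatment_log_predictions)), 5 * per_trap,
               tolerance = 1e-6)
})

test_that("NB fitter matches the brute-force likelihood grid on a tiny fixture", {
  fx <- tiny_nb_fixture()
  f4 <- fit_m4(fx$table, fx$params)
  expect_true(f4$converged)
  d <- fx$table
  oracle <- nb_grid_oracle(
    d$abundance, as.numeric(d$treatment == 2),
    log(d$seasonal_pct) + log(d$n_traps)
  )
  expect_equal(unname(coef(f4$fit)[1]), oracle$b0, tolerance = 5e-3)
  expect_equal(unname(coef(f4$fit)[2]), oracle$b1, tolerance = 5e-3)
  expect_equal(f4$dispersion, oracle$theta, tolerance = 0.01)
})

test_that("NB fit approaches the Poisson GLM on Poisson-generated data", {
  p_pois <- simulation_params(mean_catch_t1 = 30, site_sd = 0, trap_sd = 0)
  tab <- build_analysis_table(simulate_dataset(p_pois, 9))
  f4 <- fit_m4(tab, p_pois)
  d <- tab
  d$trt <- factor(d$treatment, 1:3)
  d$off <- log(d$seasonal_pct) + log(d$n_traps)
  pois <- stats::glm(abundance ~ trt + offset(off), data = d, family = stats::poisson())
  expect_gt(f4$dispersion, 100)
  expect_lt(max(abs(coef(f4$fit) - coef(pois))), 0.01)
})

test_that("M4 and M5 season-scale contrasts agree within Monte Carlo error without loss", {
  n <- 40
  d45 <- vapply(seq_len(n), function(i) {
    tab <- build_analysis_table(simulate_dataset(params_field, derive_seed(55, i)))
    fit_contrasts(fit_m5(tab, params_field))[1] -
      fit_contrasts(fit_m4(tab, params_field))[1]
  }, numeric(1))
  expect_lt(abs(mean(d45)), 3 * sd(d45) / sqrt(n))
})

test_that("degenerate tables are reported, not silently fitted", {
  d <- simulate_dataset(params_field, 60)
  tab <- build_analysis_table(d)
  no_t2 <- tab[tab$treatment != 2, ]
  expect_error(fit_m2(no_t2, params_field), "no surviving rows")
  expect_error(fit_m4(no_t2, params_field), "no surviving rows")
  # fit_all_models converts the error into a non-converged fit
  d$lost[d$treatment == 2] <- TRUE
  class(d) <- c("trap_dataset", "data.frame")
  fits <- suppressWarnings(fit_all_models(d))
  expect_false(fits$M2_offset_normal$converged)
})
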