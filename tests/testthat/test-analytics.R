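# Growth, dose-response, sampling-plan and normalization closed forms.

test_that("doubling time reproduces the closed-form two-point identities", {
  r <- doubling_time(growth_series(c(0, 24), c(1, 2)))
  expect_equal(r$gr, log(2), tolerance = 1e-12)
  expect_equal(r$td_days, 1, tolerance = 1e-12)
  r2 <- doubling_time(growth_series(c(0, 72), c(1, 8)))
  expect_equal(r2$td_days, 1, tolerance = 1e-12)
  expect_equal(r2$gr * r2$td_days, log(2), tolerance = 1e-12)
  flat <- doubling_time(growth_series(c(0, 24, 48), c(5, 5, 5)))
  expect_identical(flat$td_days, Inf)
  expect_identical(flat$flag, "non-positive-growth")
  expect_error(doubling_time(growth_series(c(0, 24), c(1, -1))))
})

test_that("noiseless exponential series has zero log-linear residuals", {
  s <- simulate_growth_series(100, 0.6, c(0, 24, 48, 72, 96), cv_noise = 0)
  expect_equal(s$values, 100 * exp(0.6 * s$hours / 24), tolerance = 1e-12)
  r <- doubling_time(s)
  expect_equal(r$gr, 0.6, tolerance = 1e-10)
  expect_equal(max(abs(r$residuals)), 0, tolerance = 1e-10)
})

test_that("growth-rate recovery from noisy series is unbiased within 2%", {
  grs <- vapply(1:1000, function(i) {
    s <- simulate_growth_series(1000, log(2), c(0, 24, 48, 72),
                                cv_noise = 0.05, seed = 20000 + i)
    doubling_time(s)$gr
  }, 0)
  expect_lt(abs(mean(grs) - log(2)) / log(2), 0.02)
})

test_that("4PL simulator hits midpoint and asymptotes exactly", {
  expect_equal(four_param_logistic(1, 100, 0, 1, 1), 50)
  expect_equal(four_param_logistic(0, 100, 20, 1, 1), 100)
  expect_equal(four_param_logistic(1e9, 100, 0, 1, 1), 0,
               tolerance = 1e-6)
  expect_error(simulate_dose_response(10, 50, 1, 1, 1:4), "top")
  tab <- simulate_dose_response(100, 0, 1, 1,
                                c(0.1, 0.25, 0.5, 1, 2.5, 5, 10, 20))
  expect_equal(tab$response[tab$dose == 1], 50, tolerance = 1e-12)
})

test_that("noise-free 4PL round trip recovers IC50 to 1e-6 relative", {
  doses <- c(0.1, 0.25, 0.5, 1, 2.5, 5, 10, 20)   # nM titration
  tab <- simulate_dose_response(100, 0, 1, 1, doses, sd = 0)
  fit <- fit_4pl(tab)
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 1), 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-4)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  expect_equal(fit$hill_slope, 1, tolerance = 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-9)
})

test_that("4PL fit is invariant to dose-unit rescaling", {
  doses <- c(0.1, 0.25, 0.5, 1, 2.5, 5, 10, 20)
  tab <- simulate_dose_response(95, 5, 1.7, 1.4, doses, sd = 2,
                                replicates = 3, seed = 77)
  f1 <- fit_4pl(tab)
  tab2 <- tab; tab2$dose <- tab$dose * 1000
  f2 <- fit_4pl(tab2)
  expect_equal(f2$ic50 / f1$ic50, 1000, tolerance = 1e-6)
  expect_equal(f2$hill_slope, f1$hill_slope, tolerance = 1e-6)
  expect_equal(f2$top, f1$top, tolerance = 1e-6)
  expect_equal(f2$bottom, f1$bottom, tolerance = 1e-6)
})

test_that("sample plan follows the SD/sqrt(n) closed form", {
  expect_equal(sample_plan(rep(42, 12), 100, 1)$n_fields, 1)
  set.seed(31)
  vals <- stats::rnorm(400, 50, 7)
  vals <- 50 + (vals - mean(vals)) * 7 / stats::sd(vals)  # exact SD 7
  sp <- sample_plan(vals, 100, 1, target_sd = 5)
  # closed form: smallest n with 7/sqrt(n) < 5 is n = 2
  expect_lte(abs(sp$n_fields - 2), 1)
  expect_equal(sp$fraction_of_area, sp$n_fields / 100, tolerance = 1e-12)
  un <- sample_plan(vals, 100, 1, target_sd = 1e-4, max_fields = 20)
  expect_identical(un$flag, "unattainable")
})

test_that("normalize_to_max scales to percentages and rejects bad input", {
  expect_equal(normalize_to_max(c(1, 2, 4)), c(25, 50, 100))
  expect_equal(normalize_to_max(7), 100)
  expect_error(normalize_to_max(c(-1, 2)), "non-negative")
  expect_error(normalize_to_max(c(0, 0)), "zero")
})
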