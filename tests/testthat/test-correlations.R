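test_that("fit_dimensional recovers exact-law coefficients", {
  sm <- exact_dimensional_summaries()
  fit <- suppressWarnings(fit_dimensional(sm))
  expect_equal(fit$coefficients$a0, -1.2220, tolerance = 1e-8)
  expect_equal(fit$coefficients$a1, 0.0067, tolerance = 1e-8)
  expect_equal(fit$coefficients$a2, -8.2069e-5, tolerance = 1e-8)
  expect_equal(fit$coefficients$kappa, 0.9830, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # round-trip through predict_dispersion
  expect_equal(predict_dispersion(fit, frequency = sm$frequency,
                                  urms = sm$urms),
               sm$d_exp, tolerance = 1e-8)
})

test_that("the velocity exponent kappa is invariant to a urms unit rescale", {
  sm <- exact_dimensional_summaries()
  sm2 <- sm
  sm2$urms <- sm$urms * 100   # e.g. cm/s -> 10 um/s: only a0 absorbs it
  f1 <- suppressWarnings(fit_dimensional(sm))
  f2 <- suppressWarnings(fit_dimensional(sm2))
  expect_equal(f2$coefficients$kappa, f1$coefficients$kappa, tolerance = 1e-8)
  expect_equal(f2$coefficients$a1, f1$coefficients$a1, tolerance = 1e-8)
  expect_equal(f2$coefficients$a0,
               f1$coefficients$a0 - f1$coefficients$kappa * 2,
               tolerance = 1e-8)
})

test_that("fit_dimensionless recovers exact-law coefficients", {
  sm <- exact_dimensionless_summaries()
  fit <- suppressWarnings(fit_dimensionless(sm))
  expect_equal(fit$coefficients$phi0, 0.4697, tolerance = 1e-8)
  expect_equal(fit$coefficients$phi1, -0.3977, tolerance = 1e-8)
  expect_equal(fit$coefficients$phi2, -1.2663, tolerance = 1e-8)
  expect_equal(fit$coefficients$K, 0.9873, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(predict_dispersion(fit, alpha = sm$alpha, pe = sm$pe),
               sm$d_exp, tolerance = 1e-8)
})

test_that("fit_scale recovers the quadratic and its vertex", {
  sm <- exact_scale_summaries()
  fit <- suppressWarnings(fit_scale(sm))
  expect_equal(fit$coefficients$lambda0, -5477e3, tolerance = 1e-8)
  expect_equal(fit$coefficients$lambda1, 1580e3, tolerance = 1e-8)
  expect_equal(fit$coefficients$lambda2, -84.09e3, tolerance = 1e-8)
  expect_lt(fit$coefficients$lambda2, 0)
  expect_equal(scale_law_maximum(fit), 1580e3 / (2 * 84.09e3),
               tolerance = 1e-6)
  expect_equal(scale_law_maximum(fit), 9.394696, tolerance = 1e-6)
})

test_that("fit_ccv recovers exact linear laws and their evaluations", {
  f <- seq(40, 130, by = 10)
  sm <- experiment_summary(data.frame(frequency = f,
                                      ccv = 0.0018 * f + 0.2144))
  fit <- suppressWarnings(fit_ccv(sm, "frequency"))
  expect_equal(fit$coefficients$a, 0.0018, tolerance = 1e-10)
  expect_equal(fit$coefficients$b, 0.2144, tolerance = 1e-10)
  expect_equal(predict_dispersion(fit, frequency = 72), 0.344,
               tolerance = 1e-3)

  u <- seq(1, 12)
  smu <- experiment_summary(data.frame(urms = u, ccv = 0.0046 * u + 0.2650))
  fitu <- suppressWarnings(fit_ccv(smu, "urms"))
  expect_equal(predict_dispersion(fitu, urms = 10), 0.311, tolerance = 1e-3)
})

test_that("published CCV coefficient evaluations match the reference values", {
  co_f <- ccv_coefficients("frequency")
  expect_equal(co_f$a * 72 + co_f$b, 0.344, tolerance = 1e-4)
  co_u <- ccv_coefficients("urms")
  expect_equal(co_u$a * 10 + co_u$b, 0.311, tolerance = 1e-4)
})

test_that("correlation fitting validates its inputs", {
  sm <- exact_dimensional_summaries(n = 4)
  expect_error(fit_dimensional(sm), "at least 5")
  expect_error(fit_dimensional(experiment_summary(
    data.frame(frequency = 1:6, d_exp = 1:6))), "missing columns")
  bad <- exact_dimensionless_summaries()
  bad$d_exp[1] <- 1e-9   # below D0
  expect_error(fit_dimensionless(bad), "d_exp > D0")
  const <- experiment_summary(data.frame(frequency = rep(60, 5),
                                         ccv = c(0.3, 0.4, 0.2, 0.35, 0.3)))
  expect_error(fit_ccv(const, "frequency"), "identical")
  # collinear design is reported, not silently dropped
  coll <- exact_dimensional_summaries()
  coll$frequency <- 60
  expect_error(suppressWarnings(fit_dimensional(coll)), "collinear")
  expect_error(experiment_summary(data.frame(d_exp = -1)), "negative")
})

test_that("summarise_cohort assembles one summary row per run", {
  g <- coarse_grid()
  cohort <- generate_cohort(c(60, 100), 1.0, noise = NULL, seed = 2,
                            grid = g, drift_velocity = 0)
  sm <- summarise_cohort(cohort, method = "MIP")
  expect_s3_class(sm, "experiment_summary")
  expect_equal(nrow(sm), 2L)
  expect_true(all(c("frequency", "urms", "alpha", "pe", "eps_amp",
                    "d_exp", "d_true", "ccv") %in% names(sm)))
  # noise- and drift-free estimates sit close to the ground truth
  expect_lt(max(abs(sm$d_exp - sm$d_true) / sm$d_true), 0.05)
})
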