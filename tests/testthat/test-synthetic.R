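test_that("the generator is deterministic for a fixed seed", {
  g <- coarse_grid()
  r1 <- simulate_tracer_experiment(D_true = 7.4, seed = 11, grid = g)
  r2 <- simulate_tracer_experiment(D_true = 7.4, seed = 11, grid = g)
  expect_identical(r1$intensities, r2$intensities)
  r3 <- simulate_tracer_experiment(D_true = 7.4, seed = 12, grid = g)
  expect_false(identical(r1$intensities, r3$intensities))
})

test_that("the injected mass is fully accounted for in every frame", {
  g <- coarse_grid()
  rec <- simulate_tracer_experiment(experiment_protocol(injection_volume = 2),
                                    D_true = 7.4, drift_velocity = 0.34,
                                    noise = NULL, grid = g)
  masses <- rowSums(rec$intensities) * g$dx
  expect_true(all(abs(masses - 2) < 1e-10))
})

test_that("the noise-free centroid drifts at the imposed velocity", {
  # wide symmetric domain so that neither wall is reached within 10 min
  g <- wide_grid()
  rec <- simulate_tracer_experiment(experiment_protocol(), D_true = 2,
                                    drift_velocity = 0.34, noise = NULL,
                                    grid = g)
  ms <- moment_series(rec)
  ccv <- caudocranial_velocity(ms)
  expect_lt(abs(ccv$ccv_cm_min - 0.34) / 0.34, 0.02)
})

test_that("the drift-free generator reduces bit-identically to the solver", {
  g <- coarse_grid()
  rec <- simulate_tracer_experiment(experiment_protocol(), D_true = 5,
                                    drift_velocity = 0, noise = NULL,
                                    grid = g)
  ic <- concentration_field(g, 0, rec$intensities[1, ])
  sol <- solve_diffusion(ic, D = 5, output_times = rec$times[-1])
  expect_identical(unname(rec$intensities[-1, ]), unname(sol$values))
})

test_that("noise residuals scale linearly with the noise amplitude", {
  g <- coarse_grid()
  clean <- simulate_tracer_experiment(D_true = 7.4, noise = NULL, grid = g)
  n1 <- simulate_tracer_experiment(D_true = 7.4,
                                   noise = noise_spec(0.02, 0.01),
                                   seed = 7, grid = g)
  n2 <- simulate_tracer_experiment(D_true = 7.4,
                                   noise = noise_spec(0.04, 0.02),
                                   seed = 7, grid = g)
  r1 <- n1$intensities - clean$intensities
  r2 <- n2$intensities - clean$intensities
  # identical seed draws the same standard normals, so before clipping the
  # residuals double exactly; zero-clipping perturbs the ratio slightly
  ratio <- stats::sd(r2) / stats::sd(r1)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("cohort ground truth follows the dimensional law", {
  g <- coarse_grid()
  ct <- physiology_constants()
  cohort <- generate_cohort(72, 1.0, noise = NULL, seed = 3, grid = g,
                            constants = ct)
  expect_length(cohort, 1L)
  st <- csf_state(72, 1.0, ct)
  expect_equal(cohort[[1]]$D_true,
               10^(-1.2220 + 0.0067 * 72 - 8.2069e-5 * 72^2 +
                     0.9830 * log10(st$urms)),
               tolerance = 1e-12)
  expect_equal(cohort[[1]]$record$metadata$frequency_bpm, 72)
})

test_that("nerve_root_factor multiplies the cohort dispersion coefficient", {
  g <- coarse_grid()
  base <- generate_cohort(72, 1.0, noise = NULL, seed = 3, grid = g)
  roots <- generate_cohort(72, 1.0, noise = NULL, seed = 3, grid = g,
                           nerve_root_factor = 4.211)
  expect_equal(roots[[1]]$D_true / base[[1]]$D_true, 4.211,
               tolerance = 1e-12)
})

test_that("cohorts are reproducible and runs use distinct derived seeds", {
  g <- coarse_grid()
  c1 <- generate_cohort(c(60, 100), 1.0, seed = 5, grid = g)
  c2 <- generate_cohort(c(60, 100), 1.0, seed = 5, grid = g)
  expect_identical(c1[[1]]$record$intensities, c2[[1]]$record$intensities)
  expect_identical(c1[[2]]$record$intensities, c2[[2]]$record$intensities)
  expect_equal(c1[[1]]$record$metadata$seed, 6)
  expect_equal(c1[[2]]$record$metadata$seed, 7)
})

test_that("default drift follows the frequency CCV law", {
  g <- coarse_grid()
  cohort <- generate_cohort(72, 1.0, noise = NULL, seed = 3, grid = g)
  expect_equal(cohort[[1]]$record$metadata$drift,
               0.0018 * 72 + 0.2144, tolerance = 1e-12)
})

test_that("generator input validation", {
  expect_error(simulate_tracer_experiment(D_true = -1, noise = NULL),
               "D_true")
  expect_error(simulate_tracer_experiment(D_true = 1), "seed")
  expect_error(noise_spec(-0.1, 0), ">= 0")
})
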