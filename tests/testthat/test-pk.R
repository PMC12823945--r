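test_that("mass_transfer_flux implements the two-film form", {
  expect_equal(mass_transfer_flux(2, 1, 0.5, 1), 0.5)
  # equilibrium: flux vanishes when c_source = K * c_sink
  expect_equal(mass_transfer_flux(3, 1.5, 0.7, 2), 0)
  # sign reverses across equilibrium
  expect_lt(mass_transfer_flux(1, 2, 0.5, 1), 0)
  expect_error(mass_transfer_flux(1, 1, -0.5, 1), ">= 0")
})

test_that("with couplings off the PK model reduces exactly to the solver", {
  g <- coarse_grid()
  c0 <- gaussian_profile(g, 0, 1.5, mass = 2)
  params <- pk_parameters(Deff = 5)
  traj <- simulate_pk(params, grid = g, output_times = 1:5,
                      initial = concentration_field(g, 0, c0))
  sol <- solve_diffusion(concentration_field(g, 0, c0), D = 5,
                         output_times = 1:5)
  expect_identical(unname(traj$c1), unname(sol$values))
})

test_that("closed-system mass balance closes to solver precision", {
  g <- coarse_grid()
  params <- pk_parameters(Deff = 3, k1 = 0.05, sigma12 = 0.2, K12 = 1.5,
                          sigma15 = 0.03,
                          lumped_transfer = list(sigma13 = 0.1, sigma34 = 0.05,
                                                 sigma35 = 0.02, sigma56 = 0.1),
                          clearance = c(c5 = 0.04))
  dose <- dose_event(start_time = 0, duration = 1, rate = 2,
                     concentration = 1)
  traj <- simulate_pk(params, list(dose), grid = g, output_times = 0:10)
  rep <- mass_balance_report(traj)
  expect_equal(rep$injected[11], 2, tolerance = 1e-12)
  expect_lt(max(abs(rep$residual_rel[-1])), 1e-10)
})

test_that("partition equilibrium between CSF and tissue satisfies c1 = K c2", {
  g <- coarse_grid()
  c0 <- gaussian_profile(g, 0, 2, mass = 2)
  run_to_eq <- function(K12) {
    params <- pk_parameters(Deff = 0, sigma12 = 5, K12 = K12)
    simulate_pk(params, grid = g, output_times = c(1, 400),
                initial = concentration_field(g, 0, c0), dt_split = 0.5)
  }
  tr <- run_to_eq(2)
  live <- tr$c2[2, ] > 1e-8
  expect_equal(tr$c1[2, live] / tr$c2[2, live], rep(2, sum(live)),
               tolerance = 1e-6)
  tr1 <- run_to_eq(1)
  live1 <- tr1$c2[2, ] > 1e-8
  expect_equal(tr1$c1[2, live1], tr1$c2[2, live1], tolerance = 1e-6)
})

test_that("first-order loss matches the analytic exponential decay", {
  g <- coarse_grid()
  c0 <- gaussian_profile(g, 0, 2, mass = 1)
  params <- pk_parameters(Deff = 2, k1 = 0.3)
  traj <- simulate_pk(params, grid = g, output_times = c(2, 5, 10),
                      initial = concentration_field(g, 0, c0),
                      dt_split = 0.001)
  rep <- mass_balance_report(traj)
  a0 <- 2   # unit concentration mass times csf_area = 2
  for (i in seq_along(traj$times)) {
    expected <- a0 * exp(-0.3 * traj$times[i])
    expect_lt(abs(rep$a1[i] - expected) / expected, 1e-3)
  }
  # degraded sink absorbs exactly what C1 loses
  expect_lt(max(abs(rep$a1 + rep$degraded - a0)), 1e-10)
})

test_that("a one-way leak to blood is monotone and conservative", {
  g <- coarse_grid()
  c0 <- gaussian_profile(g, 0, 2, mass = 1)
  params <- pk_parameters(Deff = 1, sigma15 = 0.1, K15 = 0)  # no back-flux
  traj <- simulate_pk(params, grid = g, output_times = 0:10,
                      initial = concentration_field(g, 0, c0))
  rep <- mass_balance_report(traj)
  expect_true(all(diff(rep$a1) < 0))       # CSF amount strictly decreasing
  expect_true(all(diff(rep$a5) > 0))       # blood amount strictly increasing
  tot <- rep$a1 + rep$a2 + rep$a3 + rep$a4 + rep$a5 + rep$a6 + rep$degraded
  expect_lt(max(abs(tot - tot[1])), 1e-10)
})

test_that("moment_comparison is zero against the matching record", {
  g <- coarse_grid()
  rec <- simulate_tracer_experiment(experiment_protocol(), D_true = 5,
                                    drift_velocity = 0, noise = NULL,
                                    grid = g)
  ic <- concentration_field(g, 0, rec$intensities[1, ])
  traj <- simulate_pk(pk_parameters(Deff = 5), grid = g,
                      output_times = rec$times[-1], initial = ic)
  # same stepping as the generator, so the moments agree exactly
  cmp <- moment_comparison(traj, rec)
  expect_lt(cmp$rms[["m1"]], 1e-10)
  expect_lt(cmp$rms[["m2_left"]], 1e-10)

  # a mismatched Deff produces a visibly larger moment discrepancy
  traj2 <- simulate_pk(pk_parameters(Deff = 10), grid = g,
                       output_times = rec$times[-1], initial = ic)
  cmp2 <- moment_comparison(traj2, rec)
  expect_gt(cmp2$rms[["m2_left"]], 1)
})

test_that("pk input validation", {
  expect_error(pk_parameters(Deff = -1), ">= 0")
  expect_error(pk_parameters(Deff = 1, csf_area = 0), "> 0")
  expect_error(dose_event(0, -1, 1, 1), "duration")
  g <- coarse_grid()
  expect_error(simulate_pk(pk_parameters(Deff = 1), grid = g,
                           output_times = c(2, 1)), "increasing")
})
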