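# Shared fixtures: coarse grids and exact-law synthetic summaries keep the
# unit tests fast; the acceptance tests use the full default resolution.

coarse_grid <- function() build_grid(-6, 59, 260)   # 0.25 cm cells

wide_grid <- function() build_grid(-30, 30, 300)    # symmetric, 0.2 cm cells

gaussian_profile <- function(grid, mean = 0, sd = 2, mass = 1) {
  v <- stats::dnorm(grid$centers, mean, sd)
  mass * v / (sum(v) * grid$dx)
}

# Summaries generated exactly from the dimensional law.
exact_dimensional_summaries <- function(n = 26, coefficients = dispersion_coefficients(),
                                        seed = 1) {
  set.seed(seed)
  f <- stats::runif(n, 40, 127)
  u <- stats::runif(n, 0.3, 3)
  experiment_summary(data.frame(frequency = f, urms = u,
                                d_exp = dimensional_law(f, u, coefficients)))
}

# Summaries generated exactly from the dimensionless Womersley/Peclet law.
# Alpha and Pe ranges keep log10(DeltaD) in a floating-point-friendly band.
exact_dimensionless_summaries <- function(n = 26, D0 = 1.938e-6, seed = 1) {
  set.seed(seed)
  alpha <- stats::runif(n, 0.3, 1.5)
  pe <- 10^stats::runif(n, 2, 5)
  dd <- 10^(0.4697 - 0.3977 * alpha - 1.2663 * alpha^2 +
              0.9873 * log10(pe))
  experiment_summary(data.frame(alpha = alpha, pe = pe, d_exp = D0 * (1 + dd)))
}

# Summaries generated exactly from the scale-analysis law (positive lambda
# requires alpha between the quadratic's roots, about 4.6 to 14.2).
exact_scale_summaries <- function(n = 26, D0 = 1.938e-6, seed = 1) {
  set.seed(seed)
  alpha <- stats::runif(n, 5, 14)
  eps <- 10^stats::runif(n, -4, -2)
  lam <- -5477e3 + 1580e3 * alpha - 84.09e3 * alpha^2
  experiment_summary(data.frame(alpha = alpha, eps_amp = eps,
                                d_exp = D0 * eps * lam))
}
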