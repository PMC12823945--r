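#' Experiment summary table
#'
#' Validates and normalizes a per-experiment summary table for correlation
#' fitting. Columns (units): `frequency` (bpm), `stroke_volume` (mL/beat),
#' `urms` (cm/s), `alpha` (Womersley number), `pe` (Peclet number),
#' `eps_amp` (amplitude ratio), `d_exp` (measured effective dispersion,
#' cm^2/min), `ccv` (caudocranial velocity, cm/min, optional). Only the
#' columns needed by a given fit are required.
#'
#' @param df A data frame with a subset of the columns above.
#' @return The validated data frame, class `experiment_summary`.
#' @export
experiment_summary <- function(df) {
  df <- as.data.frame(df)
  known <- c("frequency", "stroke_volume", "urms", "alpha", "pe",
             "eps_amp", "d_exp", "ccv")
  for (col in intersect(known, names(df))) {
    v <- df[[col]]
    if (any(!is.na(v) & v < 0)) stop("column '", col, "' has negative values")
  }
  class(df) <- c("experiment_summary", "data.frame")
  df
}

#' Summarise a synthetic cohort for correlation fitting
#'
#' Runs the moment analysis and dispersion estimation on every record of a
#' [generate_cohort()] result and assembles the [experiment_summary()] table.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param method `"MIP"` (default) or `"MoM"`.
#' @param roi Analysis window passed to the estimators.
#' @return An `experiment_summary` data frame, one row per run, including
#'   `d_true` for reference.
#' @export
summarise_cohort <- function(cohort, method = c("MIP", "MoM"), roi = NULL) {
  method <- match.arg(method)
  rows <- lapply(cohort, function(run) {
    est <- if (method == "MIP") mip_estimate(run$record, roi = roi)
    else mom_estimate(run$record, roi = roi)
    ccv <- caudocranial_velocity(moment_series(run$record, roi = roi))
    data.frame(frequency = run$state$frequency,
               stroke_volume = run$state$stroke_volume,
               urms = run$state$urms, alpha = run$state$alpha,
               pe = run$state$pe, eps_amp = run$state$eps_amp,
               d_exp = est$D, d_true = run$D_true,
               ccv = ccv$ccv_cm_min)
  })
  experiment_summary(do.call(rbind, rows))
}

new_correlation_fit <- function(model, coefficients, r_squared, n, lm_fit) {
  structure(list(model = model, coefficients = coefficients,
                 r_squared = r_squared, n = n, lm_fit = lm_fit),
            class = "correlation_fit")
}

#' @export
print.correlation_fit <- function(x, ...) {
  cat(sprintf("<correlation_fit> model '%s' (n = %d, R^2 = %.4f)\n",
              x$model, x$n, x$r_squared))
  print(unlist(x$coefficients))
  invisible(x)
}

check_rank <- function(fit, names) {
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("rank-deficient design: collinear regressors ",
         paste(names[is.na(co)], collapse = ", "))
  co
}

#' Fit the dimensional dispersion correlation
#'
#' OLS fit of `log10 D_exp = a0 + a1 f + a2 f^2 + kappa log10 Urms`: a
#' power-law dependence on pulsation amplitude (RMS velocity) with a
#' quadratic frequency offset, estimated simultaneously by linear regression
#' on the logarithmic form.
#'
#' @param summaries An [experiment_summary()] with `frequency`, `urms`,
#'   `d_exp`; at least 5 experiments with distinct conditions.
#' @return A `correlation_fit` with coefficients `a0`, `a1`, `a2`, `kappa`.
#' @export
fit_dimensional <- function(summaries) {
  need_cols(summaries, c("frequency", "urms", "d_exp"))
  if (nrow(summaries) < 5L) stop("need at least 5 experiments")
  dat <- data.frame(y = log10(summaries$d_exp), f = summaries$frequency,
                    lu = log10(summaries$urms))
  fit <- stats::lm(y ~ f + I(f^2) + lu, data = dat)
  co <- check_rank(fit, c("a0", "a1", "a2", "kappa"))
  new_correlation_fit("dimensional",
                      list(a0 = unname(co[1L]), a1 = unname(co[2L]),
                           a2 = unname(co[3L]), kappa = unname(co[4L])),
                      summary(fit)$r.squared, nrow(summaries), fit)
}

#' Fit the dimensionless (Womersley/Peclet) dispersion correlation
#'
#' OLS fit of `log10 DeltaD = phi0 + phi1 alpha + phi2 alpha^2 + K log10 Pe`,
#' where `DeltaD = (D_exp - D0)/D0` is the dispersion enhancement over the
#' molecular baseline `D0`.
#'
#' @param summaries An [experiment_summary()] with `alpha`, `pe`, `d_exp`.
#' @param D0 Molecular baseline diffusivity (cm^2/min), default 1.938e-6.
#' @return A `correlation_fit` with coefficients `phi0`, `phi1`, `phi2`, `K`.
#' @export
fit_dimensionless <- function(summaries, D0 = 1.938e-6) {
  need_cols(summaries, c("alpha", "pe", "d_exp"))
  if (any(summaries$d_exp <= D0))
    stop("all experiments must have d_exp > D0 (DeltaD must be positive)")
  dat <- data.frame(y = log10((summaries$d_exp - D0) / D0),
                    a = summaries$alpha, lpe = log10(summaries$pe))
  fit <- stats::lm(y ~ a + I(a^2) + lpe, data = dat)
  co <- check_rank(fit, c("phi0", "phi1", "phi2", "K"))
  new_correlation_fit("dimensionless",
                      list(phi0 = unname(co[1L]), phi1 = unname(co[2L]),
                           phi2 = unname(co[3L]), K = unname(co[4L])),
                      summary(fit)$r.squared, nrow(summaries), fit)
}

#' Fit the scale-analysis dispersion correlation
#'
#' The scale-analysis law `D_exp/D0 = eps_amp * lambda(alpha)` with
#' `lambda(alpha) = lambda0 + lambda1 alpha + lambda2 alpha^2`, fitted in the
#' normalized form `chi = (D_exp/D0)/eps_amp` regressed on `[1, alpha,
#' alpha^2]`. The quadratic captures the dispersion maximum at an intermediate
#' Womersley number.
#'
#' @param summaries An [experiment_summary()] with `alpha`, `eps_amp`,
#'   `d_exp`.
#' @param D0 Molecular baseline diffusivity (cm^2/min).
#' @return A `correlation_fit` with coefficients `lambda0`, `lambda1`,
#'   `lambda2`.
#' @export
fit_scale <- function(summaries, D0 = 1.938e-6) {
  need_cols(summaries, c("alpha", "eps_amp", "d_exp"))
  if (any(summaries$eps_amp <= 0)) stop("eps_amp must be > 0 for all points")
  dat <- data.frame(chi = (summaries$d_exp / D0) / summaries$eps_amp,
                    a = summaries$alpha)
  fit <- stats::lm(chi ~ a + I(a^2), data = dat)
  co <- check_rank(fit, c("lambda0", "lambda1", "lambda2"))
  new_correlation_fit("scale",
                      list(lambda0 = unname(co[1L]), lambda1 = unname(co[2L]),
                           lambda2 = unname(co[3L])),
                      summary(fit)$r.squared, nrow(summaries), fit)
}

#' Fit a caudocranial-velocity correlation
#'
#' Simple OLS line `CCV = a x + b` with `x` either the pulsation frequency
#' (bpm) or the RMS velocity (cm/s).
#'
#' @param summaries An [experiment_summary()] with `ccv` and the chosen
#'   regressor; at least 3 experiments.
#' @param regressor `"frequency"` or `"urms"`.
#' @return A `correlation_fit` with coefficients `a`, `b`.
#' @export
fit_ccv <- function(summaries, regressor = c("frequency", "urms")) {
  regressor <- match.arg(regressor)
  need_cols(summaries, c("ccv", regressor))
  ok <- !is.na(summaries$ccv)
  if (sum(ok) < 3L) stop("need at least 3 experiments with CCV present")
  x <- summaries[[regressor]][ok]
  if (max(x) - min(x) <= 0) stop("all regressor values identical")
  fit <- stats::lm(summaries$ccv[ok] ~ x)
  co <- check_rank(fit, c("b", "a"))
  new_correlation_fit(paste0("ccv_", regressor),
                      list(a = unname(co[2L]), b = unname(co[1L])),
                      summary(fit)$r.squared, sum(ok), fit)
}

need_cols <- function(df, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("summary table is missing columns: ",
                         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Predict effective dispersion (or CCV) from a fitted correlation
#'
#' Evaluates the inverse-transformed model: powers of 10 where the fit is
#' logarithmic. Arguments must match the fitted model:
#' \describe{
#'   \item{dimensional}{`frequency` (bpm) and `urms` (cm/s) -> D (cm^2/min).}
#'   \item{dimensionless}{`alpha` and `pe` -> D (cm^2/min), via
#'     `D = D0 (1 + DeltaD)`.}
#'   \item{scale}{`alpha` and `eps_amp` -> D (cm^2/min), via
#'     `D = D0 * eps_amp * lambda(alpha)`.}
#'   \item{ccv_frequency / ccv_urms}{the regressor -> CCV (cm/min).}
#' }
#'
#' @param fit A `correlation_fit`.
#' @param frequency,urms,alpha,pe,eps_amp Model inputs as required.
#' @param D0 Baseline diffusivity for the dimensionless/scale models.
#' @return Predicted dispersion (cm^2/min) or CCV (cm/min).
#' @export
predict_dispersion <- function(fit, frequency = NULL, urms = NULL,
                               alpha = NULL, pe = NULL, eps_amp = NULL,
                               D0 = 1.938e-6) {
  stopifnot(inherits(fit, "correlation_fit"))
  co <- fit$coefficients
  switch(fit$model,
    dimensional = {
      if (is.null(frequency) || is.null(urms))
        stop("dimensional model needs 'frequency' and 'urms'")
      10^(co$a0 + co$a1 * frequency + co$a2 * frequency^2 +
            co$kappa * log10(urms))
    },
    dimensionless = {
      if (is.null(alpha) || is.null(pe))
        stop("dimensionless model needs 'alpha' and 'pe'")
      dd <- 10^(co$phi0 + co$phi1 * alpha + co$phi2 * alpha^2 +
                  co$K * log10(pe))
      D0 * (1 + dd)
    },
    scale = {
      if (is.null(alpha) || is.null(eps_amp))
        stop("scale model needs 'alpha' and 'eps_amp'")
      D0 * eps_amp * (co$lambda0 + co$lambda1 * alpha + co$lambda2 * alpha^2)
    },
    ccv_frequency = {
      if (is.null(frequency)) stop("ccv_frequency model needs 'frequency'")
      co$a * frequency + co$b
    },
    ccv_urms = {
      if (is.null(urms)) stop("ccv_urms model needs 'urms'")
      co$a * urms + co$b
    },
    stop("unknown model: ", fit$model)
  )
}

#' Womersley number at the maximum of a scale-law fit
#'
#' Vertex of the fitted quadratic `lambda(alpha)`, `alpha* = -lambda1 /
#' (2 lambda2)`; defined for negative curvature (`lambda2 < 0`), where the
#' dispersion enhancement peaks.
#'
#' @param fit A `correlation_fit` of model `"scale"`.
#' @return The Womersley number of maximal dispersion.
#' @export
scale_law_maximum <- function(fit) {
  stopifnot(inherits(fit, "correlation_fit"), fit$model == "scale")
  co <- fit$coefficients
  if (co$lambda2 >= 0) stop("fitted quadratic has no maximum (lambda2 >= 0)")
  -co$lambda1 / (2 * co$lambda2)
}
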