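# Trapezoidal quadrature on sampled positions.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1L])) / 2
}

#' First moment (centroid) of an intensity profile
#'
#' Intensity-weighted mean axial position,
#' `M1 = integral(x C dx) / integral(C dx)`, by trapezoidal integration over
#' the sampled positions. Locates the center of gravity of the tracer cloud.
#'
#' @param positions Axial positions (cm), strictly increasing.
#' @param intensities Non-negative intensities, same length as `positions`.
#' @return Centroid position (cm).
#' @examples
#' first_moment(c(0, 1, 2), c(1, 2, 3))  # 1.25
#' @export
first_moment <- function(positions, intensities) {
  check_profile(positions, intensities)
  denom <- trapz(positions, intensities)
  if (denom <= 0) stop("all-zero profile: centroid is undefined")
  trapz(positions, positions * intensities) / denom
}

#' Left-sided second moment of an intensity profile
#'
#' Second central moment restricted to positions caudal of the centroid:
#' `M2L = integral_{x <= xbar} (x - xbar)^2 C dx / integral_{x <= xbar} C dx`.
#' Used instead of the full variance because lumbar injection and the short
#' sacral compartment make tracer profiles asymmetric; the left (caudal-to-
#' centroid) side is bounded by the sacral wall last. For a symmetric
#' (Gaussian) profile the left-sided second moment equals the full variance.
#'
#' The integration cell containing `xbar` is split, with the intensity at
#' `xbar` obtained by linear interpolation.
#'
#' @inheritParams first_moment
#' @param xbar Centroid (cm); default computed by [first_moment()]. Must lie
#'   within the position range.
#' @return Left-sided second moment (cm^2).
#' @examples
#' x <- seq(-10, 10, 0.1)
#' left_second_moment(x, dnorm(x, 0, 2))  # ~ 4 (= sigma^2)
#' @export
left_second_moment <- function(positions, intensities,
                               xbar = first_moment(positions, intensities)) {
  check_profile(positions, intensities)
  if (xbar < positions[1L] || xbar > positions[length(positions)])
    stop("'xbar' lies outside the position range")
  keep <- positions < xbar
  xs <- c(positions[keep], xbar)
  cs <- c(intensities[keep],
          stats::approx(positions, intensities, xout = xbar)$y)
  denom <- trapz(xs, cs)
  if (denom <= 0) stop("zero intensity on the left side of the centroid")
  trapz(xs, (xs - xbar)^2 * cs) / denom
}

check_profile <- function(positions, intensities) {
  if (length(positions) != length(intensities))
    stop("'positions' and 'intensities' must have equal length")
  if (length(positions) < 2L) stop("need at least two samples")
  if (any(diff(positions) <= 0)) stop("'positions' must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  invisible(TRUE)
}

#' Moment time series of an intensity record
#'
#' Per-frame first moment and left-sided second moment within the analysis
#' window (region of interest). Frames whose left-of-centroid mass is below
#' `1e-6` of the frame total are excluded with a warning (early-frame
#' artifacts in noisy data).
#'
#' @param record An `intensity_record` (see [simulate_tracer_experiment()] or
#'   [read_intensity_record()]).
#' @param roi Optional `c(lower, upper)` analysis window (cm); default the
#'   full position range.
#' @param baseline_subtract If `TRUE`, subtract each frame's minimum intensity
#'   before computing moments (constant-baseline correction for uneven
#'   lighting). Default `FALSE`.
#' @return An object of class `moment_series`: a data frame with columns
#'   `time_min`, `m1_cm`, `m2_left_cm2`, `total_intensity`.
#' @export
moment_series <- function(record, roi = NULL, baseline_subtract = FALSE) {
  stopifnot(inherits(record, "intensity_record"))
  if (length(record$times) < 2L) stop("need at least two frames")
  pos <- record$positions
  if (is.null(roi)) roi <- range(pos)
  if (roi[1L] >= roi[2L]) stop("invalid ROI")
  sel <- pos >= roi[1L] & pos <= roi[2L]
  if (sum(sel) < 3L) stop("ROI contains fewer than 3 positions")
  x <- pos[sel]

  rows <- lapply(seq_along(record$times), function(i) {
    ci <- record$intensities[i, sel]
    if (baseline_subtract) ci <- pmax(ci - min(ci), 0)
    tot <- trapz(x, ci)
    if (tot <= 0) return(NULL)
    m1 <- trapz(x, x * ci) / tot
    left <- trapz(c(x[x < m1], m1),
                  c(ci[x < m1], stats::approx(x, ci, xout = m1)$y))
    if (left < 1e-6 * tot) return(NULL)
    data.frame(time_min = record$times[i], m1_cm = m1,
               m2_left_cm2 = left_second_moment(x, ci, m1),
               total_intensity = tot)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L)
    warning(sprintf("%d frame(s) with negligible ROI/left-side mass excluded",
                    dropped))
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stop("no usable frames in the record")
  structure(out, class = c("moment_series", "data.frame"),
            roi = roi)
}

#' Caudocranial velocity from a moment series
#'
#' Ordinary least-squares slope of the centroid position versus time. The
#' sign convention is positive toward the cranial direction, matching the
#' caudocranial drift of a lumbar bolus under CSF pulsation.
#'
#' @param series A `moment_series` with at least 3 time points.
#' @return A list with `ccv_cm_min` (slope), `std_error`, `r_squared`, `n`.
#' @examples
#' \dontrun{
#' ccv <- caudocranial_velocity(moment_series(record))
#' ccv$ccv_cm_min
#' }
#' @export
caudocranial_velocity <- function(series) {
  stopifnot(inherits(series, "moment_series"))
  if (nrow(series) < 3L) stop("need at least 3 time points for a slope")
  fit <- stats::lm(m1_cm ~ time_min, data = series)
  sm <- summary(fit)
  list(ccv_cm_min = unname(stats::coef(fit)[2L]),
       std_error = unname(sm$coefficients[2L, 2L]),
       r_squared = sm$r.squared,
       n = nrow(series))
}
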