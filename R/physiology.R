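#' Physiology constants for the dispersion analysis
#'
#' Default physical constants of the bench configuration: kinematic viscosity
#' of the working fluid (water at room temperature), hydraulic diameter of the
#' spinal canal, characteristic neuraxis length (CM to S3), molecular
#' diffusivity of the tracer (trypan blue) used as the dimensionless baseline,
#' and the reference CSF-occupied cross-sectional area at which stroke volume
#' is converted to velocity (CSF area at C3 of the default geometry).
#'
#' @param nu Kinematic viscosity (cm^2/s), default 0.01.
#' @param DH Hydraulic diameter (cm), default 0.5.
#' @param L Characteristic axial length (cm), default 65.
#' @param D0 Molecular (baseline) diffusivity (cm^2/min), default 1.938e-6.
#' @param A_ref Reference CSF cross-sectional area (cm^2); default the CSF
#'   area at C3 in [default_geometry()].
#' @return A named list of constants.
#' @export
physiology_constants <- function(nu = 0.01, DH = 0.5, L = 65,
                                 D0 = 1.938e-6, A_ref = NULL) {
  if (is.null(A_ref)) {
    geom <- default_geometry()
    c3 <- geom$stations[geom$stations$label == "C3", ]
    A_ref <- pi * c3$major_radius_cm * c3$minor_radius_cm *
      (1 - c3$tissue_fraction)
  }
  vals <- c(nu = nu, DH = DH, L = L, D0 = D0, A_ref = A_ref)
  if (any(vals <= 0)) stop("all physiology constants must be > 0")
  as.list(vals)
}

#' CSF pulsation state and dimensionless numbers
#'
#' Converts a cardiac-driven CSF pulsation (frequency in beats/min, stroke
#' volume in mL/beat) into the descriptors used by the dispersion
#' correlations. The volumetric waveform is taken as sinusoidal,
#' `Q(t) = Qa sin(omega t)`, whose displaced volume over a half period equals
#' the stroke volume, so `Qa = SV * omega / 2`. Then
#' \itemize{
#'   \item `omega = 2 pi f / 60` (rad/s),
#'   \item `urms = Qa / (A_ref * sqrt(2))` (cm/s), the root-mean-square bulk
#'     velocity at the reference cross-section,
#'   \item Womersley number `alpha = (DH/2) * sqrt(omega / nu)`,
#'   \item Peclet number `Pe = urms * DH / D0` (with `D0` converted to
#'     cm^2/s),
#'   \item amplitude ratio `eps_amp = urms / (omega * L)`.
#' }
#'
#' @param frequency Pulsation frequency (beats/min), in (0, 300].
#' @param stroke_volume Stroke volume (mL/beat), >= 0.
#' @param constants A list from [physiology_constants()].
#' @return An object of class `csf_state`: a named list with `frequency`,
#'   `stroke_volume`, `omega`, `A_ref`, `urms`, `alpha`, `pe`, `eps_amp`,
#'   `nu`, `L`, `D0`.
#' @examples
#' st <- csf_state(72, 1.0, physiology_constants(A_ref = 2))
#' st$omega  # 7.5398 rad/s
#' st$urms   # 1.333 cm/s
#' @export
csf_state <- function(frequency, stroke_volume,
                      constants = physiology_constants()) {
  if (!is.numeric(frequency) || frequency <= 0 || frequency > 300)
    stop("'frequency' must lie in (0, 300] beats/min")
  if (!is.numeric(stroke_volume) || stroke_volume < 0)
    stop("'stroke_volume' must be >= 0")
  omega <- 2 * pi * frequency / 60            # rad/s
  qa <- stroke_volume * omega / 2             # mL/s peak flow
  urms <- qa / (constants$A_ref * sqrt(2))    # cm/s
  alpha <- (constants$DH / 2) * sqrt(omega / constants$nu)
  d0_s <- constants$D0 / 60                   # cm^2/s
  pe <- urms * constants$DH / d0_s
  eps_amp <- urms / (omega * constants$L)
  structure(list(frequency = frequency, stroke_volume = stroke_volume,
                 omega = omega, A_ref = constants$A_ref, urms = urms,
                 alpha = alpha, pe = pe, eps_amp = eps_amp,
                 nu = constants$nu, L = constants$L, D0 = constants$D0),
            class = "csf_state")
}

#' @export
print.csf_state <- function(x, ...) {
  cat(sprintf(paste0("<csf_state> f = %g bpm, SV = %g mL/beat\n",
                     "  omega = %.4f rad/s, Urms = %.4f cm/s\n",
                     "  alpha = %.3f, Pe = %.4g, eps_amp = %.4g\n"),
              x$frequency, x$stroke_volume, x$omega, x$urms,
              x$alpha, x$pe, x$eps_amp))
  invisible(x)
}
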