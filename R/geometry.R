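#' Neuraxis geometry from station measurements
#'
#' The spinal subarachnoid space is described by a sequence of anatomical
#' stations (cisterna magna, cervical, thoracic, lumbar, sacral landmarks),
#' each with an approximately elliptical cross-section: `major_radius` (right
#' to left extent of the CSF space) and `minor_radius` (dorsal to ventral
#' extent), plus the fraction of the cross-sectional area occupied by spinal
#' tissue. The CSF-occupied area at a station is
#' `pi * major * minor * (1 - tissue_fraction)`.
#'
#' @param stations A data frame with columns `label`, `position_cm` (axial
#'   distance from the cisterna magna, strictly increasing), `major_radius_cm`,
#'   `minor_radius_cm` (> 0) and `tissue_fraction` (in `[0, 1]`).
#' @param total_length Total canal length (cm); default the last station
#'   position.
#' @param hydraulic_diameter Hydraulic diameter (cm); default 0.5.
#'
#' @return An object of class `neuraxis_geometry`.
#' @seealso [default_geometry()], [interpolate_geometry()]
#' @export
neuraxis_geometry <- function(stations, total_length = NULL,
                              hydraulic_diameter = 0.5) {
  req <- c("label", "position_cm", "major_radius_cm", "minor_radius_cm",
           "tissue_fraction")
  miss <- setdiff(req, names(stations))
  if (length(miss)) stop("stations table is missing columns: ",
                         paste(miss, collapse = ", "))
  stations <- as.data.frame(stations)[req]
  if (nrow(stations) < 2L) stop("need at least two stations")
  if (any(diff(stations$position_cm) <= 0))
    stop("station positions must be strictly increasing")
  if (any(stations$position_cm < 0)) stop("positions must be >= 0")
  if (any(stations$major_radius_cm <= 0) || any(stations$minor_radius_cm <= 0))
    stop("radii must be > 0")
  if (any(stations$tissue_fraction < 0 | stations$tissue_fraction > 1))
    stop("tissue_fraction must lie in [0, 1]")
  if (is.null(total_length))
    total_length <- stations$position_cm[nrow(stations)]
  if (total_length < stations$position_cm[nrow(stations)])
    stop("total_length must be >= the last station position")
  if (hydraulic_diameter <= 0) stop("hydraulic_diameter must be > 0")
  structure(list(stations = stations, total_length = total_length,
                 hydraulic_diameter = hydraulic_diameter),
            class = "neuraxis_geometry")
}

#' @export
print.neuraxis_geometry <- function(x, ...) {
  cat(sprintf("<neuraxis_geometry> %d stations, length %g cm, DH %g cm\n",
              nrow(x$stations), x$total_length, x$hydraulic_diameter))
  invisible(x)
}

#' Read a neuraxis geometry table from CSV
#'
#' Expected columns: `label`, `position_cm`, `major_radius_cm`,
#' `minor_radius_cm`, `tissue_fraction`.
#'
#' @param path CSV file path.
#' @inheritParams neuraxis_geometry
#' @return A `neuraxis_geometry`.
#' @export
read_geometry <- function(path, total_length = NULL, hydraulic_diameter = 0.5) {
  neuraxis_geometry(utils::read.csv(path, stringsAsFactors = FALSE),
                    total_length = total_length,
                    hydraulic_diameter = hydraulic_diameter)
}

#' Packaged default neuraxis geometry (synthetic stand-in)
#'
#' A synthetic geometry table spanning cisterna magna (0 cm) to S3 (65 cm).
#' Minor radii and cross-sectional areas at the validated landmarks CM, T2,
#' L1 and S3 match the published in-vivo diameters and areas of the reference
#' subject; intermediate stations are plausible interpolants, not measured
#' values. Suitable for exercising the pipeline, not for subject-specific
#' prediction.
#'
#' @return A `neuraxis_geometry`.
#' @export
default_geometry <- function() {
  read_geometry(system.file("extdata", "neuraxis_geometry_synthetic.csv",
                            package = "itdisp", mustWork = TRUE))
}

#' Interpolate elliptical cross-section properties along the neuraxis
#'
#' Piecewise-linear interpolation of the major radius, minor radius and
#' tissue fraction between bracketing stations; the CSF-occupied area is
#' computed from the interpolated values as
#' `pi * major * minor * (1 - tissue_fraction)`.
#'
#' @param geometry A `neuraxis_geometry`.
#' @param position Axial position(s) (cm) within the station range.
#' @return A data frame with columns `position_cm`, `major_radius_cm`,
#'   `minor_radius_cm`, `tissue_fraction`, `csf_area_cm2`.
#' @export
interpolate_geometry <- function(geometry, position) {
  stopifnot(inherits(geometry, "neuraxis_geometry"))
  st <- geometry$stations
  rng <- range(st$position_cm)
  if (any(position < rng[1L] | position > rng[2L]))
    stop(sprintf("position out of station range [%g, %g] cm", rng[1L], rng[2L]))
  a <- stats::approx(st$position_cm, st$major_radius_cm, xout = position)$y
  b <- stats::approx(st$position_cm, st$minor_radius_cm, xout = position)$y
  tf <- stats::approx(st$position_cm, st$tissue_fraction, xout = position)$y
  data.frame(position_cm = position, major_radius_cm = a,
             minor_radius_cm = b, tissue_fraction = tf,
             csf_area_cm2 = pi * a * b * (1 - tf))
}

#' Percent difference between a reference and a measured dimension
#'
#' `100 * |measured - reference| / reference`, the metric used to validate a
#' manufactured phantom cross-section (diameter or area) against the in-vivo
#' reference.
#'
#' @param reference Reference (in-vivo) value(s), > 0.
#' @param measured Measured (mold or phantom) value(s), > 0.
#' @return Percent difference(s), unrounded.
#' @examples
#' percent_difference(1.30, 1.32)  # 1.538...
#' @export
percent_difference <- function(reference, measured) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference values must be positive (invalid measurement)")
  if (any(!is.finite(measured)) || any(measured <= 0))
    stop("measured values must be positive (invalid measurement)")
  100 * abs(measured - reference) / reference
}

#' Read phantom-validation measurement pairs from CSV
#'
#' Expected columns: `label`, `quantity` (one of `"diameter"`, `"area"`),
#' `reference_value`, `measured_value`.
#'
#' @param path CSV file path.
#' @return A data frame of validation pairs.
#' @export
read_validation_pairs <- function(path) {
  pairs <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "quantity", "reference_value", "measured_value")
  miss <- setdiff(req, names(pairs))
  if (length(miss)) stop("validation table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(pairs$quantity %in% c("diameter", "area")))
    stop("quantity must be 'diameter' or 'area'")
  pairs
}

#' Packaged phantom-validation pairs (published Table of the reference study)
#'
#' In-vivo versus manufactured-phantom diameters and areas at CM, T2, L1, S3.
#'
#' @return A data frame of validation pairs.
#' @export
default_validation_pairs <- function() {
  read_validation_pairs(system.file("extdata", "spine_validation_pairs.csv",
                                    package = "itdisp", mustWork = TRUE))
}

#' Summarise phantom-geometry validation
#'
#' Per-pair percent differences and their arithmetic mean, grouped by measured
#' quantity (diameter, area).
#'
#' @param pairs A data frame as returned by [read_validation_pairs()].
#' @return A list with `pairs` (input plus a `pct_difference` column) and
#'   `summary` (data frame of `quantity`, `n`, `mean_pct_difference`).
#' @examples
#' vs <- validation_summary(default_validation_pairs())
#' vs$summary
#' @export
validation_summary <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no validation pairs supplied")
  pairs$pct_difference <- percent_difference(pairs$reference_value,
                                             pairs$measured_value)
  agg <- stats::aggregate(pct_difference ~ quantity, data = pairs, FUN = mean)
  names(agg)[2L] <- "mean_pct_difference"
  agg$n <- as.integer(table(pairs$quantity)[agg$quantity])
  list(pairs = pairs, summary = agg[c("quantity", "n", "mean_pct_difference")])
}
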