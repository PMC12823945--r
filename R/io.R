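#' Write an intensity record to CSV (with metadata sidecar)
#'
#' Long-format CSV with columns `time_min`, `x_cm`, `intensity`, plus a JSON
#' metadata sidecar (`<path minus .csv>_metadata.json`) carrying the ground
#' truth and seed when the record is synthetic.
#'
#' @param record An `intensity_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_record <- function(record, path) {
  stopifnot(inherits(record, "intensity_record"))
  df <- data.frame(
    time_min = rep(record$times, each = length(record$positions)),
    x_cm = rep(record$positions, times = length(record$times)),
    intensity = as.vector(t(record$intensities)))
  utils::write.csv(df, path, row.names = FALSE)
  if (length(record$metadata) > 0L)
    jsonlite::write_json(record$metadata, sidecar_path(path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_metadata.json")
}

#' Read an intensity record from CSV
#'
#' Validates the documented schema (`time_min`, `x_cm`, `intensity`; complete
#' time-position grid; non-negative intensities), canonically sorts rows, and
#' attaches the metadata sidecar if present. [write_intensity_record()]
#' followed by `read_intensity_record()` is a lossless round trip.
#'
#' @param path CSV path.
#' @return An `intensity_record`.
#' @export
read_intensity_record <- function(path) {
  df <- utils::read.csv(path)
  req <- c("time_min", "x_cm", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (any(df$intensity < 0))
    stop("schema error: negative intensity values")
  times <- sort(unique(df$time_min))
  positions <- sort(unique(df$x_cm))
  if (nrow(df) != length(times) * length(positions))
    stop("schema error: incomplete time x position grid")
  df <- df[order(df$time_min, df$x_cm), ]
  intens <- matrix(df$intensity, nrow = length(times),
                   ncol = length(positions), byrow = TRUE)
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  intensity_record(times, positions, intens, metadata = meta)
}

#' Write / read a moment series
#'
#' CSV columns: `time_min`, `m1_cm`, `m2_left_cm2`, `total_intensity`.
#'
#' @param series A `moment_series`.
#' @param path CSV path.
#' @return `path` (write) or a `moment_series` (read).
#' @export
write_moment_series <- function(series, path) {
  stopifnot(inherits(series, "moment_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_moment_series
#' @export
read_moment_series <- function(path) {
  df <- utils::read.csv(path)
  req <- c("time_min", "m1_cm", "m2_left_cm2", "total_intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (any(diff(df$time_min) <= 0))
    stop("schema error: non-increasing times")
  structure(df, class = c("moment_series", "data.frame"))
}

#' Write a dispersion estimate or correlation fit to JSON
#'
#' @param x A `dispersion_estimate` or `correlation_fit`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_estimate <- function(x, path) {
  obj <- if (inherits(x, "dispersion_estimate")) {
    list(D_cm2_min = x$D, method = x$method,
         objective_value = x$objective_value, n_times = x$n_times,
         converged = x$converged, diagnostics = x$diagnostics)
  } else if (inherits(x, "correlation_fit")) {
    list(model = x$model, coefficients = x$coefficients,
         r_squared = x$r_squared, n = x$n)
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write / read an experiment summary table
#'
#' @param summaries An `experiment_summary`.
#' @param path CSV path.
#' @return `path` (write) or an `experiment_summary` (read).
#' @export
write_experiment_summary <- function(summaries, path) {
  utils::write.csv(as.data.frame(summaries), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_experiment_summary
#' @export
read_experiment_summary <- function(path) {
  experiment_summary(utils::read.csv(path))
}
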