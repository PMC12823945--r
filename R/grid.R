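#' Build a uniform one-dimensional finite-volume grid
#'
#' Cell-centered uniform grid for the axial (neuraxis) coordinate. Positions
#' are in cm, with the lumbar injection site conventionally at `x = 0`, the
#' sacral end of the dural sac at negative `x` and the cranial direction at
#' positive `x`.
#'
#' @param x0 Lower domain bound (cm), typically the sacral end (default -6).
#' @param xm Upper domain bound (cm), typically the cranial extent (default 59).
#' @param n_cells Number of finite-volume cells (>= 3).
#'
#' @return An object of class `grid1d`: a list with elements `x0`, `xm`,
#'   `n_cells`, `dx` (uniform cell width, cm) and `centers` (cell-center
#'   coordinates, cm).
#'
#' @examples
#' g <- build_grid(-6, 59, 650)
#' g$dx           # 0.1 cm
#' head(g$centers)
#' @export
build_grid <- function(x0 = -6, xm = 59, n_cells = 650) {
  if (!is.numeric(x0) || !is.numeric(xm) || length(x0) != 1L || length(xm) != 1L)
    stop("'x0' and 'xm' must be single numeric values")
  if (xm <= x0) stop("'xm' must be strictly greater than 'x0'")
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 3L) stop("'n_cells' must be an integer >= 3")
  dx <- (xm - x0) / n_cells
  structure(
    list(x0 = x0, xm = xm, n_cells = n_cells, dx = dx,
         centers = x0 + (seq_len(n_cells) - 0.5) * dx),
    class = "grid1d"
  )
}

#' @export
print.grid1d <- function(x, ...) {
  cat(sprintf("<grid1d> [%g, %g] cm, %d cells, dx = %g cm\n",
              x$x0, x$xm, x$n_cells, x$dx))
  invisible(x)
}

# Reconstruct a grid1d from a vector of (assumed cell-center) positions.
# Used when a record arrives as a table rather than with an explicit grid.
grid_from_positions <- function(positions) {
  positions <- sort(unique(positions))
  if (length(positions) < 3L) stop("need at least 3 positions to infer a grid")
  dx <- diff(positions)
  if (max(dx) - min(dx) > 1e-8 * mean(dx))
    stop("positions are not uniformly spaced; supply an explicit grid")
  dx <- mean(dx)
  build_grid(positions[1L] - dx / 2, positions[length(positions)] + dx / 2,
             length(positions))
}
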