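# Detector-array layouts and the mapping between reconstruction-grid
# indices and physical detector positions.
#
# Coordinate conventions used throughout the package:
#   * (x, y) are CAX-centred physical coordinates in cm at the detector
#     plane (100 cm source-to-detector distance); +x is lateral, +y is
#     longitudinal (toward the gantry).
#   * Grid indices (X, Y) are signed integers with (0, 0) at the CAX; one
#     unit corresponds to the array shifting step, which must be an
#     integer multiple of the detector spacing.
#   * "Shifting the array left by one step" places detector X under beam
#     position X - 1, i.e. a measurement shifted by s steps samples the
#     beam at (X + s).
#   * Detectors that do not physically exist (corner triangles, staggered
#     row ends) are carried as NA everywhere, never as zeros.

#' Construct a detector-array geometry
#'
#' @param n_rows,n_cols number of detector rows and columns.
#' @param col_spacing_cm lateral spacing between detectors in a row (cm).
#' @param row_spacing_cm longitudinal spacing between rows (cm).
#' @param row_stagger_cm lateral offset applied to every other row (cm);
#'   rows at an odd row-distance from the origin row are offset by this
#'   amount.
#' @param mask logical matrix of dimension `n_rows` x `n_cols`; `TRUE`
#'   where a physical detector exists.  Defaults to all `TRUE`.
#' @param origin_index integer `(row, col)` of the detector that sits on
#'   the beam central axis when the array is unshifted.
#' @param row_offset_cm optional numeric vector (length `n_rows`) of
#'   per-row lateral offsets; overrides the stagger rule when given.
#' @param layout short label ("custom", "grid", "mapcheck2").
#'
#' @return An object of class `array_geometry`.
#' @export
array_geometry <- function(n_rows, n_cols, col_spacing_cm, row_spacing_cm,
                           row_stagger_cm = 0, mask = NULL,
                           origin_index = NULL, row_offset_cm = NULL,
                           layout = "custom") {
  if (n_rows < 1 || n_cols < 1)
    stop("array_geometry: n_rows and n_cols must be positive")
  if (col_spacing_cm <= 0 || row_spacing_cm <= 0)
    stop("array_geometry: detector spacings must be positive")
  if (is.null(mask)) mask <- matrix(TRUE, n_rows, n_cols)
  if (!is.logical(mask) || !all(dim(mask) == c(n_rows, n_cols)))
    stop("array_geometry: mask must be a logical n_rows x n_cols matrix")
  if (is.null(origin_index))
    origin_index <- c((n_rows + 1L) %/% 2L, (n_cols + 1L) %/% 2L)
  origin_index <- as.integer(origin_index)
  if (is.null(row_offset_cm)) {
    row_offset_cm <- ifelse((seq_len(n_rows) - origin_index[1L]) %% 2L == 0L,
                            0, row_stagger_cm)
  }
  if (length(row_offset_cm) != n_rows)
    stop("array_geometry: row_offset_cm must have one entry per row")
  if (!mask[origin_index[1L], origin_index[2L]])
    stop("array_geometry: the origin detector must exist (unmasked)")
  if (row_offset_cm[origin_index[1L]] != 0)
    stop("array_geometry: the origin row must have zero lateral offset")
  geom <- structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         col_spacing_cm = col_spacing_cm, row_spacing_cm = row_spacing_cm,
         row_stagger_cm = row_stagger_cm, mask = mask,
         origin_index = origin_index, row_offset_cm = row_offset_cm,
         layout = layout),
    class = "array_geometry")
  pos <- detector_positions(geom)
  if (anyDuplicated(round(cbind(pos$x, pos$y), 9)))
    stop("array_geometry: detector positions are not unique")
  geom
}

#' Regular rectangular detector grid
#'
#' A plain unstaggered, unmasked layout with equal lateral and
#' longitudinal spacing, mostly used for simulation studies and tests.
#' Dimensions must be odd so a central detector sits on the CAX.
#'
#' @param n_rows,n_cols odd integers >= 3.
#' @param spacing_cm detector spacing (cm), > 0.
#' @return An `array_geometry`.
#' @examples
#' g <- build_grid_geometry(5, 5, 1)
#' range(detector_positions(g)$x)
#' @export
build_grid_geometry <- function(n_rows, n_cols, spacing_cm) {
  if (n_rows < 3 || n_cols < 3 || n_rows %% 2 == 0 || n_cols %% 2 == 0)
    stop("build_grid_geometry: n_rows and n_cols must be odd and >= 3 ",
         "so that a central detector exists")
  if (spacing_cm <= 0)
    stop("build_grid_geometry: spacing_cm must be positive")
  array_geometry(n_rows, n_cols,
                 col_spacing_cm = spacing_cm, row_spacing_cm = spacing_cm,
                 layout = "grid")
}

#' MapCHECK2-style staggered diode layout
#'
#' Staggered layout with 1 cm lateral detector spacing, 0.5 cm row
#' interval and a 0.5 cm alternating-row lateral shift (nearest diagonal
#' neighbours about 0.7 cm apart).  Rows span 26 cm laterally and the 65
#' rows span 32 cm longitudinally; the four 7x7 cm2 corner triangles hold
#' no detectors.  The subset of detectors on integer-cm positions forms
#' the 1 cm reconstruction grid (x in -13..13, y in -16..16).
#'
#' @param origin_index optional `(row, col)` override for the detector
#'   taken to coincide with the array centre; it must lie on an
#'   unstaggered row.
#' @return An `array_geometry` with layout `"mapcheck2"`.
#' @export
build_mapcheck2_geometry <- function(origin_index = NULL) {
  n_rows <- 65L; n_cols <- 27L
  if (is.null(origin_index)) origin_index <- c(33L, 14L)
  origin_index <- as.integer(origin_index)
  rows <- seq_len(n_rows); cols <- seq_len(n_cols)
  offset <- ifelse((rows - origin_index[1L]) %% 2L == 0L, 0, 0.5)
  x <- outer(offset, cols - origin_index[2L], function(o, c) c * 1.0 + o)
  y <- matrix((rows - origin_index[1L]) * 0.5, n_rows, n_cols)
  half_x <- 13; half_y <- 16
  mask <- abs(x) <= half_x + 1e-9 & abs(y) <= half_y + 1e-9
  # 7x7 corner triangles: masked where the taxicab distance to the corner
  # along the two edges is below 7 cm
  mask <- mask & ((half_x - abs(x)) + (half_y - abs(y)) >= 7 - 1e-9)
  array_geometry(n_rows, n_cols, col_spacing_cm = 1, row_spacing_cm = 0.5,
                 row_stagger_cm = 0.5, mask = mask,
                 origin_index = origin_index, row_offset_cm = offset,
                 layout = "mapcheck2")
}

#' Physical positions of the (possibly shifted) detectors
#'
#' @param geometry an `array_geometry`.
#' @param shift_x_cm,shift_y_cm array translation in cm; a detector at
#'   unshifted position (x, y) moves to (x + shift_x, y + shift_y)
#'   relative to the beam CAX.
#' @return A data frame with columns `row`, `col`, `x`, `y` for every
#'   physical (unmasked) detector.
#' @export
detector_positions <- function(geometry, shift_x_cm = 0, shift_y_cm = 0) {
  stopifnot(inherits(geometry, "array_geometry"))
  idx <- which(geometry$mask, arr.ind = TRUE)
  rw <- idx[, 1L]; cl <- idx[, 2L]
  x <- (cl - geometry$origin_index[2L]) * geometry$col_spacing_cm +
    geometry$row_offset_cm[rw] + shift_x_cm
  y <- (rw - geometry$origin_index[1L]) * geometry$row_spacing_cm + shift_y_cm
  out <- data.frame(row = rw, col = cl, x = x, y = y)
  out[order(out$row, out$col), , drop = FALSE]
}

#' Reconstruction-grid specification
#'
#' One grid unit corresponds to the array shifting distance, which must
#' be a positive integer multiple of the detector spacing; index 0 lies
#' on the CAX.
#'
#' @param step_x_cm,step_y_cm grid step (cm) along each axis.
#' @param x_range,y_range inclusive integer index ranges, each containing 0.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(step_x_cm, step_y_cm, x_range, y_range) {
  if (step_x_cm <= 0 || step_y_cm <= 0)
    stop("grid_spec: steps must be positive")
  x_range <- as.integer(x_range); y_range <- as.integer(y_range)
  if (x_range[1L] > 0 || x_range[2L] < 0 || y_range[1L] > 0 || y_range[2L] < 0)
    stop("grid_spec: index ranges must include 0")
  structure(list(step_x_cm = step_x_cm, step_y_cm = step_y_cm,
                 x_range = x_range, y_range = y_range),
            class = "grid_spec")
}

grid_x_index <- function(grid) grid$x_range[1L]:grid$x_range[2L]
grid_y_index <- function(grid) grid$y_range[1L]:grid$y_range[2L]

#' Default reconstruction grid for a geometry
#'
#' The largest grid of `step_cm` spacing whose nodes coincide with
#' detectors of the unshifted array.
#'
#' @param geometry an `array_geometry`.
#' @param step_x_cm,step_y_cm grid steps (cm); must be integer multiples
#'   of the corresponding detector spacing.
#' @return A `grid_spec`.
#' @export
default_grid <- function(geometry, step_x_cm = geometry$col_spacing_cm,
                         step_y_cm = NULL) {
  if (is.null(step_y_cm)) {
    # staggered layouts reconstruct on every other row (the unstaggered
    # family); regular grids use the row spacing itself
    step_y_cm <- if (geometry$row_stagger_cm != 0)
      2 * geometry$row_spacing_cm else geometry$row_spacing_cm
  }
  check_step <- function(step, spacing, what) {
    m <- step / spacing
    if (abs(m - round(m)) > 1e-9 || round(m) < 1)
      stop("default_grid: ", what,
           " step must be a positive integer multiple of the detector spacing")
  }
  check_step(step_x_cm, geometry$col_spacing_cm, "lateral")
  check_step(step_y_cm, geometry$row_spacing_cm, "longitudinal")
  pos <- detector_positions(geometry)
  on_row <- abs(pos$y %% step_y_cm) < 1e-9 | abs(pos$y %% step_y_cm - step_y_cm) < 1e-9
  on_col <- abs(pos$x %% step_x_cm) < 1e-9 | abs(pos$x %% step_x_cm - step_x_cm) < 1e-9
  p <- pos[on_row & on_col, , drop = FALSE]
  grid_spec(step_x_cm, step_y_cm,
            x_range = round(range(p$x) / step_x_cm),
            y_range = round(range(p$y) / step_y_cm))
}

# (row, col) detector index for each grid node, NA where no unmasked
# detector sits on the node.  Returns a list of two integer matrices
# [n_y, n_x].
grid_detector_index <- function(geometry, grid) {
  xs <- grid_x_index(grid); ys <- grid_y_index(grid)
  det_row <- matrix(NA_integer_, length(ys), length(xs))
  det_col <- matrix(NA_integer_, length(ys), length(xs))
  for (iy in seq_along(ys)) {
    r <- (ys[iy] * grid$step_y_cm) / geometry$row_spacing_cm +
      geometry$origin_index[1L]
    if (abs(r - round(r)) > 1e-9) next
    r <- as.integer(round(r))
    if (r < 1L || r > geometry$n_rows) next
    for (ix in seq_along(xs)) {
      cc <- (xs[ix] * grid$step_x_cm - geometry$row_offset_cm[r]) /
        geometry$col_spacing_cm + geometry$origin_index[2L]
      if (abs(cc - round(cc)) > 1e-9) next
      cc <- as.integer(round(cc))
      if (cc < 1L || cc > geometry$n_cols) next
      if (!geometry$mask[r, cc]) next
      det_row[iy, ix] <- r; det_col[iy, ix] <- cc
    }
  }
  list(row = det_row, col = det_col)
}

#' @export
print.array_geometry <- function(x, ...) {
  n_act <- sum(x$mask)
  cat(sprintf("<array_geometry '%s'> %d x %d sites, %d detectors\n",
              x$layout, x$n_rows, x$n_cols, n_act))
  cat(sprintf("  spacing: %.3g cm lateral, %.3g cm row-to-row, stagger %.3g cm\n",
              x$col_spacing_cm, x$row_spacing_cm, x$row_stagger_cm))
  pos <- detector_positions(x)
  cat(sprintf("  extent: x %.1f..%.1f cm, y %.1f..%.1f cm\n",
              min(pos$x), max(pos$x), min(pos$y), max(pos$y)))
  invisible(x)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> step (%.3g, %.3g) cm, X %d..%d, Y %d..%d\n",
              x$step_x_cm, x$step_y_cm, x$x_range[1L], x$x_range[2L],
              x$y_range[1L], x$y_range[2L]))
  invisible(x)
}
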