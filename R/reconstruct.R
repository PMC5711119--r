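# Sensitivity-free beam-profile reconstruction.
#
# The unshifted wide-field measurement is MC(X,Y) = R(X,Y) * S(X,Y); the
# laterally shifted one is MLAT(X,Y) = R(X-1,Y) * S(X,Y).  In the ratio
# MLAT/MC the sensitivity cancels, and chaining ratios outward from the
# centre yields the normalized profile
#   RXNOR(X,Y) = prod_{i=1..-X} MLAT(X+i,Y)/MC(X+i,Y)       for X < 0
#   RXNOR(X,Y) = prod_{i=1..X}  MC(i,Y)/MLAT(i,Y)           for X > 0
# and likewise longitudinally.  Products are computed as exponentials of
# cumulative sums of log ratios, extending outward from index 0; a
# masked reading truncates the chain beyond it (every intermediate
# reading is required, so gaps cannot be jumped).

#' One-dimensional normalized profile
#'
#' @param axis `"lateral"` or `"longitudinal"`.
#' @param index integer grid indices (must contain 0).
#' @param values numeric values (exactly 1 at index 0); NA where the
#'   chain could not be formed.
#' @param at the fixed index of the other axis (row Y for a lateral
#'   profile, column X for a longitudinal one).
#' @return An object of class `normalized_profile_1d`.
#' @export
normalized_profile_1d <- function(axis, index, values, at = 0L) {
  axis <- match.arg(axis, c("lateral", "longitudinal"))
  index <- as.integer(index)
  i0 <- match(0L, index)
  if (is.na(i0)) stop("normalized_profile_1d: index must contain 0")
  if (!isTRUE(all.equal(values[i0], 1)))
    stop("normalized_profile_1d: value at index 0 must be 1")
  if (any(values <= 0, na.rm = TRUE))
    stop("normalized_profile_1d: values must be positive")
  structure(list(axis = axis, index = index, values = values,
                 at = as.integer(at)),
            class = "normalized_profile_1d")
}

# core outward ratio chain; shifted/unshifted are readings aligned on
# `index` (which contains 0).  Returns values with NA beyond any gap.
ratio_chain <- function(shifted, unshifted, index) {
  index <- as.integer(index)
  i0 <- match(0L, index)
  if (is.na(i0)) stop("ratio_chain: grid index 0 is required")
  n <- length(index)
  check <- function(i) {
    s <- shifted[i]; u <- unshifted[i]
    if (is.na(s) || is.na(u)) return(FALSE)
    if (s <= 0 || u <= 0)
      stop(sprintf("ratio_chain: nonpositive reading at grid index %d",
                   index[i]))
    TRUE
  }
  out <- rep(NA_real_, n)
  out[i0] <- 1
  # negative side: ln RNOR(-k) = sum of log ratios at indices -k+1 .. 0
  acc <- 0
  for (m in seq_len(i0 - 1L)) {
    i <- i0 - m + 1L
    if (!check(i)) break
    acc <- acc + log(shifted[i]) - log(unshifted[i])
    out[i0 - m] <- exp(acc)
  }
  # positive side: ln RNOR(k) = -sum of log ratios at indices 1 .. k
  acc <- 0
  for (m in seq_len(n - i0)) {
    i <- i0 + m
    if (!check(i)) break
    acc <- acc - log(shifted[i]) + log(unshifted[i])
    out[i0 + m] <- exp(acc)
  }
  out
}

#' Reconstruct one lateral row profile from a ratio chain
#'
#' @param mc_row,mlat_row readings of one detector row (aligned on
#'   `x_index`) from the unshifted and the one-step-left-shifted
#'   wide-field measurement.
#' @param x_index integer grid indices of the readings (contains 0).
#' @param row_index the row's Y grid index (metadata).
#' @return A `normalized_profile_1d` (lateral), sensitivity-free and
#'   normalized to 1 at X = 0.
#' @export
lateral_row_profile <- function(mc_row, mlat_row, x_index, row_index = 0L) {
  if (length(mc_row) != length(mlat_row) ||
      length(mc_row) != length(x_index))
    stop("lateral_row_profile: rows and x_index must have equal length")
  normalized_profile_1d("lateral", x_index,
                        ratio_chain(mlat_row, mc_row, x_index),
                        at = row_index)
}

#' Reconstruct one longitudinal profile from a ratio chain
#'
#' @param mc_col,mlng_col readings of one detector column (aligned on
#'   `y_index`) from the unshifted and the one-step-inferior-shifted
#'   wide-field measurement.
#' @param y_index integer grid indices of the readings (contains 0).
#' @param col_index the column's X grid index (metadata).
#' @return A `normalized_profile_1d` (longitudinal).
#' @export
longitudinal_profile <- function(mc_col, mlng_col, y_index, col_index = 0L) {
  if (length(mc_col) != length(mlng_col) ||
      length(mc_col) != length(y_index))
    stop("longitudinal_profile: columns and y_index must have equal length")
  normalized_profile_1d("longitudinal", y_index,
                        ratio_chain(mlng_col, mc_col, y_index),
                        at = col_index)
}

#' Compose 2D profile from lateral rows and the central longitudinal profile
#'
#' Each lateral row profile is normalized at its own centre; reweighing
#' by the central longitudinal profile gives
#' `RNOR(X, Y) = RXNOR(X, Y) * RYNOR(0, Y)`.
#'
#' @param lateral_rows list of lateral `normalized_profile_1d` objects
#'   (one per grid row, `at` = Y index), all sharing the same `index`.
#' @param central_longitudinal longitudinal `normalized_profile_1d`
#'   covering every row index present in `lateral_rows`.
#' @return An object of class `normalized_profile_2d` with fields
#'   `x_index`, `y_index`, `values` (matrix `[Y, X]`), and the
#'   composition inputs `rxnor` and `rynor0`.
#' @export
compose_2d <- function(lateral_rows, central_longitudinal) {
  stopifnot(length(lateral_rows) > 0)
  x_index <- lateral_rows[[1L]]$index
  y_index <- vapply(lateral_rows, function(p) p$at, 0L)
  for (p in lateral_rows) {
    if (p$axis != "lateral" || !identical(p$index, x_index))
      stop("compose_2d: lateral rows must share one lateral grid index set")
  }
  ipos <- match(y_index, central_longitudinal$index)
  if (anyNA(ipos))
    stop(sprintf("compose_2d: longitudinal profile has no value for row Y = %d",
                 y_index[which(is.na(ipos))[1L]]))
  rynor0 <- central_longitudinal$values[ipos]
  rxnor <- do.call(rbind, lapply(lateral_rows, function(p) p$values))
  values <- rxnor * rynor0
  ord <- order(y_index)
  structure(list(x_index = x_index, y_index = y_index[ord],
                 values = values[ord, , drop = FALSE],
                 rxnor = rxnor[ord, , drop = FALSE],
                 rynor0 = rynor0[ord]),
            class = "normalized_profile_2d")
}

# extract the readings of a measurement at the reconstruction-grid
# detectors: matrix [n_y, n_x] indexed by grid (Y, X), NA off-grid.
#' Readings of a measurement on the reconstruction grid
#'
#' @param m a `measurement`.
#' @param geometry an `array_geometry`.
#' @param grid a `grid_spec`.
#' @return List with `values` (matrix `[Y, X]`), `x_index`, `y_index`.
#' @export
measurement_grid <- function(m, geometry, grid) {
  map <- grid_detector_index(geometry, grid)
  values <- matrix(NA_real_, nrow(map$row), ncol(map$row))
  ok <- !is.na(map$row)
  values[ok] <- m$readings[cbind(map$row[ok], map$col[ok])]
  list(values = values, x_index = grid_x_index(grid),
       y_index = grid_y_index(grid))
}

# pull a measurement with the given role out of a session, insisting on
# uniqueness
session_measurement <- function(session, role) {
  hits <- Filter(function(m) identical(m$role, role), session$measurements)
  if (length(hits) == 0L)
    stop(sprintf("session is missing the '%s' measurement", role))
  if (length(hits) > 1L)
    stop(sprintf("session has %d measurements with role '%s'; expected one",
                 length(hits), role))
  hits[[1L]]
}

#' Iterative 2D beam-profile reconstruction (2DBP)
#'
#' Applies the lateral ratio chain to every grid row, reconstructs the
#' longitudinal profile of every grid column (the central one is used
#' for composition; the others feed the longitudinal error-lock), and
#' composes the 2D profile.
#'
#' @param session a `calibration_session` containing exactly one
#'   measurement each with roles `mc`, `mlat` (shifted one step left)
#'   and `mlng` (shifted one step inferior), sharing one geometry.
#' @return A `normalized_profile_2d`; the attribute `rynor_all` holds
#'   the per-column longitudinal profiles (matrix `[Y, X]`) used by the
#'   longitudinal error-lock.
#' @export
reconstruct_2dbp <- function(session) {
  stopifnot(inherits(session, "calibration_session"))
  geometry <- session$geometry; grid <- session$grid
  mc <- session_measurement(session, "mc")
  mlat <- session_measurement(session, "mlat")
  mlng <- session_measurement(session, "mlng")
  if (!identical(mlat$shift_steps, c(-1L, 0L)))
    stop("reconstruct_2dbp: 'mlat' must be shifted (-1, 0) steps")
  if (!identical(mlng$shift_steps, c(0L, -1L)))
    stop("reconstruct_2dbp: 'mlng' must be shifted (0, -1) steps")
  g_mc <- measurement_grid(mc, geometry, grid)
  g_lat <- measurement_grid(mlat, geometry, grid)
  g_lng <- measurement_grid(mlng, geometry, grid)
  xs <- g_mc$x_index; ys <- g_mc$y_index
  lateral_rows <- lapply(seq_along(ys), function(iy)
    lateral_row_profile(g_mc$values[iy, ], g_lat$values[iy, ], xs,
                        row_index = ys[iy]))
  i0x <- match(0L, xs)
  if (all(is.na(g_mc$values[, i0x])))
    stop("reconstruct_2dbp: central column X = 0 carries no readings")
  rynor_all <- vapply(seq_along(xs), function(ix)
    ratio_chain(g_lng$values[, ix], g_mc$values[, ix], ys),
    numeric(length(ys)))
  central <- normalized_profile_1d("longitudinal", ys, rynor_all[, i0x],
                                   at = 0L)
  out <- compose_2d(lateral_rows, central)
  attr(out, "rynor_all") <- rynor_all
  attr(out, "method") <- "2dbp"
  out
}

#' Noniterative scan-based 2D reconstruction (Greer-style reference)
#'
#' The narrow field stays on the CAX while the array is scanned across
#' it; the detector brought onto the CAX in each exposure receives the
#' same fluence as the central detector did in the central exposure, so
#' relative sensitivities along the scanned axis follow from single
#' reading ratios.  Dividing the wide-field readings by them yields
#' sensitivity-free profiles with no ratio chaining: each point depends
#' only on its own pair of measurements, so local errors do not
#' propagate.
#'
#' @param session a `calibration_session` with one `mc` wide-field
#'   measurement and narrow-field scan measurements with roles
#'   `scan_lat` and `scan_lng` (one per scan position; the scan position
#'   is `-shift` in grid steps and must include 0 on both axes and form
#'   a regular sequence).
#' @return A `normalized_profile_2d` on the scan-position grid.
#' @export
reconstruct_greer <- function(session) {
  stopifnot(inherits(session, "calibration_session"))
  geometry <- session$geometry; grid <- session$grid
  mc <- session_measurement(session, "mc")
  g_mc <- measurement_grid(mc, geometry, grid)
  scans <- function(role, axis_comp) {
    ms <- Filter(function(m) identical(m$role, role), session$measurements)
    if (length(ms) == 0L)
      stop(sprintf("reconstruct_greer: session has no '%s' scan measurements",
                   role))
    pos <- vapply(ms, function(m) -m$shift_steps[axis_comp], 0L)
    ord <- order(pos)
    pos <- pos[ord]; ms <- ms[ord]
    if (anyDuplicated(pos) || length(unique(diff(pos))) > 1L)
      stop(sprintf("reconstruct_greer: '%s' scan positions must form a regular sequence",
                   role))
    if (!0L %in% pos)
      stop(sprintf("reconstruct_greer: '%s' scan must include position 0", role))
    list(pos = pos, ms = ms)
  }
  lat <- scans("scan_lat", 1L)
  lng <- scans("scan_lng", 2L)
  xs <- g_mc$x_index; ys <- g_mc$y_index
  # relative sensitivities S(p, y) / S(0, y) along the lateral axis, one
  # value per scan position p and grid row y
  lat0 <- lat$ms[[match(0L, lat$pos)]]
  g_lat0 <- measurement_grid(lat0, geometry, grid)$values
  i0x <- match(0L, xs); i0y <- match(0L, ys)
  rel_lat <- vapply(seq_along(lat$pos), function(k) {
    gk <- measurement_grid(lat$ms[[k]], geometry, grid)$values
    gk[, match(lat$pos[k], xs)] / g_lat0[, i0x]
  }, numeric(length(ys)))           # [y, p]
  # RXNOR(p, y): wide-field ratio corrected by the relative sensitivity
  rxnor <- vapply(seq_along(lat$pos), function(k) {
    p <- lat$pos[k]
    (g_mc$values[, match(p, xs)] / g_mc$values[, i0x]) / rel_lat[, k]
  }, numeric(length(ys)))           # [y, p]
  bad <- which(rxnor <= 0)
  if (length(bad))
    stop("reconstruct_greer: nonpositive profile value from lateral scan")
  # central longitudinal profile at the longitudinal scan positions
  lng0 <- lng$ms[[match(0L, lng$pos)]]
  g_lng0 <- measurement_grid(lng0, geometry, grid)$values
  rynor0 <- vapply(seq_along(lng$pos), function(k) {
    q <- lng$pos[k]
    gk <- measurement_grid(lng$ms[[k]], geometry, grid)$values
    rel <- gk[match(q, ys), i0x] / g_lng0[i0y, i0x]
    (g_mc$values[match(q, ys), i0x] / g_mc$values[i0y, i0x]) / rel
  }, 0)
  # compose on the scan-position grid
  keep_y <- match(lng$pos, ys)
  rx <- rxnor[keep_y, , drop = FALSE]
  values <- rx * rynor0
  structure(list(x_index = lat$pos, y_index = lng$pos,
                 values = values, rxnor = rx, rynor0 = rynor0),
            class = "normalized_profile_2d",
            method = "greer")
}

#' @export
print.normalized_profile_2d <- function(x, ...) {
  cat(sprintf("<normalized_profile_2d> X %d..%d, Y %d..%d (%d x %d nodes, %d defined)\n",
              min(x$x_index), max(x$x_index), min(x$y_index), max(x$y_index),
              length(x$y_index), length(x$x_index), sum(!is.na(x$values))))
  invisible(x)
}

#' @export
print.normalized_profile_1d <- function(x, ...) {
  cat(sprintf("<normalized_profile_1d %s at %d> index %d..%d, %d defined\n",
              x$axis, x$at, min(x$index), max(x$index),
              sum(!is.na(x$values))))
  invisible(x)
}
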