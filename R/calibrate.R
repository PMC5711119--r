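# Sensitivity calculation: interpolate the reconstructed grid profile to
# the physical detector positions, divide the normalized raw unshifted
# measurement by it (s = mc_nor / rnor), and compare calibrations.

#' Per-detector sensitivity map
#'
#' @param values numeric matrix matching the geometry (NA at masked
#'   positions), positive where defined.
#' @param geometry the `array_geometry` the map belongs to.
#' @param normalized `TRUE` when the map is normalized to 1 at the
#'   normalization detector (recovered maps); `FALSE` for ground-truth
#'   maps from the simulator.
#' @param method provenance label.
#' @param normalization_detector `(row, col)` of the normalization
#'   detector (defaults to the geometry origin).
#' @return An object of class `sensitivity_map`.
#' @export
sensitivity_map <- function(values, geometry, normalized = TRUE,
                            method = "unknown",
                            normalization_detector = geometry$origin_index) {
  if (!identical(dim(values), c(geometry$n_rows, geometry$n_cols)))
    stop("sensitivity_map: values shape does not match geometry")
  if (any(values <= 0, na.rm = TRUE))
    stop("sensitivity_map: sensitivities must be positive")
  if (normalized) {
    v0 <- values[normalization_detector[1L], normalization_detector[2L]]
    if (is.na(v0) || abs(v0 - 1) > 1e-12)
      stop("sensitivity_map: normalized map must be exactly 1 at the ",
           "normalization detector")
  }
  structure(list(values = values, normalized = normalized, method = method,
                 normalization_detector = as.integer(normalization_detector),
                 layout = geometry$layout),
            class = "sensitivity_map")
}

#' Interpolate a reconstructed profile to the physical detectors
#'
#' Bilinear interpolation of the grid profile at every unmasked detector
#' position; exact at grid nodes.  Detectors outside the grid's convex
#' hull, or in a grid cell with an undefined (masked) corner node, are
#' excluded and reported rather than extrapolated.
#'
#' @param profile a `normalized_profile_2d`.
#' @param geometry an `array_geometry`.
#' @param grid a `grid_spec` giving the physical grid step (defaults to
#'   1 cm steps matching integer grid indices).
#' @return List with `rnor` (matrix matching the geometry, NA where
#'   excluded or masked) and `excluded` (data frame of excluded
#'   detectors with a reason).
#' @export
interpolate_to_detectors <- function(profile, geometry, grid = NULL) {
  step_x <- if (is.null(grid)) 1 else grid$step_x_cm
  step_y <- if (is.null(grid)) 1 else grid$step_y_cm
  gx <- profile$x_index * step_x
  gy <- profile$y_index * step_y
  vals <- profile$values
  pos <- detector_positions(geometry)
  rnor <- matrix(NA_real_, geometry$n_rows, geometry$n_cols)
  excl <- list()
  for (k in seq_len(nrow(pos))) {
    x <- pos$x[k]; y <- pos$y[k]
    if (x < gx[1L] - 1e-9 || x > gx[length(gx)] + 1e-9 ||
        y < gy[1L] - 1e-9 || y > gy[length(gy)] + 1e-9) {
      excl[[length(excl) + 1L]] <-
        data.frame(row = pos$row[k], col = pos$col[k], x = x, y = y,
                   reason = "outside grid hull")
      next
    }
    ix <- findInterval(x + 1e-9, gx); ix <- min(max(ix, 1L), length(gx) - 1L)
    iy <- findInterval(y + 1e-9, gy); iy <- min(max(iy, 1L), length(gy) - 1L)
    # snap exactly onto nodes to avoid pulling in a neighbouring NA cell
    tx <- (x - gx[ix]) / (gx[ix + 1L] - gx[ix])
    ty <- (y - gy[iy]) / (gy[iy + 1L] - gy[iy])
    if (abs(tx) < 1e-9) tx <- 0
    if (abs(tx - 1) < 1e-9) tx <- 1
    if (abs(ty) < 1e-9) ty <- 0
    if (abs(ty - 1) < 1e-9) ty <- 1
    use <- matrix(c((1 - tx) * (1 - ty), tx * (1 - ty),
                    (1 - tx) * ty, tx * ty), 2L, 2L, byrow = TRUE)
    corners <- vals[iy:(iy + 1L), ix:(ix + 1L)]
    active <- use > 0
    if (any(is.na(corners[active]))) {
      excl[[length(excl) + 1L]] <-
        data.frame(row = pos$row[k], col = pos$col[k], x = x, y = y,
                   reason = "undefined grid node")
      next
    }
    rnor[pos$row[k], pos$col[k]] <- sum(use[active] * corners[active])
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(row = integer(), col = integer(), x = numeric(),
               y = numeric(), reason = character())
  list(rnor = rnor, excluded = excluded)
}

#' Compute per-detector sensitivities
#'
#' `s(x, y) = mc_nor(x, y) / rnor(x, y)`: the raw unshifted wide-field
#' reading normalized to the central detector, divided by the
#' reconstructed (interpolated) normalized beam profile.
#'
#' @param mc_nor matrix of normalized unshifted readings (1 at the
#'   normalization detector).
#' @param rnor matrix of interpolated normalized profile values.
#' @param geometry an `array_geometry`.
#' @param method provenance label for the resulting map.
#' @return A normalized `sensitivity_map` (exactly 1 at the
#'   normalization detector by construction).
#' @export
compute_sensitivities <- function(mc_nor, rnor, geometry,
                                  method = "2dbp") {
  if (!identical(dim(mc_nor), dim(rnor)))
    stop("compute_sensitivities: mc_nor and rnor shapes differ")
  if (any(rnor <= 0, na.rm = TRUE))
    stop("compute_sensitivities: rnor must be positive where defined")
  s <- mc_nor / rnor
  o <- geometry$origin_index
  if (is.na(s[o[1L], o[2L]]))
    stop("compute_sensitivities: no value at the normalization detector")
  s <- s / s[o[1L], o[2L]]
  s[o[1L], o[2L]] <- 1   # exact unity, not within rounding
  sensitivity_map(s, geometry, normalized = TRUE, method = method)
}

#' Correct raw readings with a sensitivity map
#'
#' Divides each detector's reading by its sensitivity; masked entries
#' stay untouched.  Not idempotent: applying a calibration twice divides
#' twice.
#'
#' @param measurement a `measurement`.
#' @param s a `sensitivity_map`.
#' @return The measurement with corrected readings.
#' @export
apply_calibration <- function(measurement, s) {
  svals <- if (inherits(s, "sensitivity_map")) s$values else s
  if (!identical(dim(measurement$readings), dim(svals)))
    stop("apply_calibration: shapes of readings and sensitivities differ")
  measurement$readings <- measurement$readings / svals
  measurement$meta$calibrated <- TRUE
  measurement
}

#' Percent-deviation statistics between two per-detector value sets
#'
#' Per-detector deviations `100 * |a - b| / b` over the common defined
#' support, with `b` the reference.
#'
#' @param a,b numeric matrices or vectors of equal shape.
#' @param mask optional logical array restricting the comparison.
#' @param bin_width_pct histogram bin width in percentage points.
#' @return List with `mean_abs_pct`, `sd_abs_pct`, `max_abs_pct`, `n`,
#'   and `histogram` (data frame with `bin_lo`, `bin_hi`, `count`).
#' @export
profile_deviation_stats <- function(a, b, mask = NULL,
                                    bin_width_pct = 0.1) {
  if (!identical(dim(a), dim(b)) && length(a) != length(b))
    stop("profile_deviation_stats: shapes differ")
  keep <- !is.na(a) & !is.na(b)
  if (!is.null(mask)) keep <- keep & mask
  if (!any(keep)) stop("profile_deviation_stats: empty common support")
  dev <- 100 * abs(a[keep] - b[keep]) / b[keep]
  brk <- seq(0, max(dev, bin_width_pct) + bin_width_pct, by = bin_width_pct)
  cnt <- table(cut(dev, brk, include.lowest = TRUE, right = FALSE))
  list(mean_abs_pct = mean(dev), sd_abs_pct = stats::sd(dev),
       max_abs_pct = max(dev), n = sum(keep),
       histogram = data.frame(bin_lo = brk[-length(brk)], bin_hi = brk[-1L],
                              count = as.integer(cnt)))
}

#' End-to-end calibration of a session
#'
#' Reconstructs the 2D beam profile with the requested method, applies
#' the error-lock for `"2dbp"`, interpolates to all physical detectors
#' and computes the sensitivity map.
#'
#' @param session a `calibration_session`.
#' @param method `"2dbp"` (iterative, error-locked), `"2dbp_unlocked"`
#'   (iterative, no lock) or `"greer"` (noniterative reference).
#' @return An object of class `calibration_result`: list with
#'   `sensitivities` (`sensitivity_map`), `profile`
#'   (`normalized_profile_2d`), `rnor` (per-detector interpolated
#'   profile), `errors` (error estimates, locked method only),
#'   `excluded` (interpolation exclusions), `method`.
#' @export
calibrate_session <- function(session,
                              method = c("2dbp", "2dbp_unlocked", "greer")) {
  method <- match.arg(method)
  geometry <- session$geometry; grid <- session$grid
  errors <- NULL
  if (method == "greer") {
    recon <- reconstruct_greer(session)
  } else {
    recon <- reconstruct_2dbp(session)
    if (method == "2dbp") {
      errors <- estimate_session_errors(session, recon)
      recon <- correct_reconstruction(recon, errors)
    }
  }
  interp <- interpolate_to_detectors(recon, geometry, grid)
  mc <- session_measurement(session, "mc")
  o <- geometry$origin_index
  mc_nor <- mc$readings / mc$readings[o[1L], o[2L]]
  s <- compute_sensitivities(mc_nor, interp$rnor, geometry, method = method)
  structure(list(sensitivities = s, profile = recon, rnor = interp$rnor,
                 errors = errors, excluded = interp$excluded,
                 method = method, plan_name = session$plan_name,
                 seed = session$seed),
            class = "calibration_result")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<sensitivity_map '%s'> %d detectors, mean %.4f, SD %.4f%s\n",
              x$method, length(v), mean(v), stats::sd(v),
              if (x$normalized) ", normalized at origin" else ""))
  invisible(x)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result method '%s'>\n", x$method))
  print(x$sensitivities)
  if (!is.null(x$errors)) {
    print(x$errors$lateral); print(x$errors$longitudinal)
  }
  if (nrow(x$excluded))
    cat(sprintf("  %d detectors excluded from interpolation\n",
                nrow(x$excluded)))
  invisible(x)
}
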