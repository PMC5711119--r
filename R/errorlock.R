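# Propagation-error model and narrow-field error-locking.
#
# Two multiplicative per-step error components distort an iteratively
# chained profile: E1 (machine output variation of the shifted relative
# to the unshifted measurement) and E2 (array positioning error).  The
# distorted profile follows
#   RXNOR'(X) = RXNOR(X) * (1 + E1 - E2)^(-X)   for X < 0
#   RXNOR'(X) = RXNOR(X) / (1 + E1 + E2)^X      for X > 0
# E1 alone tilts the profile (one side up, the other down); E2 alone
# flattens or sharpens both sides alike.  E2 is a single per-step factor
# although the true positioning error scales with the local profile
# gradient; the residual model error shows up in the per-row diagnostics.
#
# Anchoring the distorted profile at two positions A < 0 < C whose true
# values are known from narrow-field triad measurements gives the
# closed-form solve
#   u = (RXNOR'(A)/RXNOR(A))^(1/-A) - 1 = E1 - E2
#   v = (RXNOR(C)/RXNOR'(C))^(1/C)  - 1 = E1 + E2

#' Accumulated propagation factor
#'
#' A constant per-step relative error compounds over an n-step ratio
#' chain to `(1 + local_error)^n`.
#'
#' @param local_error per-step relative error (fraction; `1 + local_error`
#'   must be positive).
#' @param n_steps number of chain steps (>= 0).
#' @return The accumulated multiplicative factor.
#' @examples
#' propagation_factor(0.08 / 150, 16)   # ~1.0086
#' @export
propagation_factor <- function(local_error, n_steps) {
  if (any(1 + local_error <= 0))
    stop("propagation_factor: 1 + local_error must be positive")
  if (any(n_steps < 0)) stop("propagation_factor: n_steps must be >= 0")
  (1 + local_error)^n_steps
}

#' Per-step error estimate
#'
#' @param axis `"lateral"` or `"longitudinal"`.
#' @param e1 per-step output-variation fraction.
#' @param e2 per-step positioning-error fraction.
#' @param diagnostics optional data frame of per-row (or per-column)
#'   estimates and anchor residuals.
#' @return An object of class `error_estimate`; `e1_pct`/`e2_pct` carry
#'   the same values in percent.
#' @export
error_estimate <- function(axis, e1, e2, diagnostics = NULL) {
  axis <- match.arg(axis, c("lateral", "longitudinal"))
  if (1 + e1 - e2 <= 0 || 1 + e1 + e2 <= 0)
    stop("error_estimate: 1 + e1 -/+ e2 must both be positive")
  structure(list(axis = axis, e1 = e1, e2 = e2,
                 e1_pct = 100 * e1, e2_pct = 100 * e2,
                 diagnostics = diagnostics),
            class = "error_estimate")
}

#' Apply the two-sided propagation-error model to a profile
#'
#' @param profile a `normalized_profile_1d` (or plain named list with
#'   `index` and `values`).
#' @param e1,e2 per-step error fractions.
#' @return The distorted profile (same class), value at 0 unchanged.
#' @export
apply_propagation_error <- function(profile, e1, e2) {
  est <- error_estimate(if (!is.null(profile$axis)) profile$axis else "lateral",
                        e1, e2)
  idx <- profile$index
  fac <- ifelse(idx < 0, (1 + est$e1 - est$e2)^(-idx),
                ifelse(idx > 0, (1 + est$e1 + est$e2)^(-idx), 1))
  profile$values <- profile$values * fac
  profile
}

#' Remove a propagation-error estimate from a distorted profile
#'
#' Exact algebraic inverse of [apply_propagation_error()]:
#' `correct_profile(apply_propagation_error(p, e1, e2), est)` restores
#' `p` to machine precision.
#'
#' @param distorted a `normalized_profile_1d`.
#' @param estimate an `error_estimate` (or list with `e1`, `e2`).
#' @return The corrected profile.
#' @export
correct_profile <- function(distorted, estimate) {
  idx <- distorted$index
  fac <- ifelse(idx < 0, (1 + estimate$e1 - estimate$e2)^(-idx),
                ifelse(idx > 0, (1 + estimate$e1 + estimate$e2)^(-idx), 1))
  distorted$values <- distorted$values / fac
  distorted
}

#' Triad of narrow-field error-locking measurements
#'
#' @param m_a,m_b,m_c `measurement`s of the narrow field with the array
#'   shifted so that the detectors at grid positions A, 0 and C sit on
#'   the field's CAX (shift = -position).
#' @param axis `"lateral"` or `"longitudinal"`.
#' @param a,c anchor grid positions, A < 0 < C.
#' @return An object of class `locking_triad`.
#' @export
locking_triad <- function(m_a, m_b, m_c, axis, a, c) {
  axis <- match.arg(axis, c("lateral", "longitudinal"))
  a <- as.integer(a); c <- as.integer(c)
  if (!(a < 0 && c > 0)) stop("locking_triad: need A < 0 < C")
  comp <- if (axis == "lateral") 1L else 2L
  for (mm in list(A = m_a, B = m_b, C = m_c)) {
    if (!inherits(mm, "measurement"))
      stop("locking_triad: measurements must be 'measurement' objects")
  }
  chk <- function(m, pos, nm) {
    if (m$shift_steps[comp] != -pos)
      stop(sprintf("locking_triad: exposure %s must be shifted %d steps (got %d)",
                   nm, -pos, m$shift_steps[comp]))
  }
  chk(m_a, a, "A"); chk(m_b, 0L, "B"); chk(m_c, c, "C")
  if (!identical(m_a$field$label, m_b$field$label) ||
      !identical(m_b$field$label, m_c$field$label))
    stop("locking_triad: the three exposures must share one field")
  structure(list(m_a = m_a, m_b = m_b, m_c = m_c, axis = axis,
                 a = a, c = c),
            class = "locking_triad")
}

#' Relative sensitivities from a locking triad
#'
#' The detectors brought onto the narrow field's CAX in the three
#' exposures receive identical fluence, so the ratio of each detector's
#' reading (under its own exposure) to the central detector's reading
#' (under the central exposure) equals the sensitivity ratio.  Computed
#' per row of the non-scanned axis.
#'
#' @param triad a `locking_triad`.
#' @param geometry an `array_geometry`.
#' @param grid a `grid_spec`.
#' @return List with `index` (grid indices along the non-scanned axis),
#'   `s_a` = S(A,.)/S(0,.) and `s_c` = S(C,.)/S(0,.).  A known bias
#'   mode: machine-output drift of factor k on one exposure scales that
#'   anchor's ratios by k.
#' @export
triad_relative_sensitivities <- function(triad, geometry, grid) {
  stopifnot(inherits(triad, "locking_triad"))
  g_a <- measurement_grid(triad$m_a, geometry, grid)
  g_b <- measurement_grid(triad$m_b, geometry, grid)
  g_c <- measurement_grid(triad$m_c, geometry, grid)
  xs <- g_b$x_index; ys <- g_b$y_index
  if (triad$axis == "lateral") {
    ia <- match(triad$a, xs); ic <- match(triad$c, xs); i0 <- match(0L, xs)
    if (anyNA(c(ia, ic, i0)))
      stop("triad_relative_sensitivities: anchors outside the grid")
    ref <- g_b$values[, i0]
    out <- list(index = ys, s_a = g_a$values[, ia] / ref,
                s_c = g_c$values[, ic] / ref)
  } else {
    ia <- match(triad$a, ys); ic <- match(triad$c, ys); i0 <- match(0L, ys)
    if (anyNA(c(ia, ic, i0)))
      stop("triad_relative_sensitivities: anchors outside the grid")
    ref <- g_b$values[i0, ]
    out <- list(index = xs, s_a = g_a$values[ia, ] / ref,
                s_c = g_c$values[ic, ] / ref)
  }
  if (any(out$s_a <= 0, na.rm = TRUE) || any(out$s_c <= 0, na.rm = TRUE))
    stop("triad_relative_sensitivities: nonpositive reading ratio")
  out
}

#' True profile values at the anchors from the wide-field measurement
#'
#' Correcting the unshifted wide-field ratios by the triad's relative
#' sensitivities gives the propagation-error-free normalized profile at
#' the anchor positions:
#' `RXNOR(A, Y) = (MC(A, Y) / MC(0, Y)) / (S(A, Y) / S(0, Y))`.
#'
#' @param mc the unshifted wide-field `measurement`.
#' @param rel_sens result of [triad_relative_sensitivities()].
#' @param triad the `locking_triad` (for axis and anchor positions).
#' @param geometry,grid geometry and grid of the session.
#' @return List with `index`, `r_a`, `r_c`: anchor profile values per
#'   row (lateral) or per column (longitudinal).
#' @export
anchor_points <- function(mc, rel_sens, triad, geometry, grid) {
  g_mc <- measurement_grid(mc, geometry, grid)
  xs <- g_mc$x_index; ys <- g_mc$y_index
  if (triad$axis == "lateral") {
    ia <- match(triad$a, xs); ic <- match(triad$c, xs); i0 <- match(0L, xs)
    ref <- g_mc$values[, i0]
    r_a <- (g_mc$values[, ia] / ref) / rel_sens$s_a
    r_c <- (g_mc$values[, ic] / ref) / rel_sens$s_c
    idx <- ys
  } else {
    ia <- match(triad$a, ys); ic <- match(triad$c, ys); i0 <- match(0L, ys)
    ref <- g_mc$values[i0, ]
    r_a <- (g_mc$values[ia, ] / ref) / rel_sens$s_a
    r_c <- (g_mc$values[ic, ] / ref) / rel_sens$s_c
    idx <- xs
  }
  if (any(r_a <= 0, na.rm = TRUE) || any(r_c <= 0, na.rm = TRUE))
    stop("anchor_points: nonpositive anchor value")
  list(index = idx, r_a = r_a, r_c = r_c)
}

#' Closed-form solve for the per-step error components
#'
#' Given a distorted reconstructed profile and the true anchor values at
#' A < 0 < C, solves the two-sided model for (E1, E2):
#' `u = (RXNOR'(A)/RXNOR(A))^(1/-A) - 1`, `v = (RXNOR(C)/RXNOR'(C))^(1/C) - 1`,
#' `E1 = (u + v)/2`, `E2 = (v - u)/2`.
#'
#' @param reconstructed a `normalized_profile_1d` (the distorted,
#'   iteratively reconstructed profile) covering A and C.
#' @param anchors numeric length-2 `c(value_at_A, value_at_C)` of the
#'   true normalized profile, or the list returned by [anchor_points()]
#'   reduced to one row/column.
#' @param a,c anchor grid positions, A < 0 < C.
#' @return An `error_estimate` for the profile's axis.
#' @export
solve_errors <- function(reconstructed, anchors, a, c) {
  a <- as.integer(a); c <- as.integer(c)
  if (!(a < 0 && c > 0)) stop("solve_errors: need A < 0 < C")
  if (is.list(anchors)) anchors <- c(anchors$r_a, anchors$r_c)
  ra <- reconstructed$values[match(a, reconstructed$index)]
  rc <- reconstructed$values[match(c, reconstructed$index)]
  if (is.na(ra) || is.na(rc))
    stop("solve_errors: reconstructed profile does not cover both anchors")
  if (anchors[1L] <= 0 || anchors[2L] <= 0 || ra <= 0 || rc <= 0)
    stop("solve_errors: anchors and reconstructed values must be positive")
  u <- (ra / anchors[1L])^(1 / (-a)) - 1
  v <- (anchors[2L] / rc)^(1 / c) - 1
  error_estimate(if (!is.null(reconstructed$axis)) reconstructed$axis
                 else "lateral",
                 e1 = (u + v) / 2, e2 = (v - u) / 2)
}

# build the triad object for one axis out of a locked session's
# measurements
session_triad <- function(session, axis) {
  role <- sprintf("lock_%s", if (axis == "lateral") "lat" else "lng")
  ms <- Filter(function(m) identical(m$role, role), session$measurements)
  if (length(ms) != 3L)
    stop(sprintf("session does not contain the three '%s' triad measurements",
                 role))
  pos <- vapply(ms, function(m)
    -m$shift_steps[if (axis == "lateral") 1L else 2L], 0L)
  ord <- order(pos)
  ms <- ms[ord]; pos <- pos[ord]
  if (pos[2L] != 0L || !(pos[1L] < 0 && pos[3L] > 0))
    stop(sprintf("'%s' triad positions must satisfy A < 0 < C with B = 0", role))
  locking_triad(ms[[1L]], ms[[2L]], ms[[3L]], axis, pos[1L], pos[3L])
}

#' Estimate per-axis propagation errors of a locked session
#'
#' For the lateral axis the closed-form solve is carried out per grid
#' row (anchored by the lateral narrow-field triad) and the estimates
#' are averaged with equal weight over all rows whose chains reach both
#' anchors; the longitudinal axis is handled per grid column in the same
#' way.  Per-row/column values are kept in the estimate diagnostics.
#'
#' @param session a locked-plan `calibration_session`.
#' @param recon the `normalized_profile_2d` from [reconstruct_2dbp()].
#' @return List with `lateral` and `longitudinal` `error_estimate`s.
#' @export
estimate_session_errors <- function(session, recon) {
  geometry <- session$geometry; grid <- session$grid
  mc <- session_measurement(session, "mc")
  one_axis <- function(axis) {
    triad <- session_triad(session, axis)
    rel <- triad_relative_sensitivities(triad, geometry, grid)
    anch <- anchor_points(mc, rel, triad, geometry, grid)
    if (axis == "lateral") {
      prof_idx <- recon$x_index
      profiles <- lapply(seq_along(recon$y_index), function(iy)
        list(axis = axis, index = prof_idx, values = recon$rxnor[iy, ]))
    } else {
      ryn <- attr(recon, "rynor_all")
      if (is.null(ryn))
        stop("estimate_session_errors: reconstruction lacks per-column ",
             "longitudinal profiles")
      prof_idx <- recon$y_index
      profiles <- lapply(seq_along(recon$x_index), function(ix)
        list(axis = axis, index = prof_idx, values = ryn[, ix]))
    }
    rows <- lapply(seq_along(profiles), function(i) {
      ra <- anch$r_a[i]; rc <- anch$r_c[i]
      p <- profiles[[i]]
      pa <- p$values[match(triad$a, p$index)]
      pc <- p$values[match(triad$c, p$index)]
      if (anyNA(c(ra, rc, pa, pc))) return(NULL)
      est <- solve_errors(p, c(ra, rc), triad$a, triad$c)
      data.frame(at = anch$index[i], e1 = est$e1, e2 = est$e2,
                 resid_a = pa / ra - 1, resid_c = pc / rc - 1)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows) || nrow(rows) == 0L)
      stop(sprintf("estimate_session_errors: no %s row reaches both anchors",
                   axis))
    error_estimate(axis, mean(rows$e1), mean(rows$e2), diagnostics = rows)
  }
  list(lateral = one_axis("lateral"), longitudinal = one_axis("longitudinal"))
}

#' Remove estimated propagation errors from a 2D reconstruction
#'
#' Applies the inverse error model to every lateral row (lateral
#' estimate) and to the central longitudinal profile (longitudinal
#' estimate), then recomposes the 2D profile.
#'
#' @param recon a `normalized_profile_2d` from [reconstruct_2dbp()].
#' @param estimates list with `lateral` and `longitudinal`
#'   `error_estimate`s, as from [estimate_session_errors()].
#' @return The corrected `normalized_profile_2d`.
#' @export
correct_reconstruction <- function(recon, estimates) {
  lat <- estimates$lateral; lng <- estimates$longitudinal
  fx <- ifelse(recon$x_index < 0, (1 + lat$e1 - lat$e2)^(-recon$x_index),
               ifelse(recon$x_index > 0,
                      (1 + lat$e1 + lat$e2)^(-recon$x_index), 1))
  fy <- ifelse(recon$y_index < 0, (1 + lng$e1 - lng$e2)^(-recon$y_index),
               ifelse(recon$y_index > 0,
                      (1 + lng$e1 + lng$e2)^(-recon$y_index), 1))
  recon$rxnor <- sweep(recon$rxnor, 2L, fx, "/")
  recon$rynor0 <- recon$rynor0 / fy
  recon$values <- recon$rxnor * recon$rynor0
  attr(recon, "locked") <- TRUE
  attr(recon, "estimates") <- estimates
  recon
}

#' @export
print.error_estimate <- function(x, ...) {
  cat(sprintf("<error_estimate %s> E1 = %.4f%% (output), E2 = %.4f%% (positioning)\n",
              x$axis, x$e1_pct, x$e2_pct))
  if (!is.null(x$diagnostics))
    cat(sprintf("  per-%s estimates: n = %d, SD(e1) = %.4f%%, SD(e2) = %.4f%%\n",
                if (x$axis == "lateral") "row" else "column",
                nrow(x$diagnostics),
                100 * stats::sd(x$diagnostics$e1),
                100 * stats::sd(x$diagnostics$e2)))
  invisible(x)
}
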