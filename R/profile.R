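# Beam fluence models.  A profile model describes the relative in-plane
# fluence of an open field at the detector plane: a "bowl" (flattened
# photon beam, rising toward the field edges), an FFF-like central peak,
# a flat field, or an arbitrary user function.  Field edges fall off
# through an error-function penumbra of configurable 80-20 width.

#' Open-field specification
#'
#' @param width_cm,height_cm field dimensions (cm) at the detector plane
#'   (lateral x longitudinal).
#' @param label free-text label, e.g. `"wide 37x37"`.
#' @param flat_inside if `TRUE` the field's internal fluence is forced
#'   flat (the in-field shape of the profile model is ignored).  Useful
#'   to stress-test the equal-fluence assumption of narrow-field
#'   sensitivity extraction.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(width_cm, height_cm, label = NULL,
                       flat_inside = FALSE) {
  if (width_cm <= 0 || height_cm <= 0)
    stop("field_spec: field dimensions must be positive")
  if (is.null(label)) label <- sprintf("%gx%g", width_cm, height_cm)
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 label = label, flat_inside = flat_inside),
            class = "field_spec")
}

#' Beam-profile model
#'
#' The in-field shape is a radially symmetric even polynomial in
#' r = sqrt(x^2 + y^2), normalized to 1 at the CAX, with an optional
#' linear tilt for beam asymmetry:
#'   `bowl`:      R(r) = 1 + r2 * r^2 + r4 * r^4         (r2, r4 >= 0)
#'   `fff_peak`:  R(r) = 1 - r2 * r^2 - r4 * r^4
#'   `flat`:      R(r) = 1
#'   `custom`:    R(x, y) = fun(x, y)
#' multiplied by (1 + tilt[1] * x + tilt[2] * y).  The default bowl
#' reaches 1.08 at 15 cm off-axis, typical of a flattened 6 MV beam.
#'
#' @param kind one of `"bowl"`, `"fff_peak"`, `"flat"`, `"custom"`.
#' @param r2,r4 polynomial coefficients (cm^-2, cm^-4).
#' @param tilt numeric length-2, linear asymmetry coefficients (cm^-1).
#' @param penumbra_cm 80-20 penumbra width of the field edge (cm).
#' @param fun for `kind = "custom"`, a function of (x, y) in cm.
#' @return An object of class `profile_model`.
#' @export
profile_model <- function(kind = c("bowl", "fff_peak", "flat", "custom"),
                          r2 = 0.08 / 225, r4 = 0, tilt = c(0, 0),
                          penumbra_cm = 0.5, fun = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom" && !is.function(fun))
    stop("profile_model: kind 'custom' requires a function fun(x, y)")
  if (penumbra_cm <= 0) stop("profile_model: penumbra_cm must be positive")
  structure(list(kind = kind, r2 = r2, r4 = r4, tilt = tilt,
                 penumbra_cm = penumbra_cm, fun = fun),
            class = "profile_model")
}

# error-function field edge: ~1 well inside, ~0 outside, 80-20 falloff
# width equal to penumbra_cm; strictly positive everywhere so that log
# ratios stay defined.
edge_window <- function(u, half_width, penumbra_cm) {
  sigma <- penumbra_cm / (stats::qnorm(0.8) - stats::qnorm(0.2))
  stats::pnorm((half_width - abs(u)) / sigma)
}

#' Evaluate a beam profile
#'
#' Relative fluence at physical positions (x, y) cm.  When a `field` is
#' given the in-field shape is multiplied by the field's penumbra
#' windows; without a field the unbounded in-field shape is returned.
#'
#' @param model a `profile_model`.
#' @param x_cm,y_cm positions (vectorized, cm).
#' @param field optional `field_spec` bounding the irradiated area.
#' @return Numeric vector of fluence values (1 at the CAX for an
#'   untilted model evaluated inside a wide field).
#' @export
evaluate_profile <- function(model, x_cm, y_cm, field = NULL) {
  stopifnot(inherits(model, "profile_model"))
  r2d <- x_cm^2 + y_cm^2
  base <- switch(model$kind,
    bowl     = 1 + model$r2 * r2d + model$r4 * r2d^2,
    fff_peak = pmax(1 - model$r2 * r2d - model$r4 * r2d^2, 1e-6),
    flat     = rep(1, length(r2d)),
    custom   = model$fun(x_cm, y_cm))
  base <- base * (1 + model$tilt[1L] * x_cm + model$tilt[2L] * y_cm)
  if (any(base <= 0))
    stop("evaluate_profile: model is not positive at a requested position")
  if (!is.null(field)) {
    if (isTRUE(field$flat_inside)) base <- rep(1, length(r2d))
    base <- base *
      edge_window(x_cm, field$width_cm / 2, model$penumbra_cm) *
      edge_window(y_cm, field$height_cm / 2, model$penumbra_cm)
  }
  base
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model '%s'> r2 = %.3g, r4 = %.3g, tilt = (%.3g, %.3g), penumbra %.2g cm\n",
              x$kind, x$r2, x$r4, x$tilt[1L], x$tilt[2L], x$penumbra_cm))
  invisible(x)
}
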