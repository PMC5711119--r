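# Measurement simulator.  Generates complete synthetic calibration
# sessions -- wide-field irradiations at unshifted/shifted array
# positions and narrow-field irradiations for error-locking or scanning
# -- with known ground-truth beam profile, per-detector sensitivities,
# output drift, positioning error and measurement noise.
#
# Reading model for detector d at unshifted position (x_d, y_d), array
# shifted by (sx, sy) cm with unintended offset (dx, dy):
#   reading_d = MU * output_scale * noise_d
#               * R(x_d + sx + dx, y_d + sy + dy) * S_d
# All perturbations are multiplicative; MU is a pure scale that cancels
# in every ratio the reconstruction forms.

#' Per-measurement perturbation specification
#'
#' @param output_scale multiplicative machine-output factor for the whole
#'   measurement (models shot-to-shot output variation, the physical
#'   cause of the E1 error component).
#' @param position_error_cm numeric length-2 `(dx, dy)`: unintended array
#'   translation in cm on top of the intended shift (the physical cause
#'   of E2).  Applied in the continuous profile, so sub-step offsets
#'   (e.g. 5 mm with 1 cm steps) are representable.
#' @param noise_sd_rel relative SD of independent multiplicative Gaussian
#'   per-detector noise (truncated at +/- 5 sigma).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(output_scale = 1, position_error_cm = c(0, 0),
                              noise_sd_rel = 0) {
  if (output_scale <= 0) stop("perturbation_spec: output_scale must be > 0")
  if (noise_sd_rel < 0) stop("perturbation_spec: noise_sd_rel must be >= 0")
  if (length(position_error_cm) != 2L)
    stop("perturbation_spec: position_error_cm must have length 2")
  structure(list(output_scale = output_scale,
                 position_error_cm = as.numeric(position_error_cm),
                 noise_sd_rel = noise_sd_rel),
            class = "perturbation_spec")
}

# deterministic substream seed below 2^31 for a named draw site
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) * 131 + 7))
  as.integer((abs(as.numeric(seed)) * 10007 + h) %% 2147483629)
}

# N(1, sd) truncated at +/- 5 sd by redrawing
rnorm_trunc <- function(n, sd) {
  if (sd == 0) return(rep(1, n))
  z <- stats::rnorm(n, 1, sd)
  bad <- abs(z - 1) > 5 * sd
  while (any(bad)) {
    z[bad] <- stats::rnorm(sum(bad), 1, sd)
    bad <- abs(z - 1) > 5 * sd
  }
  z
}

#' Draw a ground-truth sensitivity map
#'
#' Per-detector positive multiplicative sensitivities, drawn i.i.d. from
#' N(1, spread_rel) truncated at +/- 5 sigma; masked positions are NA.
#'
#' @param geometry an `array_geometry`.
#' @param spread_rel relative spread (SD) of the sensitivities, >= 0.
#' @param seed integer seed; the same seed reproduces the map exactly.
#' @return A `sensitivity_map` whose `values` matrix matches the
#'   geometry; `normalized = FALSE` (true maps need not be 1 anywhere).
#' @export
sample_sensitivities <- function(geometry, spread_rel = 0.02, seed = 1L) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (spread_rel < 0)
    stop("sample_sensitivities: spread_rel must be >= 0")
  set.seed(substream_seed(seed, "sensitivities"))
  values <- matrix(NA_real_, geometry$n_rows, geometry$n_cols)
  n <- sum(geometry$mask)
  values[geometry$mask] <- rnorm_trunc(n, spread_rel)
  sensitivity_map(values, geometry, normalized = FALSE,
                  method = "simulated-truth")
}

#' Simulate one irradiation of the array
#'
#' @param model a `profile_model` (the beam's in-field shape).
#' @param sensitivities a `sensitivity_map` (or bare matrix) of true
#'   per-detector sensitivities.
#' @param geometry an `array_geometry`.
#' @param shift_steps integer `(sx, sy)`: intended array shift in grid
#'   steps (negative x = shifted left, so detector X samples beam X + sx).
#' @param grid a `grid_spec` defining the step lengths.
#' @param field a `field_spec` for this irradiation.
#' @param mu monitor units (pure scale, default 200).
#' @param perturb a `perturbation_spec`.
#' @param label,role free-text label and role tag carried in the result.
#' @param seed seed for the noise draw (ignored when noise SD is 0).
#' @return An object of class `measurement` with a readings matrix (NA at
#'   masked positions), the shift, field, MU and metadata.
#' @export
simulate_measurement <- function(model, sensitivities, geometry,
                                 shift_steps = c(0L, 0L), grid, field,
                                 mu = 200, perturb = perturbation_spec(),
                                 label = "measurement", role = "mc",
                                 seed = 1L) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(grid, "grid_spec"), inherits(field, "field_spec"))
  svals <- if (inherits(sensitivities, "sensitivity_map"))
    sensitivities$values else sensitivities
  if (!identical(dim(svals), c(geometry$n_rows, geometry$n_cols)))
    stop("simulate_measurement: sensitivity map shape does not match geometry")
  shift_steps <- as.integer(round(shift_steps))
  shift_cm <- c(shift_steps[1L] * grid$step_x_cm,
                shift_steps[2L] * grid$step_y_cm)
  pos <- detector_positions(geometry,
                            shift_x_cm = shift_cm[1L] + perturb$position_error_cm[1L],
                            shift_y_cm = shift_cm[2L] + perturb$position_error_cm[2L])
  fl <- evaluate_profile(model, pos$x, pos$y, field = field)
  if (role %in% c("mc", "mlat", "mlng")) {
    # wide fields should keep every detector out of the penumbra
    win <- fl / evaluate_profile(model, pos$x, pos$y)
    if (any(win < 0.999))
      warning("simulate_measurement: some detectors of a wide-field ",
              "irradiation lie in the penumbra region")
  }
  set.seed(substream_seed(seed, paste0("noise:", label)))
  noise <- rnorm_trunc(nrow(pos), perturb$noise_sd_rel)
  readings <- matrix(NA_real_, geometry$n_rows, geometry$n_cols)
  readings[cbind(pos$row, pos$col)] <-
    mu * perturb$output_scale * noise * fl * svals[cbind(pos$row, pos$col)]
  structure(list(readings = readings, shift_steps = shift_steps,
                 shift_cm = shift_cm, field = field, mu = mu,
                 label = label, role = role, meta = list()),
            class = "measurement")
}

#' Measurement plan of a calibration session
#'
#' Enumerates the irradiations of a plan without simulating them:
#' `"2dbp_unlocked"` is the three wide-field irradiations (unshifted,
#' shifted one step left, shifted one step toward the couch);
#' `"2dbp_locked"` adds a lateral narrow-field triad and a longitudinal
#' narrow-field triad (9 irradiations in total); `"greer"` is one wide
#' field plus lateral and longitudinal narrow-field scans of the stated
#' ranges (59 irradiations at 1 cm step with the default ranges).
#'
#' @param plan plan name.
#' @param grid a `grid_spec` (defines the step lengths).
#' @param anchors_lat,anchors_lng triad anchor positions in grid steps,
#'   `(A, C)` with A < 0 < C.
#' @param scan_lat,scan_lng inclusive scan ranges in grid steps for the
#'   Greer plan.
#' @param scan_step_steps Greer scan step in grid steps.
#' @param wide_field,narrow_lat_field,narrow_lng_field `field_spec`s.
#' @return A data frame with one row per irradiation: `label`, `role`,
#'   `shift_x`, `shift_y` (steps), `field` (label), `anchor` (grid
#'   position locked/scanned, NA for wide fields).
#' @export
session_plan <- function(plan = c("2dbp_locked", "2dbp_unlocked", "greer"),
                         grid,
                         anchors_lat = c(-11L, 11L),
                         anchors_lng = c(-14L, 14L),
                         scan_lat = c(-12L, 12L),
                         scan_lng = c(-16L, 16L),
                         scan_step_steps = 1L,
                         wide_field = field_spec(37, 37, "wide 37x37"),
                         narrow_lat_field = field_spec(4, 37, "narrow 4x37"),
                         narrow_lng_field = field_spec(37, 4, "narrow 37x4")) {
  plan <- match.arg(plan)
  if (anchors_lat[1L] >= 0 || anchors_lat[2L] <= 0 ||
      anchors_lng[1L] >= 0 || anchors_lng[2L] <= 0)
    stop("session_plan: anchors must satisfy A < 0 < C")
  row <- function(label, role, sx, sy, field, anchor = NA_integer_)
    data.frame(label = label, role = role, shift_x = as.integer(sx),
               shift_y = as.integer(sy), field = field$label,
               anchor = as.integer(anchor), stringsAsFactors = FALSE)
  wide <- rbind(row("mc", "mc", 0, 0, wide_field),
                row("mlat", "mlat", -1, 0, wide_field),
                row("mlng", "mlng", 0, -1, wide_field))
  out <- switch(plan,
    "2dbp_unlocked" = wide,
    "2dbp_locked" = {
      # exposure for anchor a shifts the array by -a so that the detector
      # at unshifted position a sits on the CAX of the narrow field
      tri <- function(axis, anchors, field) {
        pos <- c(anchors[1L], 0L, anchors[2L])
        nm <- c("A", "B", "C")
        do.call(rbind, lapply(seq_along(pos), function(i) {
          s <- -pos[i]
          row(sprintf("lock_%s_%s", axis, nm[i]),
              sprintf("lock_%s", axis),
              if (axis == "lat") s else 0L,
              if (axis == "lat") 0L else s,
              field, anchor = pos[i])
        }))
      }
      rbind(wide, tri("lat", anchors_lat, narrow_lat_field),
            tri("lng", anchors_lng, narrow_lng_field))
    },
    "greer" = {
      scan <- function(axis, rng, field) {
        pos <- seq(rng[1L], rng[2L], by = scan_step_steps)
        do.call(rbind, lapply(pos, function(p) {
          row(sprintf("scan_%s_%+d", axis, p), sprintf("scan_%s", axis),
              if (axis == "lat") -p else 0L,
              if (axis == "lat") 0L else -p,
              field, anchor = p)
        }))
      }
      rbind(row("mc", "mc", 0, 0, wide_field),
            scan("lat", scan_lat, narrow_lat_field),
            scan("lng", scan_lng, narrow_lng_field))
    })
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic calibration session
#'
#' Simulates every irradiation of a measurement plan with a shared
#' ground truth, returning the measurements together with the truth so
#' downstream stages can be validated.
#'
#' @param plan `"2dbp_locked"`, `"2dbp_unlocked"` or `"greer"`.
#' @param model a `profile_model` (ground-truth beam).
#' @param sensitivities ground-truth `sensitivity_map`.
#' @param geometry an `array_geometry`.
#' @param grid a `grid_spec`.
#' @param noise_sd_rel relative measurement noise applied to every
#'   irradiation.
#' @param perturb_overrides named list of `perturbation_spec` objects
#'   keyed by measurement label (e.g. `list(mlng = perturbation_spec(
#'   position_error_cm = c(0, 0.5)))`); unlisted measurements get a
#'   neutral perturbation with `noise_sd_rel`.
#' @param mu monitor units per irradiation.
#' @param seed session seed; all noise substreams derive from it.
#' @param ... plan parameters forwarded to [session_plan()].
#' @return An object of class `calibration_session`: list with
#'   `measurements` (named list), `plan` (data frame), `geometry`,
#'   `grid`, `truth` (model + sensitivities + perturbations), `seed`.
#' @export
generate_session <- function(plan = c("2dbp_locked", "2dbp_unlocked", "greer"),
                             model, sensitivities, geometry, grid,
                             noise_sd_rel = 0, perturb_overrides = list(),
                             mu = 200, seed = 1L, ...) {
  plan <- match.arg(plan)
  plan_df <- session_plan(plan, grid, ...)
  fields <- plan_fields(plan_df, ...)
  meas <- vector("list", nrow(plan_df))
  names(meas) <- plan_df$label
  for (i in seq_len(nrow(plan_df))) {
    lab <- plan_df$label[i]
    pert <- perturb_overrides[[lab]]
    if (is.null(pert)) pert <- perturbation_spec(noise_sd_rel = noise_sd_rel)
    else if (pert$noise_sd_rel == 0 && noise_sd_rel > 0)
      pert$noise_sd_rel <- noise_sd_rel
    m <- simulate_measurement(model, sensitivities, geometry,
                              shift_steps = c(plan_df$shift_x[i],
                                              plan_df$shift_y[i]),
                              grid = grid, field = fields[[plan_df$field[i]]],
                              mu = mu, perturb = pert, label = lab,
                              role = plan_df$role[i], seed = seed)
    m$meta$anchor <- plan_df$anchor[i]
    meas[[i]] <- m
  }
  structure(list(plan_name = plan, plan = plan_df, measurements = meas,
                 geometry = geometry, grid = grid,
                 truth = list(model = model, sensitivities = sensitivities,
                              perturb_overrides = perturb_overrides,
                              noise_sd_rel = noise_sd_rel),
                 seed = seed),
            class = "calibration_session")
}

# resolve the distinct field_spec objects used by a plan data frame
plan_fields <- function(plan_df, ...) {
  dots <- list(...)
  pick <- function(name, default) if (!is.null(dots[[name]])) dots[[name]] else default
  f <- list(pick("wide_field", field_spec(37, 37, "wide 37x37")),
            pick("narrow_lat_field", field_spec(4, 37, "narrow 4x37")),
            pick("narrow_lng_field", field_spec(37, 4, "narrow 37x4")))
  stats::setNames(f, vapply(f, function(x) x$label, ""))
}

#' Assemble a session from existing measurements
#'
#' Used by the file-based workflow: measurements read from disk are
#' combined with a geometry and grid into the session structure the
#' reconstruction and calibration functions expect.
#'
#' @param measurements named list (or list with `label`s) of
#'   `measurement` objects.
#' @param geometry an `array_geometry`.
#' @param grid a `grid_spec`.
#' @param plan_name optional plan label.
#' @return A `calibration_session` (without ground truth).
#' @export
as_session <- function(measurements, geometry, grid, plan_name = "external") {
  if (is.null(names(measurements)) || any(names(measurements) == ""))
    names(measurements) <- vapply(measurements, function(m) m$label, "")
  structure(list(plan_name = plan_name, plan = NULL,
                 measurements = measurements, geometry = geometry,
                 grid = grid, truth = NULL, seed = NA_integer_),
            class = "calibration_session")
}

#' @export
print.calibration_session <- function(x, ...) {
  cat(sprintf("<calibration_session '%s'> %d measurements on %s geometry\n",
              x$plan_name, length(x$measurements), x$geometry$layout))
  invisible(x)
}

#' @export
print.measurement <- function(x, ...) {
  cat(sprintf("<measurement '%s'> role %s, shift (%d, %d) steps, field %s, %g MU\n",
              x$label, x$role, x$shift_steps[1L], x$shift_steps[2L],
              x$field$label, x$mu))
  invisible(x)
}
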