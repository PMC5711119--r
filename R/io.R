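# Text file formats.  The vendor file format of commercial arrays is
# proprietary and undocumented, so the package defines its own small,
# versioned, tab-separated text formats: a measurement file (header +
# reading matrix), a geometry document (JSON with a run-length-encoded
# mask), a sensitivity TSV and a JSON calibration report.  All round
# trips are lossless for the text representation.

MEASUREMENT_MAGIC <- "#%beamcal-measurement"
MEASUREMENT_VERSION <- 1L

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 17))
}

#' Write a measurement to a text file
#'
#' @param m a `measurement`.
#' @param path output file path.
#' @param step_cm numeric length-2 grid step (cm) recorded in the
#'   header so shifts in steps are interpretable.
#' @param geometry_ref geometry reference string stored in the header
#'   (e.g. `"mapcheck2"` or `"grid:5x5:1"`).
#' @return `path`, invisibly.
#' @export
write_measurement <- function(m, path, step_cm = c(1, 1),
                              geometry_ref = "mapcheck2") {
  stopifnot(inherits(m, "measurement"))
  hdr <- c(
    paste(MEASUREMENT_MAGIC, MEASUREMENT_VERSION),
    paste0("label\t", m$label),
    paste0("role\t", m$role),
    paste0("geometry\t", geometry_ref),
    paste0("shift_steps\t", m$shift_steps[1L], "\t", m$shift_steps[2L]),
    paste0("step_cm\t", fmt_num(step_cm[1L]), "\t", fmt_num(step_cm[2L])),
    paste0("field_cm\t", fmt_num(m$field$width_cm), "\t",
           fmt_num(m$field$height_cm)),
    paste0("field_label\t", m$field$label),
    paste0("mu\t", fmt_num(m$mu)))
  extra <- m$meta[setdiff(names(m$meta), c("anchor", "calibrated"))]
  for (k in names(extra))
    hdr <- c(hdr, paste0("x-", k, "\t", as.character(extra[[k]])))
  if (!is.null(m$meta$anchor) && !is.na(m$meta$anchor))
    hdr <- c(hdr, paste0("anchor\t", m$meta$anchor))
  hdr <- c(hdr, paste0("readings\t", nrow(m$readings), "\t",
                       ncol(m$readings)))
  body <- apply(m$readings, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a measurement from a text file
#'
#' Malformed files are rejected with line-numbered diagnostics; unknown
#' header keys produce a warning and are preserved in `meta`.
#'
#' @param path file path.
#' @return A list with the `measurement` (element `measurement`) and the
#'   header's `geometry_ref` and `step_cm`.
#' @export
read_measurement <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1L], MEASUREMENT_MAGIC))
    stop("read_measurement: '", path, "' is not a beamcal measurement file")
  ver <- suppressWarnings(as.integer(sub(".*\\s", "", lines[1L])))
  if (is.na(ver) || ver != MEASUREMENT_VERSION)
    stop("read_measurement: unsupported format version in '", path, "'")
  hdr <- list(); meta <- list()
  i <- 2L; n_rows <- NULL; n_cols <- NULL
  known <- c("label", "role", "geometry", "shift_steps", "step_cm",
             "field_cm", "field_label", "mu", "anchor", "readings")
  while (i <= length(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    key <- parts[1L]
    if (key == "readings") {
      n_rows <- as.integer(parts[2L]); n_cols <- as.integer(parts[3L])
      i <- i + 1L
      break
    }
    if (startsWith(key, "x-")) {
      meta[[sub("^x-", "", key)]] <- paste(parts[-1L], collapse = "\t")
    } else if (!key %in% known) {
      warning(sprintf("read_measurement: unknown header key '%s' (line %d); preserved in meta",
                      key, i))
      meta[[key]] <- paste(parts[-1L], collapse = "\t")
    } else {
      hdr[[key]] <- parts[-1L]
    }
    i <- i + 1L
  }
  if (is.null(n_rows) || is.na(n_rows) || is.na(n_cols))
    stop("read_measurement: missing or malformed 'readings' header in '",
         path, "'")
  body <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  if (length(body) < n_rows)
    stop(sprintf("read_measurement: body truncated at line %d: expected %d reading rows, found %d",
                 length(lines) + 1L, n_rows, length(body)))
  readings <- matrix(NA_real_, n_rows, n_cols)
  for (r in seq_len(n_rows)) {
    vals <- strsplit(body[r], "\t", fixed = TRUE)[[1L]]
    if (length(vals) != n_cols)
      stop(sprintf("read_measurement: line %d has %d values, expected %d",
                   i + r - 1L, length(vals), n_cols))
    readings[r, ] <- suppressWarnings(as.numeric(vals))
  }
  if (any(readings < 0, na.rm = TRUE))
    stop("read_measurement: negative readings in '", path, "'")
  field <- field_spec(as.numeric(hdr$field_cm[1L]),
                      as.numeric(hdr$field_cm[2L]),
                      label = hdr$field_label[1L])
  shift <- as.integer(hdr$shift_steps)
  if (!is.null(hdr$anchor)) meta$anchor <- as.integer(hdr$anchor[1L])
  m <- structure(list(readings = readings, shift_steps = shift,
                      shift_cm = shift * as.numeric(hdr$step_cm),
                      field = field, mu = as.numeric(hdr$mu[1L]),
                      label = hdr$label[1L], role = hdr$role[1L],
                      meta = meta),
                 class = "measurement")
  list(measurement = m, geometry_ref = hdr$geometry[1L],
       step_cm = as.numeric(hdr$step_cm))
}

#' Resolve a geometry reference string
#'
#' `"mapcheck2"` or `"grid:<n_rows>x<n_cols>:<spacing_cm>"`.
#'
#' @param ref geometry reference string.
#' @return An `array_geometry`.
#' @export
resolve_geometry <- function(ref) {
  if (identical(ref, "mapcheck2")) return(build_mapcheck2_geometry())
  if (startsWith(ref, "grid:")) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1L]]
    dims <- as.integer(strsplit(parts[2L], "x", fixed = TRUE)[[1L]])
    return(build_grid_geometry(dims[1L], dims[2L], as.numeric(parts[3L])))
  }
  stop("resolve_geometry: unknown geometry reference '", ref, "'")
}

geometry_ref <- function(geometry) {
  if (geometry$layout == "mapcheck2") return("mapcheck2")
  sprintf("grid:%dx%d:%s", geometry$n_rows, geometry$n_cols,
          formatC(geometry$col_spacing_cm, format = "g", digits = 17))
}

#' Write a calibration session to a directory
#'
#' One measurement file per irradiation plus a JSON manifest listing the
#' files, the plan, the grid and the session seed.
#'
#' @param session a `calibration_session`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gref <- geometry_ref(session$geometry)
  step <- c(session$grid$step_x_cm, session$grid$step_y_cm)
  files <- character(0)
  for (m in session$measurements) {
    f <- file.path(dir, paste0(m$label, ".dat"))
    write_measurement(m, f, step_cm = step, geometry_ref = gref)
    files <- c(files, basename(f))
  }
  manifest <- list(format = "beamcal-session", version = 1L,
                   plan = session$plan_name, geometry = gref,
                   step_cm = step,
                   x_range = session$grid$x_range,
                   y_range = session$grid$y_range,
                   seed = session$seed, files = files)
  mp <- file.path(dir, "session.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a calibration session from a directory
#'
#' @param dir directory containing `session.json` and measurement files.
#' @return A `calibration_session` (without ground truth).
#' @export
read_session <- function(dir) {
  mp <- file.path(dir, "session.json")
  if (!file.exists(mp))
    stop("read_session: no session.json in '", dir, "'")
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  geometry <- resolve_geometry(manifest$geometry)
  grid <- grid_spec(manifest$step_cm[1L], manifest$step_cm[2L],
                    manifest$x_range, manifest$y_range)
  meas <- lapply(manifest$files, function(f)
    read_measurement(file.path(dir, f))$measurement)
  ses <- as_session(meas, geometry, grid,
                    plan_name = manifest$plan %||% "external")
  ses$seed <- manifest$seed %||% NA_integer_
  ses
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a sensitivity map as TSV
#'
#' Columns: detector `row`, `col`, physical `x_cm`, `y_cm`, sensitivity
#' `s`.  Read back bit-exactly by [read_sensitivity_tsv()].
#'
#' @param s a `sensitivity_map`.
#' @param geometry the matching `array_geometry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_tsv <- function(s, geometry, path) {
  pos <- detector_positions(geometry)
  df <- data.frame(row = pos$row, col = pos$col,
                   x_cm = fmt_num(pos$x), y_cm = fmt_num(pos$y),
                   s = fmt_num(s$values[cbind(pos$row, pos$col)]))
  lines <- c(sprintf("#%%beamcal-sensitivity 1\t%s\t%s",
                     s$method, geometry_ref(geometry)),
             paste(c("row", "col", "x_cm", "y_cm", "s"), collapse = "\t"),
             do.call(paste, c(df, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sensitivity TSV
#'
#' @param path file path.
#' @return List with `values` (matrix on the referenced geometry's
#'   shape), `method`, `geometry_ref` and the parsed `table`.
#' @export
read_sensitivity_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "#%beamcal-sensitivity"))
    stop("read_sensitivity_tsv: '", path, "' is not a sensitivity TSV")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  tab <- utils::read.table(text = lines[-1L], header = TRUE, sep = "\t",
                           colClasses = c("integer", "integer", "numeric",
                                          "numeric", "numeric"))
  geometry <- resolve_geometry(hdr[3L])
  values <- matrix(NA_real_, geometry$n_rows, geometry$n_cols)
  values[cbind(tab$row, tab$col)] <- tab$s
  list(values = values, method = hdr[2L], geometry_ref = hdr[3L],
       table = tab)
}

#' Write a calibration report as JSON
#'
#' Method label, error estimates, deviation statistics, exclusions and
#' reproducibility information (seed and a content hash of the
#' configuration).
#'
#' @param result a `calibration_result` (or a `robustness_study`).
#' @param path output path.
#' @param extra optional named list merged into the report.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(result, path, extra = list()) {
  est <- function(e) if (is.null(e)) NULL else
    list(e1_pct = e$e1_pct, e2_pct = e$e2_pct,
         n = if (is.null(e$diagnostics)) 0L else nrow(e$diagnostics),
         sd_e1_pct = if (is.null(e$diagnostics)) NA else
           100 * stats::sd(e$diagnostics$e1),
         sd_e2_pct = if (is.null(e$diagnostics)) NA else
           100 * stats::sd(e$diagnostics$e2))
  if (inherits(result, "robustness_study")) {
    rep <- list(kind = "robustness_study", table = result$table,
                config = result$config,
                errors = lapply(result$errors, function(pair)
                  if (is.null(pair)) NULL else
                    list(lateral = est(pair$lateral),
                         longitudinal = est(pair$longitudinal))))
  } else {
    rep <- list(kind = "calibration", method = result$method,
                plan = result$plan_name, seed = result$seed,
                n_excluded = nrow(result$excluded),
                errors = if (is.null(result$errors)) NULL else
                  list(lateral = est(result$errors$lateral),
                       longitudinal = est(result$errors$longitudinal)))
  }
  rep <- c(rep, extra)
  rep$config_hash <- substr(config_hash(rep), 1L, 12L)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# small deterministic content hash (djb2 over the serialized object)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  h <- 5381
  for (ch in utf8ToInt(as.character(s))) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x%04x", as.integer(h %% 2^31), nchar(s) %% 65536)
}
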