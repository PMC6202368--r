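# On-disk formats: recordings as CSV + JSON sidecar, metrics tables as CSV
# with a units sidecar, stimulus grids and population specs as JSON configs.

RECORDING_SCHEMA_VERSION <- "1.0"

sidecar_path <- function(path) sub("\\.csv$", "", path)

#' Write / read a recording
#'
#' A recording is stored as a CSV file with header
#' `time_s,voltage_V,current_A` (17 significant digits, so doubles
#' round-trip bitwise) plus a JSON sidecar `<path minus .csv>.json` holding
#' the metadata: subject, site, the stimulus fields, optional seed and the
#' schema version.
#'
#' @param rec A [recording()].
#' @param path CSV file path (`.csv`); the sidecar path is derived from it.
#' @param seed Optional integer recorded in the metadata.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [recording()]. Unknown metadata keys are preserved in
#'   `$extra` with a warning.
#' @export
write_recording <- function(rec, path, seed = NULL) {
  if (!inherits(rec, "skin_recording")) {
    ms_stop("`rec` must be a skin_recording", "invalid_parameter")
  }
  lines <- c("time_s,voltage_V,current_A",
             sprintf("%.17g,%.17g,%.17g", rec$t, rec$v, rec$i))
  writeLines(lines, path)
  meta <- list(schema_version = RECORDING_SCHEMA_VERSION,
               subject_id = rec$subject_id, site = rec$site,
               stimulus = unclass(rec$stimulus))
  if (!is.null(seed)) meta$seed <- seed
  if (!is.null(rec$extra)) meta <- c(meta, rec$extra)
  jsonlite::write_json(meta, paste0(sidecar_path(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- paste0(sidecar_path(path), ".json")
  if (!file.exists(meta_path)) {
    ms_stop(sprintf("missing metadata sidecar `%s`", meta_path), "validation")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$schema_version) ||
      meta$schema_version != RECORDING_SCHEMA_VERSION) {
    ms_stop(sprintf("recording schema version `%s` does not match supported `%s`",
                    meta$schema_version, RECORDING_SCHEMA_VERSION),
            "versioned_format")
  }
  known <- c("schema_version", "subject_id", "site", "stimulus", "seed")
  unknown <- setdiff(names(meta), known)
  if (length(unknown)) {
    ms_warn(sprintf("preserving unknown metadata keys: %s",
                    paste(unknown, collapse = ", ")), "unknown_metadata")
  }
  df <- utils::read.csv(path, colClasses = "numeric")
  st <- meta$stimulus
  stim <- voltage_stimulus(st$kind, st$amplitude, st$frequency, st$periods,
                           st$samples_per_period, st$sign)
  recording(subject_id = meta$subject_id, site = meta$site, stimulus = stim,
            t = df$time_s, v = df$voltage_V, i = df$current_A,
            extra = if (length(unknown)) meta[unknown])
}

#' Write a loop-metrics table
#'
#' Flat CSV (one row per subject x site x stimulus x period) plus a JSON
#' sidecar documenting the unit of every column.
#'
#' @param rows Loop-metrics data.frame (see [analyze_recordings()]).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_loop_metrics <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  units <- list(
    subject_id = "", site = "", kind = "", amplitude = "V", frequency = "Hz",
    sign = "", period = "", nl = "dimensionless", lobe_area = "A*V",
    lobe_area_normalized = "V", i_max = "A", i_max_angle = "deg",
    n_pinch = "count", tangential = "boolean",
    q1_signed_area = "A*V", q3_signed_area = "A*V")
  jsonlite::write_json(list(schema_version = RECORDING_SCHEMA_VERSION,
                            units = units[names(units) %in% names(rows)]),
                       paste0(sidecar_path(path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Serialize a stimulus grid or population spec to JSON
#'
#' Structured configs for reproducible runs: the stimulus grid is stored as
#' an array of stimulus field sets, the population spec with its weights and
#' seed.
#'
#' @param grid List of [voltage_stimulus()] objects.
#' @param spec A [population_spec()].
#' @param path JSON file path.
#' @return The reconstructed object (for readers) or `path` (for writers,
#'   invisibly).
#' @export
write_stimulus_grid <- function(grid, path) {
  jsonlite::write_json(lapply(grid, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_grid
#' @export
read_stimulus_grid <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    voltage_stimulus(s$kind, s$amplitude, s$frequency, s$periods,
                     s$samples_per_period, s$sign)
  })
}

#' @rdname write_stimulus_grid
#' @export
write_population_spec <- function(spec, path) {
  obj <- unclass(spec)
  obj$class_weights <- as.list(obj$class_weights)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_grid
#' @export
read_population_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  population_spec(raw$n_subjects, unlist(raw$class_weights), raw$seed)
}
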