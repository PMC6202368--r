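#' Voltage-current recording
#'
#' The unit every analysis consumes: a uniformly sampled time/voltage/current
#' triplet together with subject, site and stimulus metadata.
#'
#' @param subject_id Subject identifier string.
#' @param site Recording site: `"forehead"`, `"earlobe"` or `"fingertip"`.
#' @param stimulus The [voltage_stimulus()] that was applied.
#' @param t Time vector, seconds; strictly increasing, uniformly spaced.
#' @param v Applied voltage, volts.
#' @param i Measured current, amperes.
#' @param state Optional data.frame of simulator state trajectories
#'   (`x`, `temperature`), attached by [simulate_recording()]. Not part of
#'   the on-disk format.
#' @param extra Optional named list of additional metadata.
#' @return An object of class `skin_recording`.
#' @export
recording <- function(subject_id, site = c("forehead", "earlobe", "fingertip"),
                      stimulus, t, v, i, state = NULL, extra = NULL) {
  site <- match.arg(site)
  if (!inherits(stimulus, "voltage_stimulus")) {
    ms_stop("`stimulus` must be a voltage_stimulus", "invalid_parameter")
  }
  n <- length(t)
  if (n < 2L || length(v) != n || length(i) != n) {
    ms_stop("t, v and i must have equal length >= 2", "validation")
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    ms_stop("time vector must be strictly increasing", "validation")
  }
  if (max(dt) - min(dt) > 1e-8 * mean(dt)) {
    ms_stop("time vector must be uniformly spaced", "validation")
  }
  structure(
    list(subject_id = as.character(subject_id), site = site,
         stimulus = stimulus, t = as.numeric(t), v = as.numeric(v),
         i = as.numeric(i), state = state, extra = extra),
    class = "skin_recording"
  )
}

#' @export
print.skin_recording <- function(x, ...) {
  cat(sprintf("<skin_recording> subject %s, %s, %d samples\n",
              x$subject_id, x$site, length(x$t)))
  cat("  stimulus: ")
  print(x$stimulus)
  cat(sprintf("  current range: [%.3g, %.3g] A\n", min(x$i), max(x$i)))
  invisible(x)
}

#' Convert a plain data.frame to a recording
#'
#' Template converter for externally acquired data (for example a deposited
#' data set downloaded separately): map your columns to time, voltage and
#' current, supply the stimulus that was applied, and the result plugs into
#' every analysis function. The internal layout of external deposits is not
#' standardised, so column mapping is left to the caller.
#'
#' @param df A data.frame holding the samples.
#' @param stimulus The applied [voltage_stimulus()].
#' @param subject_id,site Metadata; see [recording()].
#' @param time_col,voltage_col,current_col Column names in `df`.
#' @return A `skin_recording`.
#' @export
as_recording <- function(df, stimulus, subject_id = "external",
                         site = "forehead", time_col = "time_s",
                         voltage_col = "voltage_V", current_col = "current_A") {
  for (cl in c(time_col, voltage_col, current_col)) {
    if (!cl %in% names(df)) {
      ms_stop(sprintf("column `%s` not found in data.frame", cl), "validation")
    }
  }
  recording(subject_id = subject_id, site = site, stimulus = stimulus,
            t = df[[time_col]], v = df[[voltage_col]], i = df[[current_col]])
}
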