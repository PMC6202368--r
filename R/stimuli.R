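#' Voltage stimulus specification
#'
#' Describes one excitation waveform of the low-frequency protocol: a
#' sinusoid, a triangle wave, or a non-periodic "decaying sine" (sinusoid
#' under a decreasing amplitude envelope). All waveforms start at v = 0 and
#' are sampled uniformly with `samples_per_period` samples per period.
#'
#' @param kind Waveform type: `"sinusoidal"`, `"triangular"` or
#'   `"decaying_sine"`.
#' @param amplitude Peak voltage in volts (> 0).
#' @param frequency Fundamental frequency in hertz (> 0).
#' @param periods Number of periods applied (positive integer, default 3).
#' @param samples_per_period Samples per period (positive integer, default 500).
#' @param sign Stimulus polarity, `+1` or `-1` (default `+1`). A negative sign
#'   flips the whole waveform.
#' @return An object of class `voltage_stimulus`.
#' @examples
#' stim <- voltage_stimulus("sinusoidal", amplitude = 1.2, frequency = 0.05)
#' wf <- generate_waveform(stim)
#' nrow(wf)       # 1500 samples
#' max(wf$time)   # just under 60 s
#' @export
voltage_stimulus <- function(kind = c("sinusoidal", "triangular", "decaying_sine"),
                             amplitude, frequency, periods = 3L,
                             samples_per_period = 500L, sign = 1) {
  kind <- match.arg(kind)
  check_positive_scalar(amplitude, "amplitude")
  check_positive_scalar(frequency, "frequency")
  check_positive_scalar(periods, "periods")
  check_positive_scalar(samples_per_period, "samples_per_period")
  if (periods != as.integer(periods) ||
      samples_per_period != as.integer(samples_per_period)) {
    ms_stop("`periods` and `samples_per_period` must be whole numbers",
            "invalid_parameter")
  }
  if (!sign %in% c(-1, 1)) {
    ms_stop("`sign` must be +1 or -1", "invalid_parameter")
  }
  structure(
    list(kind = kind, amplitude = as.numeric(amplitude),
         frequency = as.numeric(frequency),
         periods = as.integer(periods),
         samples_per_period = as.integer(samples_per_period),
         sign = as.numeric(sign)),
    class = "voltage_stimulus"
  )
}

#' @export
print.voltage_stimulus <- function(x, ...) {
  cat(sprintf("<voltage_stimulus> %s, %g V, %g Hz, %d period(s), %d samples/period, sign %+d\n",
              x$kind, x$amplitude, x$frequency, x$periods,
              x$samples_per_period, x$sign))
  invisible(x)
}

# Total sample count and sampling interval of a stimulus.
stim_n_samples <- function(stim) stim$periods * stim$samples_per_period
stim_dt <- function(stim) 1 / (stim$frequency * stim$samples_per_period)

# Time of the last sample; the decaying-sine envelope reaches zero there.
stim_t_last <- function(stim) (stim_n_samples(stim) - 1L) * stim_dt(stim)

# Waveform value v(t), vectorised over t. Pure function of (stim, t).
stim_value <- function(stim, t) {
  a <- stim$sign * stim$amplitude
  w <- 2 * pi * stim$frequency
  switch(stim$kind,
    sinusoidal = a * sin(w * t),
    triangular = a * (2 / pi) * asin(sin(w * t)),
    decaying_sine = {
      env <- pmax(0, 1 - t / stim_t_last(stim))
      a * env * sin(w * t)
    }
  )
}

# Analytic time derivative dv/dt, used for the capacitive current term.
# At triangle corners (measure-zero set) the slope of the following segment
# is used.
stim_deriv <- function(stim, t) {
  a <- stim$sign * stim$amplitude
  w <- 2 * pi * stim$frequency
  switch(stim$kind,
    sinusoidal = a * w * cos(w * t),
    triangular = {
      s <- ifelse(cos(w * t) >= 0, 1, -1)
      4 * a * stim$frequency * s
    },
    decaying_sine = {
      tl <- stim_t_last(stim)
      env <- pmax(0, 1 - t / tl)
      denv <- ifelse(t <= tl, -1 / tl, 0)
      a * (denv * sin(w * t) + env * w * cos(w * t))
    }
  )
}

#' Sample a voltage stimulus
#'
#' Generates the uniformly sampled waveform of a [voltage_stimulus()]: time
#' starts at 0 with spacing `1 / (frequency * samples_per_period)` and the
#' signal has exactly `periods * samples_per_period` samples.
#'
#' @param stim A `voltage_stimulus`.
#' @return A `data.frame` with columns `time` (seconds) and `voltage` (volts).
#' @export
generate_waveform <- function(stim) {
  if (!inherits(stim, "voltage_stimulus")) {
    ms_stop("`stim` must be a voltage_stimulus", "invalid_parameter")
  }
  n <- stim_n_samples(stim)
  t <- (seq_len(n) - 1L) * stim_dt(stim)
  data.frame(time = t, voltage = stim_value(stim, t))
}

#' The 30-stimulus experimental grid
#'
#' Crosses the five stimulus types (sinusoids at 0.4, 0.8 and 1.2 V, a
#' triangle wave at 1.2 V and a decaying sine at 1.2 V) with the six-point
#' frequency sweep, three periods each. The intermediate frequencies of the
#' sweep are a package choice (only the 0.05-2.5 Hz endpoints are fixed by
#' the protocol) and can be overridden.
#'
#' @param frequencies Frequency sweep in hertz.
#' @param periods Periods per stimulus.
#' @param samples_per_period Samples per period.
#' @param randomize If `TRUE`, shuffle stimulus-type order, the frequency
#'   sweep within each type, and draw a random polarity per stimulus,
#'   mimicking the randomised acquisition protocol. Requires `seed`.
#'   Randomisation changes presentation order and sign only; no computed
#'   statistic depends on it.
#' @param seed Integer seed for the optional shuffle.
#' @return A list of 30 [voltage_stimulus()] objects (5 types x 6 frequencies
#'   by default).
#' @export
experiment_grid <- function(frequencies = c(0.05, 0.1, 0.25, 0.5, 1, 2.5),
                            periods = 3L, samples_per_period = 500L,
                            randomize = FALSE, seed = NULL) {
  types <- list(
    list(kind = "sinusoidal",    amplitude = 0.4),
    list(kind = "sinusoidal",    amplitude = 0.8),
    list(kind = "sinusoidal",    amplitude = 1.2),
    list(kind = "triangular",    amplitude = 1.2),
    list(kind = "decaying_sine", amplitude = 1.2)
  )
  if (randomize && is.null(seed)) {
    ms_stop("`randomize = TRUE` requires a `seed`", "invalid_parameter")
  }
  with_local_seed(if (randomize) seed else NULL, {
    type_order <- if (randomize) sample(length(types)) else seq_along(types)
    out <- list()
    for (ti in type_order) {
      freq_order <- if (randomize) sample(frequencies) else frequencies
      for (f in freq_order) {
        sgn <- if (randomize) sample(c(-1, 1), 1L) else 1
        out[[length(out) + 1L]] <- voltage_stimulus(
          kind = types[[ti]]$kind, amplitude = types[[ti]]$amplitude,
          frequency = f, periods = periods,
          samples_per_period = samples_per_period, sign = sgn)
      }
    }
    out
  })
}
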