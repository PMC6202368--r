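# Per-recording statistics of pinched hysteresis V-I loops.
#
# All metrics are computed on the sign-corrected loop (voltage and current
# multiplied by the stimulus sign), so that a negative-polarity stimulus is
# analysed in the same orientation as a positive one.

sign_corrected <- function(per) {
  s <- per$stimulus$sign
  list(v = s * per$v, i = s * per$i)
}

#' Extract one period from a recording
#'
#' Returns the contiguous `samples_per_period` samples of the requested
#' period with time re-zeroed. Loop statistics are conventionally evaluated
#' on the third (last) period, by which the loop shape has stabilised.
#'
#' @param rec A [recording()] of a periodic stimulus.
#' @param period_index Period to extract, `1..periods`.
#' @return A [recording()] holding one period (`stimulus$periods == 1`).
#' @export
extract_period <- function(rec, period_index) {
  if (!inherits(rec, "skin_recording")) {
    ms_stop("`rec` must be a skin_recording", "invalid_parameter")
  }
  stim <- rec$stimulus
  if (stim$kind == "decaying_sine") {
    ms_stop("period extraction is not defined for the non-periodic decaying_sine stimulus",
            "unsupported_stimulus")
  }
  if (length(period_index) != 1L || period_index < 1L ||
      period_index > stim$periods || period_index != as.integer(period_index)) {
    ms_stop(sprintf("`period_index` must be an integer in 1..%d", stim$periods),
            "invalid_index")
  }
  spp <- stim$samples_per_period
  sel <- ((period_index - 1L) * spp + 1L):(period_index * spp)
  stim1 <- stim
  stim1$periods <- 1L
  recording(subject_id = rec$subject_id, site = rec$site, stimulus = stim1,
            t = rec$t[sel] - rec$t[sel[1]], v = rec$v[sel], i = rec$i[sel],
            state = if (!is.null(rec$state)) rec$state[sel, , drop = FALSE],
            extra = rec$extra)
}

# Indices of the ascending-voltage branch ending at the global voltage
# maximum, walked back cyclically while v is non-increasing backwards,
# stopping once a non-positive voltage sample has been included.
ascending_branch <- function(w) {
  n <- length(w)
  m <- which.max(w)
  tiny <- 1e-12 * max(abs(w))
  idx <- integer(n)
  idx[n] <- m
  top <- n
  k <- m
  for (step in seq_len(n - 1L)) {
    p <- if (k == 1L) n else k - 1L
    if (w[p] > w[k] + tiny) break
    top <- top - 1L
    idx[top] <- p
    k <- p
    if (w[p] <= 0) break
  }
  idx[top:n]
}

#' Non-linearity parameter of one V-I loop period
#'
#' The non-linearity statistic
#' `NL = (i_max - i(0.5 v_max)) / (i(0.75 v_max) - i(0.5 v_max))`,
#' where `v_max` is the stimulus amplitude, `i_max` is the global maximum of
#' the current over the period (preferred over `i(v_max)` because the
#' memristive state keeps changing past the voltage peak), and the two
#' intermediate currents are linearly interpolated on the ascending-voltage
#' branch in the first quadrant. A purely resistive in-phase response gives
#' `NL = 2`; memristive loops give larger values; a phase lead of the
#' current reduces it below 2. The ratio is insensitive to a DC offset of
#' the current (as long as the offset does not relocate the global maximum).
#'
#' @param per One period, as returned by [extract_period()], of a sinusoidal
#'   or triangular stimulus.
#' @param v_max Reference voltage amplitude; defaults to the stimulus
#'   amplitude.
#' @param denom_floor Smallest admissible denominator magnitude in amperes;
#'   below it the loop is reported as degenerate.
#' @return The dimensionless NL value.
#' @examples
#' th <- 2 * pi * (0:499) / 500
#' stim <- voltage_stimulus("sinusoidal", 1, 2.5, periods = 1)
#' rec <- recording("ex", "forehead", stim, t = th / (2 * pi * 2.5),
#'                  v = sin(th), i = 1e-5 * sin(th + 2.1 * pi / 180))
#' non_linearity(rec)  # ~1.93: a 2.1 degree phase lead biases NL below 2
#' @export
non_linearity <- function(per, v_max = NULL, denom_floor = 1e-12) {
  if (!inherits(per, "skin_recording")) {
    ms_stop("`per` must be a skin_recording", "invalid_parameter")
  }
  if (per$stimulus$kind == "decaying_sine" && is.null(v_max)) {
    ms_stop("NL needs an explicit `v_max` for non-periodic stimuli",
            "unsupported_stimulus")
  }
  if (is.null(v_max)) v_max <- per$stimulus$amplitude
  sc <- sign_corrected(per)
  w <- sc$v
  j <- sc$i
  br <- ascending_branch(w)
  if (max(w[br]) < 0.75 * v_max || min(w[br]) > 0.5 * v_max) {
    ms_stop("ascending-voltage branch does not span [0.5, 0.75] * v_max",
            "invalid_period")
  }
  i_ref <- stats::approx(w[br], j[br], xout = c(0.5, 0.75) * v_max,
                         ties = mean)$y
  denom <- i_ref[2] - i_ref[1]
  if (abs(denom) < denom_floor) {
    ms_stop(sprintf("degenerate loop: |i(0.75 v_max) - i(0.5 v_max)| < %g A",
                    denom_floor), "degenerate_loop")
  }
  (max(j) - i_ref[1]) / denom
}

#' Maximum current and its phase angle
#'
#' Global maximum of the (sign-corrected) current over one period and the
#' phase angle `360 * t / T` at which it occurs. For memristive loops the
#' angle exceeds 90 degrees: the state keeps growing after the voltage peak.
#' Ties are broken to the earliest sample.
#'
#' @param per One period, as returned by [extract_period()].
#' @return A list with `i_max` (amperes) and `angle` (degrees).
#' @export
max_current <- function(per) {
  sc <- sign_corrected(per)
  idx <- which.max(sc$i)
  list(i_max = sc$i[idx],
       angle = 360 * (per$t[idx] - per$t[1]) * per$stimulus$frequency)
}

#' Lobe area of a pinched hysteresis loop
#'
#' Total unsigned area enclosed by the loop's lobes. The closed V-I curve is
#' split at its two voltage extrema into an ascending and a descending
#' branch; both are resampled onto a common uniform voltage grid per
#' voltage-sign region (`n_grid` nodes each for v >= 0 and v < 0), and per
#' grid step the absolute difference of the two branches' trapezoid areas is
#' accumulated. Taking absolute values stepwise keeps contributions on both
#' sides of the pinched point positive, so the result is the sum of the lobe
#' areas regardless of where the pinch sits. If a branch is not monotone in
#' voltage after splitting (self-looping artifact), the routine falls back
#' to the polygon decomposition of [lobe_area_polygon()] with a warning.
#'
#' @param per One period, as returned by [extract_period()].
#' @param n_grid Number of voltage nodes per sign region (default 500).
#' @return A list with `a_total` (ampere volts), `a_pos` and `a_neg` (the
#'   v >= 0 and v < 0 contributions; `NA` when the polygon fallback was
#'   used) and `method`.
#' @export
lobe_area <- function(per, n_grid = 500L) {
  sc <- sign_corrected(per)
  w <- sc$v
  j <- sc$i
  n <- length(w)
  im <- which.max(w)
  il <- which.min(w)
  cyc <- function(a, b) if (a <= b) a:b else c(a:n, 1:b)
  asc <- cyc(il, im)
  des <- cyc(im, il)
  if (any(diff(w[asc]) < 0) || any(diff(w[des]) > 0)) {
    ms_warn("non-monotone branch after splitting at the voltage extrema; falling back to polygon decomposition",
            "branch_fallback")
    return(list(a_total = lobe_area_polygon(per), a_pos = NA_real_,
                a_neg = NA_real_, method = "polygon"))
  }
  region <- function(lo, hi) {
    if (hi - lo <= 0) return(0)
    grid <- seq(lo, hi, length.out = n_grid)
    ia <- stats::approx(w[asc], j[asc], xout = grid, ties = mean, rule = 2)$y
    id <- stats::approx(w[des], j[des], xout = grid, ties = mean, rule = 2)$y
    dv <- diff(grid)
    sum(abs(0.5 * dv * (ia[-1] + ia[-n_grid] - id[-1] - id[-n_grid])))
  }
  a_pos <- region(max(0, w[il]), max(0, w[im]))
  a_neg <- region(min(0, w[il]), min(0, w[im]))
  list(a_total = a_pos + a_neg, a_pos = a_pos, a_neg = a_neg,
       method = "resample")
}

#' Lobe area by polygon decomposition
#'
#' Independent geometric route to the lobe area: the closed V-I polyline is
#' decomposed at its self-intersections into simple loops and the absolute
#' shoelace areas of the loops are summed. Used as cross-check and as
#' fallback of [lobe_area()] for non-monotone branches.
#'
#' @param per One period ([extract_period()]), or a list with `v` and `i`.
#' @return Total unsigned enclosed area in ampere volts.
#' @export
lobe_area_polygon <- function(per) {
  decompose_loop_area(per$v, per$i)
}

#' Detect pinched points of a V-I loop
#'
#' Brute-force segment-pair intersection over the closed V-I polyline
#' (endpoint gap closed). Intersections closer than `merge_frac` of the data
#' range per axis are clustered into one pinched point. At each pinch, the
#' local direction of either branch is estimated over `slope_window` samples
#' on each side (principal axis in range-normalised coordinates); the pinch
#' is flagged tangential when the two branch directions agree within
#' `tangent_tol_deg` degrees of arc, transversal otherwise.
#'
#' @param per One period, as returned by [extract_period()].
#' @param merge_frac Cluster radius as a fraction of the per-axis data range.
#' @param slope_window Half-width, in samples, of the local slope fit.
#' @param tangent_tol_deg Angular tolerance for the tangential flag.
#' @return A data.frame with one row per pinch: `v`, `i`, `angle1`, `angle2`
#'   (branch directions, degrees, in normalised coordinates) and
#'   `tangential`.
#' @export
detect_pinch_points <- function(per, merge_frac = 0.01, slope_window = 5L,
                                tangent_tol_deg = 15) {
  v <- per$v
  i <- per$i
  n <- length(v)
  if (n < 8L) ms_stop("need at least 8 samples to detect pinch points",
                      "insufficient_data")
  rv <- max(diff(range(v)), 1e-300)
  ri <- max(diff(range(i)), 1e-300)
  vn <- (v - min(v)) / rv
  jn <- (i - min(i)) / ri
  ints <- poly_self_intersections(vn, jn)
  empty <- data.frame(v = numeric(), i = numeric(), angle1 = numeric(),
                      angle2 = numeric(), tangential = logical())
  if (nrow(ints) == 0L) return(empty)
  lab <- cluster_points(ints$x, ints$y, merge_frac, merge_frac)

  branch_angle <- function(seg) {
    sel <- ((seg - slope_window):(seg + 1L + slope_window) - 1L) %% n + 1L
    px <- vn[sel]
    py <- jn[sel]
    cm <- cbind(px - mean(px), py - mean(py))
    ev <- eigen(crossprod(cm), symmetric = TRUE)$vectors[, 1]
    (atan2(ev[2], ev[1]) * 180 / pi) %% 180
  }
  out <- lapply(sort(unique(lab)), function(cl) {
    rows <- which(lab == cl)
    r <- rows[1]
    a1 <- branch_angle(ints$seg1[r])
    a2 <- branch_angle(ints$seg2[r])
    d <- abs(a1 - a2)
    d <- min(d, 180 - d)
    data.frame(v = mean(ints$x[rows]) * rv + min(v),
               i = mean(ints$y[rows]) * ri + min(i),
               angle1 = a1, angle2 = a2, tangential = d <= tangent_tol_deg)
  })
  do.call(rbind, out)
}

#' Phase shift of a linear RC response
#'
#' For a conductance `g` in parallel with a capacitance `c` under a
#' sinusoidal voltage of frequency `f`, the current leads the voltage by
#' `alpha = atan(2 * pi * f * c / g)`.
#'
#' @param g Conductance, siemens (> 0).
#' @param c Capacitance, farads (>= 0).
#' @param f Frequency, hertz (>= 0).
#' @return Phase shift in degrees.
#' @examples
#' phase_shift(6.7e-6, 15.6e-9, 0.05)  # ~0.04 degrees
#' phase_shift(6.7e-6, 15.6e-9, 2.5)   # ~2.1 degrees
#' @export
phase_shift <- function(g, c, f) {
  if (!is.numeric(g) || any(g <= 0)) {
    ms_stop("`g` must be positive", "invalid_parameter")
  }
  check_nonneg_scalar(c, "c")
  check_nonneg_scalar(f, "f")
  atan(2 * pi * f * c / g) * 180 / pi
}

#' State-dependent phase shift along a conductance trajectory
#'
#' Elementwise `atan(2 * pi * f * c / G)` for a state-dependent conductance:
#' as the memductance grows during a non-linear measurement, the capacitive
#' phase lead shrinks.
#'
#' @param g Either a numeric vector of conductances (siemens, > 0) or a
#'   function mapping `states` to conductances.
#' @param c Capacitance, farads.
#' @param f Frequency, hertz.
#' @param states Optional state trajectory passed to `g` when it is a
#'   function.
#' @return Vector of phase shifts in degrees.
#' @export
state_dependent_phase_shift <- function(g, c, f, states = NULL) {
  if (is.function(g)) g <- g(states)
  if (!is.numeric(g) || any(g <= 0)) {
    ms_stop("conductance trajectory must be positive", "invalid_parameter")
  }
  check_nonneg_scalar(c, "c")
  check_nonneg_scalar(f, "f")
  atan(2 * pi * f * c / g) * 180 / pi
}

#' Lock-in small-signal admittance
#'
#' Demodulates the measured current against in-phase and quadrature
#' references at the stimulus frequency, averaging over whole periods:
#' `g = 2 * mean(i * sin) / amplitude`, `b = 2 * mean(i * cos) / amplitude`,
#' and the equivalent parallel capacitance `c = b / (2 * pi * f)`. This is
#' the standard technique for separating conductance and susceptance in a
#' linear small-signal measurement (e.g. 100 mV at 20 Hz).
#'
#' @param rec A [recording()] of a sinusoidal stimulus covering at least one
#'   whole period. A trailing partial period is truncated with a warning.
#' @return An object of class `admittance_measurement`: list with `g`, `b`
#'   (siemens), `c` (farads) and `f` (hertz).
#' @export
lockin_admittance <- function(rec) {
  stim <- rec$stimulus
  if (stim$kind != "sinusoidal") {
    ms_stop("lock-in demodulation requires a sinusoidal stimulus",
            "unsupported_stimulus")
  }
  spp <- stim$samples_per_period
  n <- length(rec$t)
  whole <- (n %/% spp) * spp
  if (whole == 0L) ms_stop("recording shorter than one period", "validation")
  if (whole < n) {
    ms_warn(sprintf("truncating %d samples beyond the last whole period",
                    n - whole), "partial_period")
  }
  sel <- seq_len(whole)
  ph <- 2 * pi * stim$frequency * (rec$t[sel] - rec$t[1])
  a <- stim$sign * stim$amplitude
  g <- 2 * mean(rec$i[sel] * sin(ph)) / a
  b <- 2 * mean(rec$i[sel] * cos(ph)) / a
  structure(list(g = g, b = b, c = b / (2 * pi * stim$frequency),
                 f = stim$frequency),
            class = "admittance_measurement")
}

#' @export
print.admittance_measurement <- function(x, ...) {
  cat(sprintf("<admittance_measurement> G = %.4g S, B = %.4g S (C = %.4g F) at %g Hz\n",
              x$g, x$b, x$c, x$f))
  invisible(x)
}

# Signed shoelace areas of the first- and third-quadrant sub-loops,
# delimited by the sign of the (sign-corrected) voltage.
quadrant_signed_areas <- function(per) {
  sc <- sign_corrected(per)
  sub <- function(keep) {
    if (sum(keep) < 3L) return(NA_real_)
    shoelace_signed(sc$v[keep], sc$i[keep])
  }
  c(q1 = sub(sc$v >= 0), q3 = sub(sc$v < 0))
}

#' All loop metrics for one recording period
#'
#' Convenience wrapper computing the full per-period statistics row: NL,
#' lobe area (absolute and normalised by the maximum current), maximum
#' current and its phase angle, pinched-point count and tangential flag, and
#' the signed areas of the first- and third-quadrant sub-loops
#' (positive = counter-clockwise).
#'
#' @param rec A [recording()].
#' @param period_index Period to analyse (default 3, the stabilised loop).
#' @return A one-row data.frame.
#' @export
loop_metrics <- function(rec, period_index = 3L) {
  per <- extract_period(rec, period_index)
  nl <- tryCatch(non_linearity(per), memskin_error = function(e) NA_real_)
  la <- lobe_area(per)
  mc <- max_current(per)
  pp <- tryCatch(detect_pinch_points(per),
                 memskin_error = function(e) NULL)
  qa <- quadrant_signed_areas(per)
  data.frame(
    subject_id = rec$subject_id, site = rec$site,
    kind = rec$stimulus$kind, amplitude = rec$stimulus$amplitude,
    frequency = rec$stimulus$frequency, sign = rec$stimulus$sign,
    period = as.integer(period_index), nl = nl,
    lobe_area = la$a_total,
    lobe_area_normalized = la$a_total / mc$i_max,
    i_max = mc$i_max, i_max_angle = mc$angle,
    n_pinch = if (is.null(pp)) NA_integer_ else nrow(pp),
    tangential = if (is.null(pp) || nrow(pp) == 0L) NA else all(pp$tangential),
    q1_signed_area = qa[["q1"]], q3_signed_area = qa[["q3"]],
    stringsAsFactors = FALSE)
}

#' Loop metrics for a set of recordings
#'
#' Applies [loop_metrics()] to every periodic recording in a list. Recordings
#' of the non-periodic decaying-sine stimulus are skipped (per-period loop
#' statistics are not defined for them), and recordings that fail to analyse
#' are collected rather than aborting the batch.
#'
#' @param recs List of [recording()] objects.
#' @param period_index Period to analyse (default 3).
#' @return A data.frame with one row per analysed recording; skipped and
#'   failed recordings are reported in attributes `skipped` and `failures`.
#' @export
analyze_recordings <- function(recs, period_index = 3L) {
  rows <- list()
  skipped <- character(0)
  failures <- character(0)
  for (k in seq_along(recs)) {
    rec <- recs[[k]]
    if (rec$stimulus$kind == "decaying_sine") {
      skipped <- c(skipped, sprintf("%s/%s/#%d (decaying_sine)",
                                    rec$subject_id, rec$site, k))
      next
    }
    row <- tryCatch(withCallingHandlers(
      loop_metrics(rec, period_index),
      memskin_warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) {
        failures <<- c(failures, sprintf("%s/%s/#%d: %s", rec$subject_id,
                                         rec$site, k, conditionMessage(e)))
        NULL
      })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "skipped") <- skipped
  attr(out, "failures") <- failures
  out
}
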