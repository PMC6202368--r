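# Population-level aggregation of loop metrics.

#' Amplitude-specific noise exclusion filter
#'
#' Drops rows whose maximum current falls below the amplitude-specific noise
#' threshold (defaults 2.1, 1.4 and 0.7 uA at 1.2, 0.8 and 0.4 V). The
#' comparison is strict: rows exactly at the threshold are retained. For
#' amplitudes without a configured threshold, a linear rate of 1.75 uA per
#' volt is applied and noted in the log.
#'
#' @param rows A loop-metrics data.frame with `amplitude` and `i_max`
#'   columns (see [analyze_recordings()]).
#' @param thresholds Named vector mapping amplitude (volts, as names) to the
#'   exclusion threshold in amperes.
#' @param rate Fallback threshold slope in amperes per volt.
#' @return A list with `kept` (the filtered table) and `log` (a data.frame
#'   recording every dropped row's key and the threshold applied).
#' @export
exclusion_filter <- function(rows,
                             thresholds = c("0.4" = 0.7e-6, "0.8" = 1.4e-6,
                                            "1.2" = 2.1e-6),
                             rate = 1.75e-6) {
  if (nrow(rows) == 0L) {
    return(list(kept = rows, log = data.frame()))
  }
  amp_key <- as.character(rows$amplitude)
  thr <- unname(thresholds[amp_key])
  fallback <- is.na(thr)
  thr[fallback] <- rate * rows$amplitude[fallback]
  drop <- rows$i_max < thr
  log <- data.frame()
  if (any(drop | fallback)) {
    log <- data.frame(
      subject_id = rows$subject_id, site = rows$site,
      amplitude = rows$amplitude, frequency = rows$frequency,
      i_max = rows$i_max, threshold = thr,
      excluded = drop,
      note = ifelse(fallback, "threshold scaled at 1.75 uA/V", ""),
      stringsAsFactors = FALSE)[drop | fallback, , drop = FALSE]
  }
  list(kept = rows[!drop, , drop = FALSE], log = log)
}

# Percentile by linear interpolation between order statistics (R's default
# quantile definition, type 7).
pctl <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

#' Grouped cohort summaries
#'
#' Per (site, waveform, amplitude, frequency) group: the number of retained
#' observations and mean, median, 5% and 95% percentiles of
#' `log10(lobe_area)`, `log10(i_max)` and NL. The log10 transform reduces
#' the strong between-subject skew of area and current. Percentiles use
#' linear interpolation between order statistics; groups with fewer than two
#' observations get `NA` percentiles and are flagged.
#'
#' @param rows A filtered loop-metrics data.frame.
#' @return A data.frame with one row per group, columns
#'   `<metric>_<stat>` for metric in `log_lobe`, `log_imax`, `nl` and stat
#'   in `mean`, `median`, `p5`, `p95`, plus `n` and `small_group`.
#' @export
summarize_cohort <- function(rows) {
  if (nrow(rows) == 0L) return(data.frame())
  key <- interaction(rows$site, rows$kind, rows$amplitude, rows$frequency,
                     drop = TRUE)
  groups <- split(rows, key)
  out <- lapply(groups, function(g) {
    stats_of <- function(x, prefix) {
      small <- length(x) < 2L
      s <- c(mean(x), stats::median(x),
             if (small) c(NA_real_, NA_real_) else c(pctl(x, 0.05), pctl(x, 0.95)))
      names(s) <- paste0(prefix, "_", c("mean", "median", "p5", "p95"))
      s
    }
    cbind(
      data.frame(site = g$site[1], kind = g$kind[1],
                 amplitude = g$amplitude[1], frequency = g$frequency[1],
                 n = nrow(g), small_group = nrow(g) < 2L,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(c(stats_of(log10(g$lobe_area), "log_lobe"),
                              stats_of(log10(g$i_max), "log_imax"),
                              stats_of(g$nl, "nl")))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$site, out$kind, out$amplitude, out$frequency), , drop = FALSE]
}

#' Random-intercept mixed model for the non-linearity parameter
#'
#' Fits `nl ~ 1 + amplitude + log2(frequency) + (1 | subject)` by restricted
#' maximum likelihood (REML), with the absolute voltage amplitude and the
#' base-2 log of frequency as fixed effects and a per-subject random
#' intercept. The frequency coefficient is reported per unit `log2(f)`; a
#' frequency bisection is one unit decrease of `log2(f)`, so a positive
#' effect of bisection corresponds to a negative coefficient here.
#'
#' 95% confidence intervals are profile-likelihood by default (`"Wald"`
#' available for speed). Degrees-of-freedom-based p-values are deliberately
#' not reported; inference is via the CIs.
#'
#' @param rows Loop-metrics data.frame (typically period-3 sinusoidal rows
#'   after [exclusion_filter()]) with columns `nl`, `amplitude`, `frequency`
#'   and `subject_id`, without missing NL values.
#' @param ci_method `"profile"` (default) or `"Wald"`.
#' @return An object of class `lmm_fit`: coefficients, `ci` (2-column
#'   matrix), `ci_half` (half-widths), variance components, `n_obs`,
#'   `n_subjects` and the underlying `lme4` fit in `$model`.
#' @export
fit_nl_mixed_model <- function(rows, ci_method = c("profile", "Wald")) {
  ci_method <- match.arg(ci_method)
  rows <- rows[!is.na(rows$nl), , drop = FALSE]
  d <- data.frame(nl = rows$nl, amplitude = abs(rows$amplitude),
                  log2f = log2(rows$frequency),
                  subject = factor(rows$subject_id))
  if (nlevels(d$subject) < 2L) {
    ms_stop("rank-deficient design: need at least 2 subjects", "rank_deficiency")
  }
  if (length(unique(d$amplitude)) < 2L) {
    ms_stop("rank-deficient design: need at least 2 amplitude levels",
            "rank_deficiency")
  }
  if (length(unique(d$log2f)) < 2L) {
    ms_stop("rank-deficient design: need at least 2 frequencies",
            "rank_deficiency")
  }
  fit <- lme4::lmer(nl ~ amplitude + log2f + (1 | subject), data = d,
                    REML = TRUE)
  beta <- lme4::fixef(fit)
  ci <- suppressMessages(
    stats::confint(fit, parm = names(beta), method = ci_method, quiet = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    beta_intercept = unname(beta["(Intercept)"]),
    beta_amplitude = unname(beta["amplitude"]),
    beta_log2freq = unname(beta["log2f"]),
    ci = ci,
    ci_half = (ci[, 2] - ci[, 1]) / 2,
    var_subject = vc$vcov[vc$grp == "subject"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    n_obs = nrow(d),
    n_subjects = nlevels(d$subject),
    ci_method = ci_method,
    model = fit), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> NL ~ amplitude + log2(frequency) + (1 | subject), REML\n")
  cat(sprintf("  intercept    %8.4f  [%.4f, %.4f]\n", x$beta_intercept,
              x$ci["(Intercept)", 1], x$ci["(Intercept)", 2]))
  cat(sprintf("  amplitude    %8.4f  [%.4f, %.4f]  per volt\n",
              x$beta_amplitude, x$ci["amplitude", 1], x$ci["amplitude", 2]))
  cat(sprintf("  log2(freq)   %8.4f  [%.4f, %.4f]  per doubling\n",
              x$beta_log2freq, x$ci["log2f", 1], x$ci["log2f", 2]))
  cat(sprintf("  var(subject) %.4g, var(resid) %.4g, n_obs %d, subjects %d (%s CIs)\n",
              x$var_subject, x$var_residual, x$n_obs, x$n_subjects,
              x$ci_method))
  invisible(x)
}

#' Boundary between the linear and non-linear measurement range
#'
#' For each frequency, the smallest tested amplitude whose group statistic
#' exceeds the NL threshold (default 2.05): above this amplitude the cohort
#' measurement is considered non-linear. `rule = "median"` uses the group
#' median (cohort-level boundary); `rule = "p5"` uses the lower 5% whisker,
#' delimiting the region where more than 95% of subjects are non-linear.
#'
#' @param summaries Output of [summarize_cohort()], restricted to one site
#'   and waveform over a rectangular amplitude x frequency grid.
#' @param threshold NL level above which a group is non-linear.
#' @param rule `"median"` or `"p5"`.
#' @return A data.frame with one row per frequency: `frequency`, `amplitude`
#'   (the boundary, `NA` when no tested amplitude is non-linear),
#'   `threshold` and `rule`.
#' @export
boundary_map <- function(summaries, threshold = 2.05,
                         rule = c("median", "p5")) {
  rule <- match.arg(rule)
  stat_col <- if (rule == "median") "nl_median" else "nl_p5"
  freqs <- sort(unique(summaries$frequency))
  amps <- sort(unique(summaries$amplitude))
  cells <- table(summaries$frequency, summaries$amplitude)
  if (any(cells == 0L)) {
    ms_warn("non-rectangular amplitude x frequency grid; missing cells treated as undefined",
            "missing_cells")
  }
  out <- lapply(freqs, function(f) {
    sub <- summaries[summaries$frequency == f, , drop = FALSE]
    sub <- sub[order(sub$amplitude), , drop = FALSE]
    hit <- which(!is.na(sub[[stat_col]]) & sub[[stat_col]] > threshold)
    data.frame(frequency = f,
               amplitude = if (length(hit)) sub$amplitude[hit[1]] else NA_real_,
               threshold = threshold, rule = rule, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
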