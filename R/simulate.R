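#' Simulate one voltage-current recording
#'
#' Integrates the two-state skin circuit (duct filling `x`, stratum-corneum
#' temperature `T`) under the applied stimulus and returns the resulting
#' current
#' `i(t) = (G_D(x) + G_S(T)) * v_eff + c_s * dv/dt + noise`,
#' with `v_eff = v + e_dc`. Integration is fixed-step classical
#' Runge-Kutta (RK4) on the stimulus sample grid with `n_substeps` internal
#' substeps per sample; the waveform is evaluated analytically at the
#' half-substep points, and the capacitive term uses the analytic `dv/dt`.
#'
#' @param params A [skin_circuit_params()] object.
#' @param stim A [voltage_stimulus()].
#' @param seed Integer seed for the additive current noise; `NULL` draws from
#'   the current RNG stream. With `noise_sd = 0` the output is deterministic.
#' @param subject_id,site Metadata stored on the recording.
#' @param n_substeps Internal RK4 substeps per output sample (default 10).
#' @param x_init,t_init Initial state; default baseline filling `x0` and
#'   ambient temperature (fresh-skin initial condition). Pass the final
#'   state of a previous recording to model carry-over between stimuli in a
#'   measurement series.
#' @return A [recording()] with the simulator state trajectories attached as
#'   `$state` (columns `x`, `temperature`).
#' @examples
#' p <- skin_circuit_params(noise_sd = 0)
#' stim <- voltage_stimulus("sinusoidal", 1.2, 0.05)
#' rec <- simulate_recording(p, stim)
#' plot(rec$v, rec$i, type = "l", xlab = "v [V]", ylab = "i [A]")
#' @export
simulate_recording <- function(params, stim, seed = NULL,
                               subject_id = "synthetic", site = "forehead",
                               n_substeps = 10L, x_init = NULL, t_init = NULL) {
  if (!inherits(params, "skin_circuit_params")) {
    ms_stop("`params` must be a skin_circuit_params object", "invalid_parameter")
  }
  if (!inherits(stim, "voltage_stimulus")) {
    ms_stop("`stim` must be a voltage_stimulus", "invalid_parameter")
  }
  check_positive_scalar(n_substeps, "n_substeps")
  d <- params$duct
  s <- params$sc
  if (is.null(x_init)) x_init <- d$x0
  if (is.null(t_init)) t_init <- s$t_amb

  n <- stim_n_samples(stim)
  dt <- stim_dt(stim)
  t <- (seq_len(n) - 1L) * dt
  h2 <- dt / n_substeps / 2
  t_half <- (seq_len(2L * (n - 1L) * n_substeps + 1L) - 1L) * h2
  v_half <- stim_value(stim, t_half) + params$e_dc

  st <- sim_skin_rk4(v_half, n, as.integer(n_substeps), dt,
                     d$g_min, d$g_max, d$x0, d$a_plus, d$a_minus, d$tau_x,
                     s$g_ref, s$b_ntc, s$t_ref, s$t_amb, s$c_th, s$r_th,
                     x_init, t_init)
  if (!all(is.finite(st$x)) || !all(is.finite(st$temperature)) ||
      any(st$temperature <= 0) || any(st$temperature > s$t_amb + 100)) {
    ms_stop(sprintf(paste0(
      "state integration left the physical regime (non-finite state or ",
      "temperature outside (0, t_amb + 100 K]) ",
      "(g_ref = %.3g S, b_ntc = %.3g K, c_th = %.3g J/K, r_th = %.3g K/W); ",
      "the thermal parameters are likely in a runaway regime"),
      s$g_ref, s$b_ntc, s$c_th, s$r_th), "numerical_failure")
  }

  v <- stim_value(stim, t)
  v_eff <- v + params$e_dc
  g_tot <- duct_conductance(d, st$x) + sc_conductance(s, st$temperature)
  i <- g_tot * v_eff + s$c_s * stim_deriv(stim, t)
  if (params$noise_sd > 0) {
    i <- i + with_local_seed(seed, stats::rnorm(n, 0, params$noise_sd))
  }
  recording(subject_id = subject_id, site = site, stimulus = stim,
            t = t, v = v, i = i,
            state = data.frame(x = st$x, temperature = st$temperature))
}

#' Phenotype class defaults
#'
#' Median circuit parameters and between-subject spreads for the five
#' phenotype classes the generator reproduces:
#' * `A` - symmetric pinched loops with relatively large lobes,
#' * `B` - loops with small lobe areas,
#' * `C` - asymmetric loops (large first-quadrant, small third-quadrant lobe),
#' * `D` - loops with a strongly shifted pinched point,
#' * `F` - small, highly symmetric loops with two pinched points (no galvanic
#'   duct contact; stratum-corneum thermistor + capacitance dominate).
#'
#' Values are read from the versioned config shipped in
#' `inst/extdata/phenotype_defaults.json`. They are package choices tuned to
#' reproduce the qualitative phenotypes and cohort ranges, not fits to any
#' subject data.
#'
#' @return Named list of per-class parameter configs (fields: `version`,
#'   `classes`).
#' @export
phenotype_defaults <- function() {
  path <- system.file("extdata", "phenotype_defaults.json", package = "memskin")
  if (path == "") ms_stop("phenotype defaults config not found", "validation")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Population specification
#'
#' Describes a synthetic cohort: number of subjects, mixture weights over the
#' phenotype classes, and a seed. Default weights follow the observed
#' forehead frequencies 6:10:8:1:3 over 28 subjects for classes A, B, C, D, F.
#'
#' @param n_subjects Positive integer.
#' @param class_weights Named probabilities over classes `A,B,C,D,F`, summing
#'   to 1.
#' @param seed Integer seed governing all parameter draws.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 28L,
                            class_weights = c(A = 6, B = 10, C = 8, D = 1, F = 3) / 28,
                            seed = 1L) {
  check_positive_scalar(n_subjects, "n_subjects")
  classes <- c("A", "B", "C", "D", "F")
  if (is.null(names(class_weights)) || !setequal(names(class_weights), classes)) {
    ms_stop("`class_weights` must be named over classes A, B, C, D, F",
            "invalid_spec")
  }
  class_weights <- class_weights[classes]
  if (any(class_weights < 0) || abs(sum(class_weights) - 1) > 1e-9) {
    ms_stop("`class_weights` must be non-negative and sum to 1 (within 1e-9)",
            "invalid_spec")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "population_spec")
}

# Draw one skin_circuit_params from a class config. Positive parameters are
# log-normal around the class median; e_dc is normal; x0 is clipped to [0,1].
draw_class_params <- function(cfg) {
  ln <- function(field) {
    m <- cfg[[field]][["median"]]
    s <- cfg[[field]][["sdlog"]]
    if (m == 0) 0 else stats::rlnorm(1, meanlog = log(m), sdlog = s)
  }
  x0 <- min(1, max(0, stats::rnorm(1, cfg$x0$median, cfg$x0$sd)))
  g_min <- ln("g_min")
  g_max <- g_min + ln("g_span")     # span parametrisation keeps g_max >= g_min
  skin_circuit_params(
    duct = sweat_duct_params(g_min = g_min, g_max = g_max, x0 = x0,
                             a_plus = ln("a_plus"), a_minus = ln("a_minus"),
                             tau_x = ln("tau_x")),
    sc = stratum_corneum_params(g_ref = ln("g_ref"), b_ntc = cfg$b_ntc,
                                t_ref = cfg$t_ref, t_amb = cfg$t_amb,
                                c_th = ln("c_th"), r_th = ln("r_th"),
                                c_s = ln("c_s")),
    e_dc = stats::rnorm(1, cfg$e_dc$mean, cfg$e_dc$sd),
    noise_sd = cfg$noise_sd)
}

#' Sample a synthetic subject population
#'
#' Draws one circuit parameter set per subject from the class-conditional
#' distributions in [phenotype_defaults()], with phenotype classes drawn from
#' the mixture weights. Deterministic given the spec's seed.
#'
#' @param spec A [population_spec()].
#' @return A list with one entry per subject: `subject_id`, `class`, `params`.
#' @export
sample_population <- function(spec) {
  if (!inherits(spec, "population_spec")) {
    ms_stop("`spec` must be a population_spec", "invalid_spec")
  }
  defaults <- phenotype_defaults()$classes
  with_local_seed(spec$seed, {
    classes <- sample(names(spec$class_weights), spec$n_subjects,
                      replace = TRUE, prob = spec$class_weights)
    lapply(seq_len(spec$n_subjects), function(k) {
      list(subject_id = sprintf("S%02d", k), class = classes[k],
           params = draw_class_params(defaults[[classes[k]]]))
    })
  })
}

#' Simulate a full cohort
#'
#' One recording per (subject, stimulus). The circuit state is re-initialised
#' to the fresh-skin condition for every stimulus (set
#' `carry_over = TRUE` to propagate the final state of each recording into
#' the next stimulus of the same subject, emulating the after-effect of a
#' non-linear measurement on subsequent ones). Per-recording noise seeds are
#' derived deterministically from the population seed.
#'
#' @param spec A [population_spec()].
#' @param grid List of stimuli, default [experiment_grid()].
#' @param site Recording site label.
#' @param carry_over Logical; propagate state between consecutive stimuli.
#' @return A list of [recording()] objects of length
#'   `n_subjects * length(grid)`.
#' @export
simulate_cohort <- function(spec, grid = experiment_grid(), site = "forehead",
                            carry_over = FALSE) {
  subjects <- sample_population(spec)
  out <- vector("list", length(subjects) * length(grid))
  idx <- 1L
  for (sj in seq_along(subjects)) {
    sub <- subjects[[sj]]
    x_init <- NULL
    t_init <- NULL
    for (gj in seq_along(grid)) {
      seed_k <- (spec$seed + 7919L * sj + 104729L * gj) %% 2147483647L
      rec <- tryCatch(
        simulate_recording(sub$params, grid[[gj]], seed = seed_k,
                           subject_id = sub$subject_id, site = site,
                           x_init = x_init, t_init = t_init),
        memskin_error = function(e) {
          ms_stop(sprintf("subject %s, stimulus %d: %s",
                          sub$subject_id, gj, conditionMessage(e)),
                  "numerical_failure")
        })
      rec$extra <- list(class = sub$class)
      if (carry_over) {
        ns <- nrow(rec$state)
        x_init <- rec$state$x[ns]
        t_init <- rec$state$temperature[ns]
      }
      out[[idx]] <- rec
      idx <- idx + 1L
    }
  }
  out
}
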