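# Shared fixtures: canonical parameter sets and analytic loops.

# Duct-memristor-only circuit: no stratum-corneum conduction, no capacitance,
# no DC offset, no noise. Deterministic pinched transversal loops.
duct_only_params <- function(a_plus = 0.05, a_minus = 0.05) {
  skin_circuit_params(
    duct = sweat_duct_params(g_min = 5e-6, g_max = 30e-6, x0 = 0.2,
                             a_plus = a_plus, a_minus = a_minus, tau_x = 4),
    sc = stratum_corneum_params(g_ref = 0, b_ntc = 0, c_s = 0),
    e_dc = 0, noise_sd = 0)
}

# Stratum-corneum thermistor circuit (no duct contact), optional capacitance.
thermistor_params <- function(c_s = 0) {
  skin_circuit_params(
    duct = sweat_duct_params(g_min = 0, g_max = 0, a_plus = 0, a_minus = 0),
    sc = stratum_corneum_params(g_ref = 4e-6, b_ntc = 3000,
                                c_th = 1e-5, r_th = 3e5, c_s = c_s),
    e_dc = 0, noise_sd = 0)
}

# One period of a sinusoidal stimulus with an arbitrary analytic current.
analytic_loop <- function(i_fun, amplitude = 1, frequency = 2.5, n = 500L) {
  stim <- voltage_stimulus("sinusoidal", amplitude, frequency, periods = 1L,
                           samples_per_period = n)
  wf <- generate_waveform(stim)
  theta <- 2 * pi * frequency * wf$time
  recording("analytic", "forehead", stim, wf$time, wf$voltage, i_fun(theta))
}

# Linear current with a phase lead (degrees), conductance G.
linear_loop <- function(phase_deg = 0, g = 1e-5, amplitude = 1,
                        frequency = 2.5, n = 500L) {
  analytic_loop(function(th) g * amplitude * sin(th + phase_deg * pi / 180),
                amplitude = amplitude, frequency = frequency, n = n)
}

# NL = 2 + 0.33 * amplitude - 0.075 * log2(f) + subject intercept + noise;
# the generating model of the mixed-model recovery check.
nl_cohort_table <- function(n_subjects = 28, intercept_sd = 0.1,
                            noise_sd = 0.05,
                            amplitudes = c(0.4, 0.8, 1.2),
                            frequencies = c(0.05, 0.1, 0.25, 0.5, 1, 2.5)) {
  ids <- sprintf("S%02d", seq_len(n_subjects))
  d <- expand.grid(subject_id = ids, amplitude = amplitudes,
                   frequency = frequencies, stringsAsFactors = FALSE)
  b <- stats::rnorm(n_subjects, 0, intercept_sd)
  names(b) <- ids
  d$nl <- 2 + 0.33 * d$amplitude - 0.075 * log2(d$frequency) +
    b[d$subject_id] + stats::rnorm(nrow(d), 0, noise_sd)
  d
}
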