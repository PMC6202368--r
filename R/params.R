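#' Sweat-duct memristor parameters
#'
#' The sweat-duct pathway is modelled as a memristor whose memductance
#' `G_D(x) = g_min + (g_max - g_min) * x` tracks a dimensionless duct-filling
#' state `x` in `[0, 1]`. The state is driven by the effective voltage
#' (electro-osmotic filling during the positive half-cycle, draining during
#' the negative one) with separate fill/drain gains, plus first-order
#' relaxation back to the baseline filling `x0`:
#' `dx/dt = a(v) * v - (x - x0) / tau_x`, where `a(v)` is `a_plus` for
#' `v > 0` and `a_minus` otherwise.
#'
#' @param g_min Memductance at empty ducts, siemens (>= 0).
#' @param g_max Memductance at full ducts, siemens (> `g_min`, or equal for a
#'   state-independent pathway).
#' @param x0 Baseline duct filling, dimensionless in `[0, 1]`.
#' @param a_plus Fill gain, 1/(volt second) (>= 0).
#' @param a_minus Drain gain, 1/(volt second) (>= 0).
#' @param tau_x Relaxation time of duct filling, seconds (> 0).
#' @return An object of class `sweat_duct_params`.
#' @export
sweat_duct_params <- function(g_min = 5e-6, g_max = 30e-6, x0 = 0.2,
                              a_plus = 0.05, a_minus = 0.05, tau_x = 4) {
  check_nonneg_scalar(g_min, "g_min")
  check_nonneg_scalar(g_max, "g_max")
  if (g_max < g_min) ms_stop("`g_max` must be >= `g_min`", "invalid_parameter")
  check_nonneg_scalar(x0, "x0")
  if (x0 > 1) ms_stop("`x0` must lie in [0, 1]", "invalid_parameter")
  check_nonneg_scalar(a_plus, "a_plus")
  check_nonneg_scalar(a_minus, "a_minus")
  check_positive_scalar(tau_x, "tau_x")
  structure(list(g_min = g_min, g_max = g_max, x0 = x0,
                 a_plus = a_plus, a_minus = a_minus, tau_x = tau_x),
            class = "sweat_duct_params")
}

#' Stratum-corneum parameters (NTC thermistor + capacitance)
#'
#' The stratum corneum is modelled as a negative-temperature-coefficient
#' conductance `G_S(T) = g_ref * exp(-b_ntc * (1/T - 1/t_ref))` (Arrhenius
#' form, non-decreasing in temperature) in parallel with a capacitance
#' `c_s`. The layer temperature follows a lumped thermal balance between
#' Joule heating and conduction to ambient:
#' `dT/dt = (G_S(T) * v^2 - (T - t_amb) / r_th) / c_th`.
#'
#' @param g_ref Conductance at the reference temperature, siemens (>= 0).
#' @param b_ntc Thermistor sensitivity coefficient, kelvin (>= 0).
#' @param t_ref Reference temperature, kelvin.
#' @param t_amb Ambient (baseline skin) temperature, kelvin.
#' @param c_th Thermal heat capacity, joules/kelvin (> 0).
#' @param r_th Thermal resistance to ambient, kelvin/watt (> 0).
#' @param c_s Stratum-corneum capacitance, farads (>= 0).
#' @return An object of class `stratum_corneum_params`.
#' @export
stratum_corneum_params <- function(g_ref = 2e-6, b_ntc = 3000,
                                   t_ref = 306.15, t_amb = 306.15,
                                   c_th = 2e-4, r_th = 5e4, c_s = 15.6e-9) {
  check_nonneg_scalar(g_ref, "g_ref")
  check_nonneg_scalar(b_ntc, "b_ntc")
  check_positive_scalar(t_ref, "t_ref")
  check_positive_scalar(t_amb, "t_amb")
  check_positive_scalar(c_th, "c_th")
  check_positive_scalar(r_th, "r_th")
  check_nonneg_scalar(c_s, "c_s")
  structure(list(g_ref = g_ref, b_ntc = b_ntc, t_ref = t_ref, t_amb = t_amb,
                 c_th = c_th, r_th = r_th, c_s = c_s),
            class = "stratum_corneum_params")
}

#' Full skin circuit parameters
#'
#' Combines the sweat-duct memristor, the stratum-corneum thermistor and
#' capacitance, a DC offset (endogenous skin potential plus electrode
#' half-cell potentials, entering as a series EMF so the element voltage is
#' `v + e_dc`), and additive Gaussian current-measurement noise.
#'
#' @param duct A [sweat_duct_params()] object.
#' @param sc A [stratum_corneum_params()] object.
#' @param e_dc DC offset voltage, volts (any sign).
#' @param noise_sd Standard deviation of additive current noise, amperes
#'   (>= 0, default 50 nA).
#' @return An object of class `skin_circuit_params`.
#' @export
skin_circuit_params <- function(duct = sweat_duct_params(),
                                sc = stratum_corneum_params(),
                                e_dc = 0, noise_sd = 5e-8) {
  if (!inherits(duct, "sweat_duct_params")) {
    ms_stop("`duct` must be a sweat_duct_params object", "invalid_parameter")
  }
  if (!inherits(sc, "stratum_corneum_params")) {
    ms_stop("`sc` must be a stratum_corneum_params object", "invalid_parameter")
  }
  if (!is.numeric(e_dc) || length(e_dc) != 1L || !is.finite(e_dc)) {
    ms_stop("`e_dc` must be a finite scalar", "invalid_parameter")
  }
  check_nonneg_scalar(noise_sd, "noise_sd")
  structure(list(duct = duct, sc = sc, e_dc = e_dc, noise_sd = noise_sd),
            class = "skin_circuit_params")
}

#' Sweat-duct memductance G_D(x)
#' @param duct A [sweat_duct_params()] object.
#' @param x Duct-filling state(s) in `[0, 1]`.
#' @return Memductance in siemens.
#' @export
duct_conductance <- function(duct, x) {
  duct$g_min + (duct$g_max - duct$g_min) * x
}

#' Stratum-corneum conductance G_S(T)
#' @param sc A [stratum_corneum_params()] object.
#' @param temperature Temperature(s) in kelvin.
#' @return Conductance in siemens.
#' @export
sc_conductance <- function(sc, temperature) {
  sc$g_ref * exp(-sc$b_ntc * (1 / temperature - 1 / sc$t_ref))
}

#' Small-signal mem-admittance about an equilibrium state
#'
#' About a quiescent state `(x_q, t_q)` the parallel circuit has admittance
#' `Y = G_D(x_q) + G_S(t_q) + j * 2 * pi * f * c_s`: a real conductance from
#' both state-dependent pathways plus the capacitive susceptance.
#'
#' @param params A [skin_circuit_params()] object.
#' @param x_q Quiescent duct filling, in `[0, 1]`.
#' @param t_q Quiescent temperature, kelvin (> 0).
#' @param f Frequency, hertz (>= 0).
#' @return A complex admittance in siemens.
#' @examples
#' p <- skin_circuit_params()
#' small_signal_admittance(p, x_q = 0.2, t_q = 306.15, f = 20)
#' @export
small_signal_admittance <- function(params, x_q, t_q, f) {
  if (!inherits(params, "skin_circuit_params")) {
    ms_stop("`params` must be a skin_circuit_params object", "invalid_parameter")
  }
  if (!is.numeric(x_q) || any(x_q < 0 | x_q > 1)) {
    ms_stop("`x_q` must lie in [0, 1]", "invalid_state")
  }
  if (!is.numeric(t_q) || any(t_q <= 0)) {
    ms_stop("`t_q` must be positive (kelvin)", "invalid_state")
  }
  check_nonneg_scalar(f, "f")
  g <- duct_conductance(params$duct, x_q) + sc_conductance(params$sc, t_q)
  complex(real = g, imaginary = 2 * pi * f * params$sc$c_s)
}
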