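{
  "version": "1.0",
  "comment": "Per-class circuit parameter distributions for the synthetic cohort generator. Medians/spreads are package choices reproducing the qualitative loop phenotypes (A symmetric large-lobe, B small-lobe, C asymmetric, D shifted pinch, F two-pinch thermistor-dominated); they are not fits to subject data. Positive fields: log-normal {median, sdlog}; e_dc: normal {mean, sd}; x0: clipped normal {median, sd}. g_span = g_max - g_min. Units: siemens, volts, seconds, farads, kelvin, J/K, K/W, amperes.",
  "classes": {
    "A": {
      "g_min": {"median": 4e-06, "sdlog": 0.4},
      "g_span": {"median": 2.2e-05, "sdlog": 0.4},
      "x0": {"median": 0.2, "sd": 0.05},
      "a_plus": {"median": 0.05, "sdlog": 0.2},
      "a_minus": {"median": 0.05, "sdlog": 0.2},
      "tau_x": {"median": 4, "sdlog": 0.3},
      "g_ref": {"median": 2e-06, "sdlog": 0.3},
      "b_ntc": 3000, "t_ref": 306.15, "t_amb": 306.15,
      "c_th": {"median": 2e-04, "sdlog": 0.3},
      "r_th": {"median": 5e04, "sdlog": 0.3},
      "c_s": {"median": 1.5e-08, "sdlog": 0.3},
      "e_dc": {"mean": 0, "sd": 0.02},
      "noise_sd": 5e-08
    },
    "B": {
      "g_min": {"median": 3e-06, "sdlog": 0.4},
      "g_span": {"median": 1e-05, "sdlog": 0.4},
      "x0": {"median": 0.2, "sd": 0.05},
      "a_plus": {"median": 0.008, "sdlog": 0.25},
      "a_minus": {"median": 0.008, "sdlog": 0.25},
      "tau_x": {"median": 4, "sdlog": 0.3},
      "g_ref": {"median": 2e-06, "sdlog": 0.3},
      "b_ntc": 3000, "t_ref": 306.15, "t_amb": 306.15,
      "c_th": {"median": 2e-04, "sdlog": 0.3},
      "r_th": {"median": 5e04, "sdlog": 0.3},
      "c_s": {"median": 1.5e-08, "sdlog": 0.3},
      "e_dc": {"mean": 0, "sd": 0.02},
      "noise_sd": 5e-08
    },
    "C": {
      "g_min": {"median": 4e-06, "sdlog": 0.4},
      "g_span": {"median": 1.8e-05, "sdlog": 0.4},
      "x0": {"median": 0.15, "sd": 0.05},
      "a_plus": {"median": 0.06, "sdlog": 0.2},
      "a_minus": {"median": 0.012, "sdlog": 0.2},
      "tau_x": {"median": 4, "sdlog": 0.3},
      "g_ref": {"median": 2e-06, "sdlog": 0.3},
      "b_ntc": 3000, "t_ref": 306.15, "t_amb": 306.15,
      "c_th": {"median": 2e-04, "sdlog": 0.3},
      "r_th": {"median": 5e04, "sdlog": 0.3},
      "c_s": {"median": 1.5e-08, "sdlog": 0.3},
      "e_dc": {"mean": 0, "sd": 0.02},
      "noise_sd": 5e-08
    },
    "D": {
      "g_min": {"median": 3e-06, "sdlog": 0.4},
      "g_span": {"median": 1e-05, "sdlog": 0.4},
      "x0": {"median": 0.2, "sd": 0.05},
      "a_plus": {"median": 0.03, "sdlog": 0.25},
      "a_minus": {"median": 0.03, "sdlog": 0.25},
      "tau_x": {"median": 4, "sdlog": 0.3},
      "g_ref": {"median": 2e-06, "sdlog": 0.3},
      "b_ntc": 3000, "t_ref": 306.15, "t_amb": 306.15,
      "c_th": {"median": 2e-04, "sdlog": 0.3},
      "r_th": {"median": 5e04, "sdlog": 0.3},
      "c_s": {"median": 4e-08, "sdlog": 0.25},
      "e_dc": {"mean": 0.05, "sd": 0.02},
      "noise_sd": 5e-08
    },
    "F": {
      "g_min": {"median": 0, "sdlog": 0},
      "g_span": {"median": 0, "sdlog": 0},
      "x0": {"median": 0.2, "sd": 0.05},
      "a_plus": {"median": 0.05, "sdlog": 0.2},
      "a_minus": {"median": 0.05, "sdlog": 0.2},
      "tau_x": {"median": 4, "sdlog": 0.3},
      "g_ref": {"median": 4e-06, "sdlog": 0.3},
      "b_ntc": 3000, "t_ref": 306.15, "t_amb": 306.15,
      "c_th": {"median": 1e-05, "sdlog": 0.3},
      "r_th": {"median": 3e05, "sdlog": 0.3},
      "c_s": {"median": 2e-08, "sdlog": 0.3},
      "e_dc": {"mean": 0, "sd": 0.005},
      "noise_sd": 5e-08
    }
  }
}
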