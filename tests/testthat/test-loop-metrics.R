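test_that("period extraction partitions the recording and checks bounds", {
  rec <- simulate_recording(duct_only_params(),
                            voltage_stimulus("sinusoidal", 0.8, 0.25))
  p3 <- extract_period(rec, 3)
  expect_equal(p3$v, rec$v[1001:1500])
  expect_equal(p3$i, rec$i[1001:1500])
  expect_equal(p3$t[1], 0)
  expect_equal(do.call(c, lapply(1:3, function(k) extract_period(rec, k)$i)),
               rec$i)
  expect_error(extract_period(rec, 4), class = "memskin_invalid_index")
  expect_error(extract_period(rec, 0), class = "memskin_invalid_index")
  dec <- simulate_recording(duct_only_params(),
                            voltage_stimulus("decaying_sine", 1.2, 0.25))
  expect_error(extract_period(dec, 1), class = "memskin_unsupported_stimulus")
})

test_that("NL reproduces the linear-response reference values", {
  # strictly proportional in-phase current: NL = 2 exactly
  expect_equal(non_linearity(linear_loop(0)), 2, tolerance = 1e-9)
  # phase leads bias NL below 2: 2.1 deg -> 1.93, 13.26 deg -> 1.60
  expect_equal(round(non_linearity(linear_loop(2.1)), 2), 1.93)
  expect_equal(round(non_linearity(linear_loop(13.26)), 2), 1.60)
})

test_that("NL matches a dense-resampling oracle on a simulated loop", {
  p <- duct_only_params()
  stim <- voltage_stimulus("sinusoidal", 1.2, 0.05)
  stim_hi <- voltage_stimulus("sinusoidal", 1.2, 0.05,
                              samples_per_period = 10000L)
  nl <- non_linearity(extract_period(simulate_recording(p, stim), 3))
  nl_hi <- non_linearity(extract_period(simulate_recording(p, stim_hi), 3))
  expect_equal(nl, nl_hi, tolerance = 5e-3)
})

test_that("NL is invariant to a DC current offset and to the denominator floor", {
  per <- extract_period(simulate_recording(
    duct_only_params(), voltage_stimulus("sinusoidal", 1.2, 0.05)), 3)
  shifted <- per
  shifted$i <- per$i + 2e-6
  expect_equal(non_linearity(shifted), non_linearity(per))
  flat <- linear_loop(0)
  flat$i <- rep(1e-5, length(flat$i))   # constant current: zero denominator
  expect_error(non_linearity(flat), class = "memskin_degenerate_loop")
})

test_that("lobe area: zero-width curve, analytic ellipse and scaling", {
  # single-valued curve traversed up and back encloses nothing
  v <- c(seq(0, 1, length.out = 250), seq(1, 0, length.out = 250))
  stim <- voltage_stimulus("triangular", 1, 1, periods = 1L,
                           samples_per_period = 500L)
  flatrec <- recording("z", "forehead", stim, seq(0, 0.998, by = 0.002),
                       v - 0.5, 1e-5 * (v - 0.5)^3)
  la0 <- lobe_area(flatrec)
  expect_lt(la0$a_total, 1e-9 * 1e-5)
  # linear RC ellipse: area = pi * W * A^2 with quadrature weight W
  ell <- analytic_loop(function(th) 1e-6 * sin(th) + 0.5e-6 * cos(th))
  expect_equal(lobe_area(ell)$a_total, pi * 0.5e-6, tolerance = 0.01)
  expect_equal(lobe_area_polygon(ell), pi * 0.5e-6, tolerance = 0.01)
  # pinched analytic loop agrees with the polygon decomposition oracle
  pinched <- analytic_loop(function(th) 1e-6 * sin(th) * (1 + 0.3 * cos(th)))
  expect_equal(lobe_area(pinched)$a_total, lobe_area_polygon(pinched),
               tolerance = 0.01)
  # exact homogeneity in current and voltage scaling
  k <- 3.7
  scaled <- pinched
  scaled$i <- k * pinched$i
  expect_equal(lobe_area(scaled)$a_total, k * lobe_area(pinched)$a_total)
  scaled_v <- pinched
  scaled_v$v <- k * pinched$v
  expect_equal(lobe_area(scaled_v)$a_total, k * lobe_area(pinched)$a_total)
})

test_that("maximum current reports the first-quadrant peak and its angle", {
  pure <- linear_loop(0)
  mc <- max_current(pure)
  expect_equal(mc$angle, 90)
  expect_equal(mc$i_max, max(pure$i))
  # memristive state keeps growing past the voltage peak: angle > 90 deg
  per <- extract_period(simulate_recording(
    duct_only_params(), voltage_stimulus("sinusoidal", 1.2, 0.05)), 3)
  expect_gt(max_current(per)$angle, 90)
  # ties break to the earliest sample
  stim <- voltage_stimulus("sinusoidal", 1, 1, periods = 1L,
                           samples_per_period = 8L)
  twin <- recording("t", "forehead", stim, (0:7) / 8, sin(2 * pi * (0:7) / 8),
                    c(0, 1, 0, 1, 0, -1, 0, -0.5) * 1e-6)
  expect_equal(max_current(twin)$angle, 360 / 8)
})

test_that("pinch detection: ellipse none, pinched loop one transversal at origin", {
  ell <- analytic_loop(function(th) 1e-6 * sin(th) + 0.5e-6 * cos(th))
  expect_equal(nrow(detect_pinch_points(ell)), 0L)
  pinched <- analytic_loop(function(th) 1e-6 * sin(th) * (1 + 0.3 * cos(th)))
  pp <- detect_pinch_points(pinched)
  expect_equal(nrow(pp), 1L)
  expect_lt(abs(pp$v), 0.01)
  expect_lt(abs(pp$i), 1e-8)
  expect_false(pp$tangential)   # branch slopes 1 +/- 0.3 differ by > 15 deg
  short <- pinched
  short$t <- short$t[1:5]; short$v <- short$v[1:5]; short$i <- short$i[1:5]
  expect_error(detect_pinch_points(short), class = "memskin_insufficient_data")
})

test_that("pinch count is stable under 2x resampling", {
  for (n in c(500L, 1000L)) {
    stim <- voltage_stimulus("sinusoidal", 1.2, 0.05, samples_per_period = n)
    per <- extract_period(simulate_recording(duct_only_params(), stim), 3)
    expect_equal(nrow(detect_pinch_points(per)), 1L)
    per2 <- extract_period(simulate_recording(thermistor_params(2e-8), stim), 3)
    expect_equal(nrow(detect_pinch_points(per2)), 2L)
  }
})

test_that("phase shift follows the RC arctangent with its reference values", {
  expect_equal(round(phase_shift(6.7e-6, 15.6e-9, 0.05), 2), 0.04)
  expect_equal(phase_shift(6.7e-6, 15.6e-9, 2.5), 2.1, tolerance = 0.01)
  expect_equal(round(phase_shift(2e-6, 30e-9, 0.05), 2), 0.27)
  expect_equal(round(phase_shift(2e-6, 30e-9, 2.5), 2), 13.26)
  expect_identical(phase_shift(1e-6, 1e-8, 0), 0)
  expect_error(phase_shift(0, 1e-8, 1), class = "memskin_invalid_parameter")
})

test_that("state-dependent phase shift reduces to the static law and brackets", {
  expect_equal(state_dependent_phase_shift(rep(2e-6, 5), 30e-9, 2.5),
               rep(phase_shift(2e-6, 30e-9, 2.5), 5))
  g_traj <- seq(2e-6, 4e-6, length.out = 20)
  a <- state_dependent_phase_shift(g_traj, 30e-9, 2.5)
  expect_true(all(diff(a) < 0))      # alpha falls as conductance doubles
  # along a duct simulation, alpha stays inside the G_min/G_max static bounds
  rec <- simulate_recording(duct_only_params(),
                            voltage_stimulus("sinusoidal", 1.2, 2.5))
  g_t <- duct_conductance(duct_only_params()$duct, rec$state$x)
  a_t <- state_dependent_phase_shift(g_t, 15.6e-9, 2.5)
  expect_true(all(a_t <= phase_shift(min(g_t), 15.6e-9, 2.5) + 1e-9))
  expect_true(all(a_t >= phase_shift(max(g_t), 15.6e-9, 2.5) - 1e-9))
})

test_that("lock-in demodulation separates conductance and susceptance", {
  stim <- voltage_stimulus("sinusoidal", 0.1, 20, periods = 10L)
  wf <- generate_waveform(stim)
  # pure conductance
  rec_g <- recording("s", "forehead", stim, wf$time, wf$voltage,
                     1e-5 * wf$voltage)
  adm <- lockin_admittance(rec_g)
  expect_equal(adm$g, 1e-5, tolerance = 1e-4)
  expect_lt(abs(adm$b), 1e-4 * 1e-5)
  # parallel RC: susceptance = 2 pi f C within 0.1%
  rec_rc <- recording("s", "forehead", stim, wf$time, wf$voltage,
                      1e-5 * wf$voltage +
                        15.6e-9 * 2 * pi * 20 * 0.1 * cos(2 * pi * 20 * wf$time))
  adm2 <- lockin_admittance(rec_rc)
  expect_equal(adm2$b, 2 * pi * 20 * 15.6e-9, tolerance = 1e-3)
  expect_equal(adm2$c, 15.6e-9, tolerance = 1e-3)
  # consistency with the phase-shift law within 0.1 degree
  expect_equal(atan(adm2$b / adm2$g) * 180 / pi,
               phase_shift(1e-5, 15.6e-9, 20), tolerance = 0.1)
})

test_that("lock-in recovers conductance under noise over 30 s of averaging", {
  stim <- voltage_stimulus("sinusoidal", 0.1, 20, periods = 600L,
                           samples_per_period = 100L)
  wf <- generate_waveform(stim)
  i_clean <- 1e-5 * wf$voltage
  set.seed(123)
  i_noisy <- i_clean + stats::rnorm(length(i_clean), 0, 0.01 * 1e-5 * 0.1)
  rec <- recording("s", "forehead", stim, wf$time, wf$voltage, i_noisy)
  expect_equal(lockin_admittance(rec)$g, 1e-5, tolerance = 0.01)
})

test_that("lock-in truncates a partial trailing period with a warning", {
  stim <- voltage_stimulus("sinusoidal", 0.1, 20, periods = 3L)
  wf <- generate_waveform(stim)
  n <- nrow(wf) - 100L
  rec <- recording("s", "forehead", stim, wf$time[1:n], wf$voltage[1:n],
                   1e-5 * wf$voltage[1:n])
  expect_warning(adm <- lockin_admittance(rec), class = "memskin_partial_period")
  expect_equal(adm$g, 1e-5, tolerance = 1e-4)
})

test_that("loop_metrics assembles a consistent row and batch analysis logs failures", {
  rec <- simulate_recording(duct_only_params(),
                            voltage_stimulus("sinusoidal", 1.2, 0.05),
                            subject_id = "S01")
  row <- loop_metrics(rec, 3)
  expect_equal(row$n_pinch, 1L)
  expect_gt(row$nl, 2)
  expect_equal(row$lobe_area_normalized, row$lobe_area / row$i_max)
  expect_gte(row$i_max, 0)
  recs <- list(rec,
               simulate_recording(duct_only_params(),
                                  voltage_stimulus("decaying_sine", 1.2, 0.05)))
  tbl <- analyze_recordings(recs)
  expect_equal(nrow(tbl), 1L)
  expect_length(attr(tbl, "skipped"), 1L)
})
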