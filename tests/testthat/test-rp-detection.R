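test_that("filtering reduces variance and preserves a constant baseline", {
  g <- straight_30()
  ds <- quick_dataset(g, n = 0, duration = 0.02, seed = 4, snr = 20)
  # white noise on a constant: filtered variance must drop
  tr <- rp_preprocess(ds$trace)
  expect_lt(stats::var(tr$filtered_A), stats::var(tr$current_A))

  dsc <- quick_dataset(g, n = 0, duration = 0.02, seed = 4, snr = Inf)
  trc <- rp_preprocess(dsc$trace)
  expect_true(all(abs(trc$baseline_A - 5e-8) < 1e-18))
  expect_error(rp_preprocess(ds$trace, detrend_window_s = 1e-5), "10 samples")
})

test_that("slow drift is removed by the running-median baseline", {
  g <- straight_30()
  acq <- acquisition_model(noise_sd_A = 2e-11, drift_amplitude = 0.01,
                           drift_period_s = 2)
  ds <- generate_dataset(g, 0, 1, seed = 6, acq = acq, render = FALSE)
  tr <- rp_preprocess(ds$trace)
  resid <- tr$filtered_A - tr$baseline_A
  expect_lt(abs(mean(resid)), 0.1 * attr(tr, "noise_sd_A"))
})

test_that("detection finds every deep pulse and no false positives", {
  g <- straight_30()
  # 10 pulses at ~20 sigma
  ds <- quick_dataset(g, n = 10, duration = 0.3, seed = 8, snr = 20, y_frac = 0)
  tr <- rp_preprocess(ds$trace)
  ev <- rp_detect_events(tr)
  expect_equal(nrow(ev), 10)
  # spans cover at least the FWHM of each pulse (here, most of the transit)
  tru <- ground_truth(ds$trace)
  expect_true(all(ev$t_end_s - ev$t_start_s > 0.5 * tru$duration_s))

  # event-free noise trace: expect zero detections (Gaussian tail at k = 6)
  ds0 <- quick_dataset(g, n = 0, duration = 0.5, seed = 9, snr = 20)
  expect_equal(nrow(rp_detect_events(rp_preprocess(ds0$trace))), 0)
})

test_that("detection is invariant to adding a constant to the trace", {
  g <- straight_30()
  ds <- quick_dataset(g, n = 5, duration = 0.2, seed = 10, snr = 20)
  tr1 <- rp_preprocess(ds$trace)
  shifted <- ds$trace
  shifted$current_A <- shifted$current_A + 1e-8
  tr2 <- rp_preprocess(shifted)
  e1 <- rp_detect_events(tr1)
  e2 <- rp_detect_events(tr2)
  expect_equal(e1$start_idx, e2$start_idx)
  expect_equal(e1$end_idx, e2$end_idx)
})

test_that("hysteresis merges pulses that never fall below the closing threshold", {
  # two co-moving particles a short gap apart: excursion stays high between
  g <- straight_30()
  fl <- flow_model(1e5)
  t1 <- simulate_trajectory(g, fl, 0, 0.005)
  t2 <- simulate_trajectory(g, fl, 0, 0.005 + 4e-4)  # overlaps in channel
  acq <- acquisition_model(noise_sd_A = a30() * 5e-8 / 20)
  set.seed(2)
  trace <- synthesize_current(g, list(t1, t2), acq, duration_s = 0.02)
  tr <- rp_preprocess(trace)
  ev <- rp_detect_events(tr)
  expect_equal(nrow(ev), 1)
})

test_that("characterization recovers amplitude, FWHM and plateau of clean pulses", {
  g <- straight_30()
  ds <- quick_dataset(g, n = 5, duration = 0.2, seed = 12, snr = Inf,
                      y_frac = 0)
  p <- detect_rp_pipeline(ds)
  ev <- p$events
  expect_equal(nrow(ev), 5)
  expect_equal(ev$plateau_amplitude, rep(a30(), 5), tolerance = 1e-3)
  expect_equal(ev$n_extrema, rep(1L, 5))
  # FWHM vs the half-amplitude positions of the simulator: with the default
  # half-plateau mouth amplitude the half-peak crossings sit at the channel
  # ends, so FWHM tracks the physical transit time
  tru <- ground_truth(ds$trace)
  expect_equal(ev$fwhm_s, tru$duration_s, tolerance = 0.02)
})

test_that("amplitude estimator bias is below 1% at sigma = A/20", {
  g <- straight_30()
  ds <- quick_dataset(g, n = 30, duration = 0.8, seed = 13, snr = 20,
                      y_frac = 0)
  p <- detect_rp_pipeline(ds)
  expect_equal(nrow(p$events), 30)
  expect_lt(abs(mean(p$events$plateau_amplitude) / a30() - 1), 0.01)
})

test_that("FWHM is exact on ideal pulse shapes", {
  # fabricate a trace with one rectangular and one triangular pulse
  dt <- 4e-6
  n <- 6000
  i0 <- 5e-8
  cur <- rep(i0, n)
  A <- 5e-10
  rect <- 1001:1500                       # width 500 samples
  cur[rect] <- i0 - A
  tri_rise <- 3001:3400; tri_fall <- 3401:3800   # base 800 samples
  cur[tri_rise] <- i0 - A * seq(0, 1, length.out = 400)
  cur[tri_fall] <- i0 - A * seq(1, 0, length.out = 400)
  trace <- rpmap:::new_rp_trace(
    tibble::tibble(time_s = (seq_len(n) - 1) * dt, current_A = cur),
    sample_period_s = dt, i0_A = i0)
  tr <- rp_preprocess(trace, lowpass_hz = NULL, detrend_window_s = 0.02)
  attr(tr, "noise_sd_A") <- A / 100      # nominal floor for thresholds
  ev <- rp_characterize(rp_detect_events(tr, min_duration_s = 1e-5), tr)
  expect_equal(nrow(ev), 2)
  # rectangular: peak = A/I_p-normalised depth, FWHM = full width
  expect_equal(ev$fwhm_s[1], 500 * dt, tolerance = 0.01)
  expect_equal(ev$peak_amplitude[1], (i0 - (i0 - A)) / (i0 - A),
               tolerance = 1e-3)
  # triangular with base 2T: FWHM = T
  expect_equal(ev$fwhm_s[2], 400 * dt, tolerance = 0.02)
})

test_that("FWHM of simulated pulses tracks the transit within one frame period", {
  g <- straight_30()
  ds <- quick_dataset(g, n = 5, duration = 0.2, seed = 14, snr = Inf,
                      y_frac = 0)
  p <- detect_rp_pipeline(ds)
  tru <- ground_truth(ds$trace)
  # mouth amplitude is half the plateau by construction, so the transit time
  # is the true FWHM; the smoothing chain widens it by a few current samples,
  # still well below one frame period (20 us)
  expect_true(all(abs(p$events$fwhm_s - tru$duration_s) <= 2e-5))
})

test_that("cavity events keep exactly the three physical extrema", {
  g <- cavity_2050()
  ds <- quick_dataset(g, n = 3, duration = 0.1, seed = 3, snr = Inf,
                      y_frac = 0)
  p <- detect_rp_pipeline(ds)
  expect_equal(p$events$n_extrema, rep(3L, 3))
  types <- p$events$extrema[[1]]$type
  expect_equal(types, c("max", "min", "max"))
})

test_that("amplitude-duration gates drop events outside the ranges", {
  g <- straight_30()
  ds <- quick_dataset(g, n = 8, duration = 0.3, seed = 15, snr = 20)
  p <- detect_rp_pipeline(ds)
  ev <- p$events
  expect_identical(nrow(suppressMessages(rp_gate_events(ev))), nrow(ev))
  kept <- suppressMessages(
    rp_gate_events(ev, amplitude_range = c(0, stats::median(ev$peak_amplitude))))
  expect_lt(nrow(kept), nrow(ev))
  none <- suppressMessages(
    rp_gate_events(ev, polygon = data.frame(duration_s = c(0, 1e-9, 1e-9, 0),
                                            amplitude = c(0, 0, 1e-9, 1e-9))))
  expect_equal(nrow(none), 0)
})

test_that("doublets are removed by an amplitude gate at twice the singleton level", {
  g <- straight_30()
  fl <- flow_model(1e5)
  # two singletons and one co-located pair (a doublet at ~2x amplitude)
  trajs <- list(simulate_trajectory(g, fl, 0, 0.005),
                simulate_trajectory(g, fl, 0, 0.02),
                simulate_trajectory(g, fl, 1, 0.04),
                simulate_trajectory(g, fl, -1, 0.04))
  acq <- acquisition_model(noise_sd_A = a30() * 5e-8 / 20)
  set.seed(5)
  trace <- synthesize_current(g, trajs, acq, duration_s = 0.06)
  tr <- rp_preprocess(trace)
  ev <- rp_characterize(rp_detect_events(tr), tr)
  expect_equal(nrow(ev), 3)
  gated <- suppressMessages(
    rp_gate_events(ev, amplitude_range = c(0, 1.5 * a30())))
  expect_equal(nrow(gated), 2)
})
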