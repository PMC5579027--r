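test_that("centreline transit time equals length over velocity", {
  tr <- simulate_trajectory(straight_30(), flow_model(1e5), 0, 0.01)
  expect_equal(tr$duration_s, 150 / 1e5, tolerance = 1e-12)
  # cavity channel: continuity slows nothing, the wider section moves slower
  trc <- simulate_trajectory(cavity_2050(), flow_model(1e5), 0, 0.01)
  expect_equal(trc$duration_s, 100 / 1e5 + 50 / (1e5 * 20 / 50),
               tolerance = 1e-12)
})

test_that("transit duration is symmetric in y0 and grows off axis", {
  fl <- flow_model(1e5)
  g <- straight_30()
  t_pos <- simulate_trajectory(g, fl, 8, 0.01)$duration_s
  t_neg <- simulate_trajectory(g, fl, -8, 0.01)$duration_s
  t_ctr <- simulate_trajectory(g, fl, 0, 0.01)$duration_s
  expect_equal(t_pos, t_neg, tolerance = 1e-12)
  expect_gt(t_pos, t_ctr)
  # exact parabolic profile: T(y)/T(0) = 1/(1 - (2y/w)^2)
  expect_equal(t_pos / t_ctr, 1 / (1 - (16 / 30)^2), tolerance = 1e-12)
  expect_error(simulate_trajectory(g, fl, 10.5, 0.01), "accessible")
})

test_that("streamline following conserves the relative lateral position", {
  g <- cavity_2050()
  tr <- simulate_trajectory(g, flow_model(1e5), 3, 0.01)
  pos <- trajectory_position(tr, seq(tr$t_s[1], max(tr$t_s), length.out = 400))
  inside_narrow <- pos$x_c > 5 & pos$x_c < 45
  inside_cavity <- pos$x_c > 55 & pos$x_c < 95
  expect_true(all(abs(pos$y_c[inside_narrow] - 3) < 1e-9))
  expect_true(all(abs(pos$y_c[inside_cavity] - 3 * 50 / 20) < 1e-9))
})

test_that("flux conservation sets the cavity centreline velocity", {
  g <- cavity_2050()
  tr <- simulate_trajectory(g, flow_model(1e5), 0, 0)
  pos <- trajectory_position(tr, seq(0, max(tr$t_s), by = 1e-5))
  # velocity in the cavity = v_max * w_narrow / w_wide
  in_cav <- which(pos$x_c > 55 & pos$x_c < 95)
  v_cav <- diff(pos$x_c[in_cav]) / diff(pos$t_s[in_cav])
  expect_equal(mean(v_cav), 1e5 * 20 / 50, tolerance = 1e-9)
})

test_that("noise-free synthesized blockade equals the closed form everywhere", {
  g <- cavity_2050()
  acq <- acquisition_model()   # sigma = 0, no drift
  tr <- simulate_trajectory(g, flow_model(1e5), 4, 0.01)
  trace <- synthesize_current(g, list(tr), acq, duration_s = 0.03)
  a_meas <- (attr(trace, "i0_A") - trace$current_A) / trace$current_A
  pos <- trajectory_position(tr, trace$time_s / 1)  # eps = 0, offset = 0
  active <- trace$time_s >= tr$t_s[1] & trace$time_s <= max(tr$t_s)
  a_true <- blockade_theory(g, 10, pos$x_c[active], 4)
  expect_equal(a_meas[active], a_true, tolerance = 1e-10)
  expect_true(all(abs(a_meas[!active]) < 1e-12))
})

test_that("empty trajectory list yields a pure baseline trace", {
  trace <- synthesize_current(straight_30(), list(), acquisition_model(),
                              duration_s = 0.01)
  expect_true(all(trace$current_A == 5e-8))
  expect_null(ground_truth(trace))
})

test_that("on-axis plateau equals the equivalent-diameter on-axis form", {
  g <- straight_30()
  tr <- simulate_trajectory(g, flow_model(1e5), 0, 0.005)
  trace <- synthesize_current(
    g, list(tr), acquisition_model(),
    transition = transition_model(ell_t_um = 0, access_frac = 0),
    duration_s = 0.012)
  a_meas <- (5e-8 - trace$current_A) / trace$current_A
  plateau <- trace$time_s > 0.0055 & trace$time_s < 0.0060  # mid-transit
  expect_equal(mean(a_meas[plateau]), a30(), tolerance = 1e-10)
})

test_that("cavity pulse has two equal maxima and an interior minimum at the predicted ratio", {
  g <- cavity_2050()
  tr <- simulate_trajectory(g, flow_model(1e5), 0, 0.005)
  trace <- synthesize_current(g, list(tr), acquisition_model(),
                              duration_s = 0.012)
  a <- (5e-8 - trace$current_A) / trace$current_A
  # timeline: entry 5 ms; narrow 0-50 um at v_max (0.5 ms); cavity 50-100 um
  # at 0.4 v_max (1.25 ms); narrow 100-150 um (0.5 ms)
  t_nar1 <- trace$time_s > 0.00525 & trace$time_s < 0.00535  # first narrow
  t_cav <- trace$time_s > 0.0060 & trace$time_s < 0.0065     # cavity centre
  t_nar2 <- trace$time_s > 0.0068 & trace$time_s < 0.0070    # second narrow
  a_n1 <- max(a[t_nar1]); a_c <- min(a[t_cav]); a_n2 <- max(a[t_nar2])
  expect_equal(a_n1, a_n2, tolerance = 1e-9)
  expect_lt(a_c, a_n1)
  expect_equal(a_c / a_n1, cavity_ratio_theory(g, 10), tolerance = 1e-6)
})

test_that("transit durations over uniform entry positions follow the Poiseuille passage-time law", {
  g <- straight_30()
  fl <- flow_model(1e5)
  set.seed(99)
  y0 <- runif(500, -10, 10)   # uniform over the accessible range
  durations <- vapply(y0, function(y) {
    simulate_trajectory(g, fl, y, 0)$duration_s
  }, numeric(1))
  u_max <- 2 * 10 / 30  # accessible |2 y0 / w| bound
  t0 <- 150 / 1e5
  cdf <- function(t) {
    p <- numeric(length(t))
    p[t >= t0] <- pmin(sqrt(pmax(1 - t0 / t[t >= t0], 0)), u_max) / u_max
    p
  }
  ks <- suppressWarnings(stats::ks.test(durations, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("frame timestamps follow the camera clock exactly", {
  g <- straight_30()
  ds <- quick_dataset(g, n = 2, duration = 0.05, seed = 3, snr = Inf,
                      render = TRUE)
  fr <- ds$frames
  expect_equal(fr$time_s, fr$frame_index * 2e-5, tolerance = 1e-15)
  expect_true(all(diff(fr$time_s) > 0))
})

test_that("datasets are reproducible from the seed", {
  g <- straight_30()
  d1 <- quick_dataset(g, n = 3, duration = 0.05, seed = 7, render = TRUE)
  d2 <- quick_dataset(g, n = 3, duration = 0.05, seed = 7, render = TRUE)
  expect_identical(d1$trace$current_A, d2$trace$current_A)
  expect_identical(d1$frames$frames, d2$frames$frames)
  expect_identical(d1$truth, d2$truth)
  d3 <- quick_dataset(g, n = 3, duration = 0.05, seed = 8, render = FALSE)
  expect_false(identical(d1$trace$current_A, d3$trace$current_A))
})

test_that("zero arrivals give a baseline-only dataset; counts are by construction", {
  ds0 <- quick_dataset(straight_30(), n = 0, duration = 0.02, seed = 1,
                       snr = Inf)
  expect_null(ds0$truth)
  ds <- quick_dataset(straight_30(), n = 20, duration = 0.5, seed = 2)
  expect_equal(nrow(ds$truth), 20)
})
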