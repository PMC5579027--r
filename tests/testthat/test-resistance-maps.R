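# one small synchronized dataset shared by the map/profile tests
matched_fixture <- function(geom = straight_30(), n = 6, seed = 81,
                            snr = Inf, y_frac = 1, duration = 0.15, ...) {
  ds <- quick_dataset(geom, n = n, duration = duration, seed = seed,
                      snr = snr, y_frac = y_frac, render = TRUE, ...)
  p <- detect_rp_pipeline(ds)
  im <- detect_im_events(ds$frames, geom, expected_diameter_um = 10)
  m <- match_events(p$events, im, p$trace, geom)
  list(matched = m, truth = ground_truth(ds$trace), ds = ds)
}

test_that("map bins agree with the closed-form blockade in a straight channel", {
  fx <- matched_fixture(y_frac = 0)
  map <- build_map(fx$matched, bin_um = 2)
  inside <- map$x_c > 20 & map$x_c < 130 & map$n >= 3
  a_true <- blockade_theory(straight_30(), 10, map$x_c[inside], 0)
  expect_gt(sum(inside), 20)
  expect_lt(max(abs(map$mean_a[inside] / a_true - 1)), 1e-3)
  expect_true(all(map$n > 0))   # untouched bins are absent, never zero-filled
  expect_error(build_map(fx$matched[0, ]), "no matched events")
})

test_that("cavity bins are lighter than narrow bins", {
  fx <- matched_fixture(geom = cavity_2050(), y_frac = 0, duration = 0.2)
  map <- build_map(fx$matched, bin_um = 2)
  cav <- map$x_c > 60 & map$x_c < 90
  nar <- (map$x_c > 20 & map$x_c < 45) | (map$x_c > 105 & map$x_c < 130)
  expect_gt(sum(cav), 0)
  expect_gt(sum(nar), 0)
  expect_lt(max(map$mean_a[cav]), min(map$mean_a[nar]))
})

test_that("a bin spanning the whole channel holds the grand mean", {
  fx <- matched_fixture(n = 3, y_frac = 0)
  smp <- tidyr::unnest(fx$matched[, c("rp_id", "samples")], "samples")
  smp <- smp[smp$n_in_channel <= 1 & smp$x_c >= 0 & smp$x_c <= 150, ]
  map <- build_map(fx$matched, bin_um = 1000, extent = c(0, 150, -500, 500))
  expect_equal(nrow(map), 1)
  expect_equal(map$mean_a, mean(smp$a), tolerance = 1e-12)
})

test_that("maps and profiles are invariant to event order and to split/merge", {
  fx <- matched_fixture(n = 6, y_frac = 0)
  m <- fx$matched
  perm <- m[sample(nrow(m)), ]
  attr(perm, "geom") <- attr(m, "geom")
  map1 <- build_map(m); map2 <- build_map(perm)
  expect_equal(dplyr::arrange(as.data.frame(map1), x_c, y_c),
               dplyr::arrange(as.data.frame(map2), x_c, y_c))
  # streaming consistency: bin counts/means from two halves merge to the whole
  h1 <- build_map(m[1:3, ]); h2 <- build_map(m[4:6, ])
  both <- dplyr::full_join(as.data.frame(h1), as.data.frame(h2),
                           by = c("x_c", "y_c"))
  both[is.na(both)] <- 0
  merged_mean <- (both$mean_a.x * both$n.x + both$mean_a.y * both$n.y) /
    (both$n.x + both$n.y)
  whole <- dplyr::left_join(both[, c("x_c", "y_c")], as.data.frame(map1),
                            by = c("x_c", "y_c"))
  expect_equal(merged_mean, whole$mean_a, tolerance = 1e-12)
})

test_that("axial profile finds the transition-zone saturation position", {
  fx <- matched_fixture(n = 8, y_frac = 0, duration = 0.2)
  prof <- axial_profile(fx$matched)
  expect_lt(abs(attr(prof, "saturation_x") - 15), 2)
  # symmetric channel: profile symmetric about the midpoint
  inside <- prof$x_c >= 10 & prof$x_c <= 140
  xs <- prof$x_c[inside]
  mirrored <- stats::approx(prof$x_c, prof$mean_a, 150 - xs)$y
  expect_equal(prof$mean_a[inside], mirrored, tolerance = 5e-3)
})

test_that("a zero transition length gives a flat in-channel profile", {
  fx <- matched_fixture(n = 8, y_frac = 0, duration = 0.2,
                        transition = transition_model(ell_t_um = 0,
                                                      access_frac = 0))
  prof <- axial_profile(fx$matched, min_count = 3)
  inside <- prof$x_c > 5 & prof$x_c < 145
  expect_gt(sum(inside), 50)
  expect_lt(diff(range(prof$mean_a[inside])) / max(prof$mean_a[inside]), 0.02)
})

test_that("entrance and exit amplitudes sit at half peak by default", {
  fx <- matched_fixture(n = 6, y_frac = 0, duration = 0.2)
  chk <- fwhm_vs_entrance_check(fx$matched)
  expect_equal(mean(chk$entrance_ratio), 0.5, tolerance = 0.05)
  expect_equal(mean(chk$exit_ratio), 0.5, tolerance = 0.05)
  # reproducible across events in a noise-free run
  expect_lt(stats::sd(chk$entrance_ratio), 0.02)

  # with no transition zone the mouth amplitude equals the plateau
  fx0 <- matched_fixture(n = 4, y_frac = 0,
                         transition = transition_model(ell_t_um = 0,
                                                       access_frac = 1))
  chk0 <- fwhm_vs_entrance_check(fx0$matched)
  expect_equal(mean(chk0$entrance_ratio), 1, tolerance = 0.05)
})

test_that("lateral statistics recover the Poiseuille duration law exactly", {
  fx <- matched_fixture(n = 10, y_frac = 1, duration = 0.25, seed = 83)
  ls <- lateral_stats(fx$matched, region = "whole")
  cx <- convexity(ls)
  expect_gt(cx$quad_coef[cx$profile == "duration"], 0)
  # noise-free check of Dt(y)/Dt(0) = 1/(1 - (2y/w)^2)
  ev <- ls$events
  t0 <- 150 / 1e5
  pred <- t0 / (1 - (2 * ev$y_mean_um / 30)^2)
  expect_equal(ev$duration_s, pred, tolerance = 5e-3)
})

test_that("amplitude-duration fits have the expected signs and tidiers", {
  fx <- matched_fixture(n = 12, y_frac = 1, duration = 0.3, seed = 84,
                        snr = 40)
  ev <- region_amplitudes(fx$matched, "whole")
  fit <- amp_duration_fit(ev)
  expect_gt(fit$slope, 0)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("(Intercept)", "duration_s"))
  gl <- generics::glance(fit)
  expect_false(gl$degenerate)

  same <- ev
  same$duration_s <- 1e-3
  same$amplitude <- 0.01
  fit0 <- amp_duration_fit(same)
  expect_true(fit0$degenerate)
  expect_true(is.na(fit0$r))
  expect_error(amp_duration_fit(ev[1:3, ]), "at least 10")
})

test_that("cavity ratio distribution matches the local-resistance prediction", {
  fx <- matched_fixture(geom = cavity_2050(), n = 6, y_frac = 0,
                        duration = 0.2, seed = 85)
  rd <- ratio_distribution(fx$matched, cavity_2050(), 10)
  expect_equal(nrow(rd), 6)
  expect_equal(rd$ratio, rep(attr(rd, "theory"), 6), tolerance = 1e-3)
  expect_equal(attr(rd, "theory"), 0.1516, tolerance = 2e-3)
  # straight-channel events lack the morphology
  fx_s <- matched_fixture(n = 3, y_frac = 0)
  expect_error(suppressMessages(
    ratio_distribution(fx_s$matched, cavity_2050(), 10)), "morphology")
})

test_that("suppressed-near-wall cavity mode inverts the amplitude correlation", {
  fx <- matched_fixture(
    geom = cavity_2050(), n = 25, y_frac = 1, duration = 0.6, seed = 86,
    snr = 60, transition = transition_model(cavity_mode = "suppressed_near_wall"))
  nar <- region_amplitudes(fx$matched, "narrow")
  cav <- region_amplitudes(fx$matched, "cavity")
  expect_gt(amp_duration_fit(nar)$slope, 0)
  expect_lt(amp_duration_fit(cav)$slope, 0)
})

test_that("autoplot methods return ggplot objects", {
  fx <- matched_fixture(n = 3, y_frac = 0)
  expect_s3_class(ggplot2::autoplot(build_map(fx$matched)), "ggplot")
  expect_s3_class(ggplot2::autoplot(axial_profile(fx$matched)), "ggplot")
})
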