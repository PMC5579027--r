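test_that("template subtraction is exact and sign-correct", {
  tpl <- matrix(200, 10, 12)
  expect_true(all(subtract_template(tpl, tpl) == 0))
  fr <- tpl; fr[4:6, 5:7] <- 150   # dark particle: positive response
  d <- subtract_template(fr, tpl)
  expect_equal(max(d), 50)
  # constant brightness offset shifts the difference by its negative
  expect_equal(subtract_template(fr + 7, tpl), d - 7)
  expect_error(subtract_template(matrix(0, 2, 2), tpl), "dimensions")
})

test_that("connected-component labeling honours connectivity and min_area", {
  d <- matrix(0, 12, 12)
  d[2:6, 2:6] <- 30          # 5x5 square
  d[8:12, 8:12] <- 30        # disjoint 5x5 square
  expect_equal(nrow(threshold_and_label(d, 10)), 2)

  diag_touch <- matrix(0, 8, 8)
  diag_touch[2:3, 2:3] <- 30
  diag_touch[4:5, 4:5] <- 30   # touches only at the corner (3,3)-(4,4)
  expect_equal(nrow(threshold_and_label(diag_touch, 10, connectivity = 8)), 1)
  expect_equal(nrow(threshold_and_label(diag_touch, 10, connectivity = 4)), 2)

  speck <- matrix(0, 6, 6); speck[3, 3] <- 30
  expect_equal(nrow(threshold_and_label(speck, 10, min_area = 2)), 0)
})

test_that("labeling agrees with an independent component-labeling oracle", {
  skip_if_not_installed("EBImage")
  set.seed(21)
  for (rep in 1:10) {
    d <- matrix(rbinom(30 * 40, 1, 0.2) * 30, 30, 40)
    mine <- threshold_and_label(d, 10, connectivity = 4, min_area = 1)
    oracle <- EBImage::bwlabel(d >= 10)   # 4-connectivity labeling
    expect_equal(nrow(mine), max(oracle))
  }
})

test_that("centroids of rendered disks are sub-pixel accurate", {
  g <- straight_30()
  acq <- acquisition_model(pixel_noise_sd = 0)
  tr <- simulate_trajectory(g, flow_model(1e5), 2, 0.001)
  fs <- render_frames(list(tr), g, acq)
  det <- im_detect(fs, expected_diameter_um = 10)
  expect_gt(nrow(det), 50)
  # compare each centroid with the trajectory position at mid-exposure
  pos <- trajectory_position(tr, det$time_s)
  px <- to_pixel_coords(data.frame(x_c = pos$x_c, y_c = pos$y_c), fs$frame)
  err <- sqrt((det$x_px - px$x_px)^2 + (det$y_px - px$y_px)^2)
  expect_lt(max(err), 0.5)
})

test_that("zero particles give empty detections; detection count matches render count", {
  g <- straight_30()
  fs0 <- render_frames(list(), g, acquisition_model(), t_end = 0.002,
                       active_only = FALSE)
  expect_equal(nrow(im_detect(fs0, expected_diameter_um = 10)), 0)

  ds <- quick_dataset(g, n = 4, duration = 0.08, seed = 31, render = TRUE)
  det <- im_detect(ds$frames, expected_diameter_um = 10)
  # every frame with a fully-in-view particle yields exactly one detection
  counts <- table(det$frame_index)
  expect_true(all(counts == 1))
})

test_that("greedy linking matches the brute-force optimal assignment on random scenes", {
  set.seed(77)
  for (rep in 1:25) {
    n1 <- sample(0:5, 1); n2 <- sample(0:5, 1)
    # well-separated particles moving < max_disp between frames
    nb <- max(n1, n2, 1)
    base <- cbind(runif(nb, 0, 100), runif(nb, 0, 100))
    while (nb > 1 && min(dist(base)) < 25) {
      base <- cbind(runif(nb, 0, 100), runif(nb, 0, 100))
    }
    a <- base[seq_len(n1), , drop = FALSE]
    b <- base[seq_len(n2), , drop = FALSE]
    if (n2 > 0) b <- b + matrix(runif(2 * n2, -4, 4), n2)
    det <- tibble::tibble(
      frame_index = rep(c(1L, 2L), c(n1, n2)),
      time_s = rep(c(1e-3, 2e-3), c(n1, n2)),
      x_px = c(a[, 1], b[, 1]), y_px = c(a[, 2], b[, 2]),
      area = 5L, peak = 30)
    linked <- link_tracks(det, max_disp_px = 10)
    # map track ids back to input rows of a and b
    f1 <- linked[linked$frame_index == 1L, ]
    f2 <- linked[linked$frame_index == 2L, ]
    row_a <- match(paste(f1$x_px, f1$y_px), paste(a[, 1], a[, 2]))
    row_b <- match(paste(f2$x_px, f2$y_px), paste(b[, 1], b[, 2]))
    carried <- f2$track %in% f1$track
    got_pairs <- cbind(row_a[match(f2$track[carried], f1$track)],
                       row_b[carried])
    got_pairs <- got_pairs[order(got_pairs[, 1]), , drop = FALSE]
    oracle <- brute_force_assignment(a, b, 10)
    expect_equal(got_pairs, oracle, ignore_attr = TRUE)
  }
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(5)
  det <- tibble::tibble(
    frame_index = rep(1:6, each = 3),
    time_s = rep(1:6, each = 3) * 1e-3,
    x_px = rep(c(10, 50, 90), 6) + rnorm(18, 0, 1),
    y_px = rep(c(20, 20, 20), 6) + rnorm(18, 0, 1),
    area = 5L, peak = 30)
  shuffled <- det[sample(nrow(det)), ]
  l1 <- link_tracks(det, 10)
  l2 <- link_tracks(shuffled, 10)
  key <- function(x) {
    x <- x[order(x$frame_index, x$x_px), ]
    split(paste(x$frame_index, round(x$x_px, 6)), x$track)
  }
  expect_setequal(unname(key(l1)), unname(key(l2)))
})

test_that("tracks split after more than max_frame_gap missed frames", {
  det <- tibble::tibble(
    frame_index = c(1L, 2L, 3L, 8L, 9L),
    time_s = c(1, 2, 3, 8, 9) * 1e-3,
    x_px = 50, y_px = 20, area = 5L, peak = 30)
  linked <- link_tracks(det, max_disp_px = 10, max_frame_gap = 2)
  expect_equal(length(unique(linked$track)), 2)
  # short gap is bridged
  det2 <- det
  det2$frame_index <- c(1L, 2L, 3L, 5L, 6L)
  expect_equal(length(unique(link_tracks(det2, 10, 2)$track)), 1)
})

test_that("IM events recover transit kinematics and lateral position", {
  g <- straight_30()
  ds <- quick_dataset(g, n = 3, duration = 0.08, seed = 33, render = TRUE,
                      y_frac = 0)
  im <- detect_im_events(ds$frames, g, expected_diameter_um = 10)
  tru <- ground_truth(ds$trace)
  expect_equal(nrow(im), 3)
  expect_true(all(im$complete))
  expect_equal(sort(im$duration_s), sort(tru$duration_s), tolerance = 2e-5 / min(tru$duration_s))
  # on-axis particles: |mean lateral| below half a pixel's worth of microns
  expect_true(all(abs(im$y_mean_um) < 0.5 * ds$frames$scale_um_px))
})

test_that("tracks that never cross both planes are flagged incomplete", {
  g <- straight_30()
  acq <- acquisition_model()
  # trajectory truncated before the exit: render only the first half
  tr <- simulate_trajectory(g, flow_model(1e5), 0, 0.001)
  fs <- render_frames(list(tr), g, acq, t_end = 0.001 + 0.0006)
  im <- detect_im_events(fs, g, expected_diameter_um = 10)
  expect_equal(nrow(im), 1)
  expect_false(im$complete[1])
  expect_true(is.na(im$duration_s[1]))
})
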