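#' Render microscopy frames for a set of trajectories
#'
#' Produces the imaging stream: dark anti-aliased particle disks on a bright
#' background with the channel walls drawn as static dark outlines (present
#' in the particle-free template as well, so template subtraction removes
#' them). Each frame shows the particles at their position at the frame's
#' mid-exposure time. Frame-start timestamps are truthful
#' (`j * frame_period`); the camera is the reference clock. By default only
#' frames during which at least one particle is inside the field of view are
#' rendered (plus a small pad); their true frame indices are kept so
#' inter-event gaps remain visible to downstream tracking.
#'
#' @param trajectories List of [simulate_trajectory()] objects.
#' @param geom A [channel_geometry()].
#' @param acq An [acquisition_model()].
#' @param frame A [channel_frame()] mapping channel to pixel coordinates;
#'   default [default_channel_frame()] for the acquisition image size.
#' @param t_end End of the recording (s); default just after the last path.
#' @param active_only Render only frames with a particle in view.
#' @param pad_frames Extra frames kept on each side of an active window.
#' @return An object of class `frame_sequence`: fields `frames` (list of
#'   integer matrices, grey levels 0–255, row = image y, column = image x),
#'   `frame_index` (0-based true indices), `time_s` (frame-start
#'   timestamps), `exposure_s`, `template`, `frame` (the channel frame),
#'   `scale_um_px`.
#' @export
render_frames <- function(trajectories, geom, acq, frame = NULL,
                          t_end = NULL, active_only = TRUE, pad_frames = 4) {
  stopifnot(inherits(geom, "channel_geometry"),
            inherits(acq, "acquisition_model"))
  if (is.null(frame)) {
    frame <- default_channel_frame(geom, scale_um_px = acq$scale_um_px,
                                   margin_px = round(acq$image_nx_px / 6),
                                   ny_px = acq$image_ny_px)
  }
  if (is.null(t_end)) {
    t_end <- if (length(trajectories)) {
      max(vapply(trajectories, function(tr) max(tr$t_s), numeric(1)))
    } else 0
  }
  dtf <- acq$frame_period_s
  n_frames <- max(floor(t_end / dtf) + 1L, 1L)

  template <- render_template(geom, acq, frame)

  if (active_only && length(trajectories)) {
    keep <- sort(unique(unlist(lapply(trajectories, function(tr) {
      j0 <- max(0L, floor(tr$t_s[1] / dtf) - pad_frames)
      j1 <- min(n_frames - 1L, ceiling(tr$t_s[length(tr$t_s)] / dtf) + pad_frames)
      if (j1 < j0) integer(0) else j0:j1
    }))))
  } else {
    keep <- 0:(n_frames - 1L)
  }

  # precompute, per trajectory, the pixel position at every frame it spans
  t_mid_all <- keep * dtf + acq$exposure_s / 2
  draws <- vector("list", length(keep))
  for (p in seq_along(trajectories)) {
    tr <- trajectories[[p]]
    r_px <- tr$d / 2 / frame$scale_um_px
    active <- which(t_mid_all >= tr$t_s[1] & t_mid_all <= max(tr$t_s))
    if (!length(active)) next
    pos <- trajectory_position(tr, t_mid_all[active])
    px <- to_pixel_coords(pos[, c("x_c", "y_c")], frame)
    for (k in seq_along(active)) {
      i <- active[k]
      draws[[i]] <- c(draws[[i]], list(c(px$x_px[k], px$y_px[k], r_px)))
    }
  }
  frames <- vector("list", length(keep))
  clipped <- 0L
  for (i in seq_along(keep)) {
    img <- template
    for (d in draws[[i]]) {
      drawn <- draw_disk(img, d[1], d[2], d[3], acq$particle_depth)
      if (is.null(drawn)) clipped <- clipped + 1L else img <- drawn
    }
    if (acq$pixel_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, acq$pixel_noise_sd),
                          nrow(img))
    }
    frames[[i]] <- quantize8(img)
  }
  if (clipped > 0) {
    message(sprintf("render_frames: %d particle draws outside field of view (clipped)",
                    clipped))
  }
  structure(list(frames = frames, frame_index = keep, time_s = keep * dtf,
                 exposure_s = acq$exposure_s, template = quantize8(template),
                 frame = frame, scale_um_px = frame$scale_um_px),
            class = "frame_sequence")
}

render_template <- function(geom, acq, frame, wall_contrast = 60) {
  img <- matrix(acq$background_level, acq$image_ny_px, acq$image_nx_px)
  # channel wall outline: boundary polylines y = +/- w(x)/2 for x in [0, L]
  xs <- seq(0, geom$length_um, by = frame$scale_um_px / 2)
  w <- width_profile(geom, xs)
  pts <- tibble::tibble(x_c = c(xs, xs), y_c = c(w / 2, -w / 2))
  px <- to_pixel_coords(pts, frame)
  rr <- round(px$y_px); cc <- round(px$x_px)
  ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
  img[cbind(rr[ok], cc[ok])] <- acq$background_level - wall_contrast
  img
}

# returns NULL when the disk lies entirely outside the image
draw_disk <- function(img, cx, cy, r_px, depth) {
  nr <- nrow(img); nc <- ncol(img)
  c0 <- floor(cx - r_px - 1); c1 <- ceiling(cx + r_px + 1)
  r0 <- floor(cy - r_px - 1); r1 <- ceiling(cy + r_px + 1)
  if (c1 < 1 || c0 > nc || r1 < 1 || r0 > nr) return(NULL)
  cols <- max(1, c0):min(nc, c1)
  rows <- max(1, r0):min(nr, r1)
  dist <- sqrt(outer((rows - cy)^2, (cols - cx)^2, `+`))
  coverage <- pmin(pmax(r_px + 0.5 - dist, 0), 1)  # 1 px anti-aliased edge
  img[rows, cols] <- img[rows, cols] - depth * coverage
  img
}

quantize8 <- function(img) {
  storage.mode(img) <- "double"
  m <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), nrow(img))
  m
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames (%d x %d px), %.4g um/px, %s\n",
              length(x$frames),
              if (length(x$frames)) nrow(x$frames[[1]]) else 0,
              if (length(x$frames)) ncol(x$frames[[1]]) else 0,
              x$scale_um_px,
              if (length(x$time_s)) sprintf("t in [%.4f, %.4f] s",
                                            min(x$time_s), max(x$time_s))
              else "empty"))
  invisible(x)
}
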