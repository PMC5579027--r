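#' Subtract a particle-free template from a frame
#'
#' Returns `template - frame`, so dark particles on a bright background give
#' a positive response while static features (channel walls, illumination
#' pattern) cancel. A constant brightness offset on the frame shifts the
#' whole difference by the negative of that constant; the robust automatic
#' threshold in [im_detect()] absorbs small offsets.
#'
#' @param frame,template Numeric/integer matrices of identical shape.
#' @return Numeric difference matrix.
#' @export
subtract_template <- function(frame, template) {
  if (!all(dim(frame) == dim(template))) {
    stop("frame and template dimensions differ", call. = FALSE)
  }
  template - frame
}

#' Threshold a difference image and label connected clusters
#'
#' Pixels with difference at or above `theta` are grouped into connected
#' components by flood fill under the chosen connectivity; components
#' smaller than `min_area` pixels are dropped. Cluster centroids are
#' intensity-weighted sub-pixel positions.
#'
#' @param diff Difference image from [subtract_template()].
#' @param theta Intensity threshold (> 0).
#' @param connectivity 4 or 8.
#' @param min_area Minimum cluster area (pixels).
#' @return A tibble with one row per cluster: `label`, `x_px`, `y_px`
#'   (centroid; x = column, y = row), `area`, `peak` (maximum difference).
#' @export
threshold_and_label <- function(diff, theta, connectivity = 8, min_area = 1) {
  stopifnot(theta > 0, connectivity %in% c(4, 8))
  df <- label_clusters(diff, theta, connectivity, min_area)
  tibble::as_tibble(df)
}

# base-R hot path shared by threshold_and_label() and im_detect()
label_clusters <- function(diff, theta, connectivity, min_area) {
  empty <- data.frame(label = integer(), x_px = numeric(), y_px = numeric(),
                      area = integer(), peak = numeric())
  hits <- which(diff >= theta)
  if (!length(hits)) return(empty)
  nr <- nrow(diff)
  row <- ((hits - 1L) %% nr) + 1L
  col <- ((hits - 1L) %/% nr) + 1L
  labels <- flood_fill_labels(hits, row, col, nr, connectivity)
  lab <- match(labels, unique(labels))
  w <- diff[hits]
  sw <- rowsum(w, lab)[, 1]
  x <- rowsum(col * w, lab)[, 1] / sw
  y <- rowsum(row * w, lab)[, 1] / sw
  area <- tabulate(lab)
  peak <- vapply(split(w, lab), max, numeric(1))
  keep <- area >= min_area
  if (!any(keep)) return(empty)
  ord <- order(x[keep], y[keep])
  data.frame(label = seq_along(ord),
             x_px = unname(x[keep][ord]), y_px = unname(y[keep][ord]),
             area = area[keep][ord], peak = unname(peak[keep][ord]))
}

# union-find flood fill over the sparse set of above-threshold pixels
flood_fill_labels <- function(hits, row, col, nr, connectivity) {
  m <- length(hits)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- list(c(1L, 0L), c(0L, 1L))            # down, right
  if (connectivity == 8) {
    offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))  # two diagonals
  }
  ord <- order(hits)
  pos <- hits[ord]
  for (off in offsets) {
    nb <- hits + off[1] + off[2] * nr
    valid <- (row + off[1]) >= 1 & (row + off[1]) <= nr
    j <- findInterval(nb, pos)
    match_ok <- valid & j >= 1 & j <= m
    match_ok[match_ok] <- pos[j[match_ok]] == nb[match_ok]
    for (i in which(match_ok)) {
      ra <- find(i); rb <- find(ord[j[i]])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(m), find, integer(1))
}

#' Detect particles in every frame of a sequence
#'
#' Runs template subtraction and [threshold_and_label()] on each frame. When
#' `theta` is `NULL` it is set automatically to `k_theta` times the robust
#' (MAD-based) noise scale of the difference images, with a floor of 10 grey
#' levels for noise-free imagery. When `min_area` is `NULL` it defaults to a
#' quarter of the expected particle disk area if `expected_diameter_um` is
#' given, else 4 pixels.
#'
#' @param frames A `frame_sequence` (see [render_frames()] / [read_frames()]).
#' @param theta Intensity threshold, or `NULL` for automatic.
#' @param k_theta Multiplier for the automatic threshold.
#' @param connectivity 4 or 8.
#' @param min_area Minimum cluster area (px), or `NULL` for automatic.
#' @param expected_diameter_um Expected particle diameter used for the
#'   automatic `min_area`.
#' @return A tibble of detections: `frame_index`, `time_s` (mid-exposure),
#'   `x_px`, `y_px`, `area`, `peak`; attribute `theta`.
#' @export
im_detect <- function(frames, theta = NULL, k_theta = 5, connectivity = 8,
                      min_area = NULL, expected_diameter_um = NULL) {
  stopifnot(inherits(frames, "frame_sequence"))
  n <- length(frames$frames)
  if (is.null(min_area)) {
    min_area <- if (!is.null(expected_diameter_um)) {
      max(1, floor(pi * (expected_diameter_um / 2 / frames$scale_um_px)^2 / 4))
    } else 4
  }
  template <- frames$template
  if (is.null(theta)) {
    probe <- unique(round(seq(1, n, length.out = min(n, 32))))
    sig <- stats::median(vapply(probe, function(i) {
      mad_sigma(as.numeric(template - frames$frames[[i]]))
    }, numeric(1)))
    theta <- max(k_theta * sig, 10)
  }
  dets <- vector("list", n)
  for (i in seq_len(n)) {
    d <- label_clusters(template - frames$frames[[i]], theta, connectivity,
                        min_area)
    if (nrow(d)) {
      d$frame_index <- frames$frame_index[i]
      d$time_s <- frames$time_s[i] + frames$exposure_s / 2
      dets[[i]] <- d
    }
  }
  dets <- dets[!vapply(dets, is.null, logical(1))]
  out <- if (length(dets)) {
    tibble::as_tibble(do.call(rbind, dets))
  } else {
    tibble::tibble(label = integer(), x_px = numeric(), y_px = numeric(),
                   area = integer(), peak = numeric(),
                   frame_index = integer(), time_s = numeric())
  }
  out <- dplyr::relocate(out, "frame_index", "time_s")
  attr(out, "theta") <- theta
  out
}

#' Link per-frame detections into particle tracks
#'
#' Greedy globally-minimum-distance frame-to-frame assignment: all candidate
#' (active track, new detection) pairs within `max_disp_px` are sorted by
#' distance and accepted when both endpoints are still unassigned. Unmatched
#' detections start new tracks; a track ends after `max_frame_gap`
#' consecutive missed frames. Deterministic and independent of detection
#' order within a frame.
#'
#' @param detections Detection tibble from [im_detect()].
#' @param max_disp_px Maximum linking displacement between consecutive
#'   observations (px).
#' @param max_frame_gap Maximum number of consecutive frames a track may be
#'   missed before it is terminated.
#' @return The detections with an added `track` column.
#' @export
link_tracks <- function(detections, max_disp_px, max_frame_gap = 2) {
  det <- dplyr::arrange(detections, .data$frame_index, .data$x_px, .data$y_px)
  n <- nrow(det)
  track <- integer(n)
  if (!n) {
    det$track <- track
    return(det)
  }
  next_track <- 0L
  # active track state: id, last x, y, last frame
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- integer(0); act_row <- integer(0)
  frames_u <- unique(det$frame_index)
  idx_by_frame <- split(seq_len(n), factor(det$frame_index, levels = frames_u))
  for (f in seq_along(frames_u)) {
    fi <- frames_u[f]
    rows <- idx_by_frame[[f]]
    live <- which(fi - act_f <= max_frame_gap + 1L)
    assigned_det <- rep(FALSE, length(rows))
    assigned_trk <- rep(FALSE, length(live))
    if (length(live) && length(rows)) {
      dx <- outer(act_x[live], det$x_px[rows], `-`)
      dy <- outer(act_y[live], det$y_px[rows], `-`)
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= max_disp_px)
      if (length(cand)) {
        ord <- cand[order(dist[cand])]
        for (k in ord) {
          ti <- ((k - 1L) %% length(live)) + 1L
          di <- ((k - 1L) %/% length(live)) + 1L
          if (assigned_trk[ti] || assigned_det[di]) next
          assigned_trk[ti] <- TRUE
          assigned_det[di] <- TRUE
          r <- rows[di]
          track[r] <- act_id[live[ti]]
          li <- live[ti]
          act_x[li] <- det$x_px[r]; act_y[li] <- det$y_px[r]; act_f[li] <- fi
        }
      }
    }
    new_rows <- rows[!assigned_det]
    for (r in new_rows) {
      next_track <- next_track + 1L
      track[r] <- next_track
      act_id <- c(act_id, next_track)
      act_x <- c(act_x, det$x_px[r]); act_y <- c(act_y, det$y_px[r])
      act_f <- c(act_f, fi)
    }
    keep <- which(fi - act_f <= max_frame_gap + 1L)
    act_id <- act_id[keep]; act_x <- act_x[keep]; act_y <- act_y[keep]
    act_f <- act_f[keep]
  }
  det$track <- track
  det
}

#' Build imaging events from linked tracks
#'
#' Converts each track's centroids to channel coordinates, interpolates the
#' entrance (`x_c = 0`) and exit (`x_c = L`) crossing times, and summarises
#' the lateral position as the mean `y_c` over in-channel frames. Tracks
#' that never cross both planes are flagged incomplete (no duration).
#'
#' @param detections Tracked detections from [link_tracks()].
#' @param frame A [channel_frame()].
#' @param geom A [channel_geometry()].
#' @param min_detections Minimum track length (detections).
#' @return A tibble of IM events: `track`, `t_entry_s`, `t_exit_s`,
#'   `duration_s`, `y_mean_um`, `n_frames`, `complete`, and a `path`
#'   list-column of per-frame `(t_s, x_c, y_c)`.
#' @export
im_events <- function(detections, frame, geom, min_detections = 2) {
  stopifnot(inherits(frame, "channel_frame"), inherits(geom, "channel_geometry"))
  if (!nrow(detections)) {
    return(tibble::tibble(track = integer(), t_entry_s = numeric(),
                          t_exit_s = numeric(), duration_s = numeric(),
                          y_mean_um = numeric(), n_frames = integer(),
                          complete = logical(), path = list()))
  }
  L <- geom$length_um
  det <- dplyr::bind_cols(
    detections,
    to_channel_coords(data.frame(x_px = detections$x_px,
                                 y_px = detections$y_px), frame))
  det |>
    dplyr::group_by(.data$track) |>
    dplyr::filter(dplyr::n() >= min_detections) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      t_entry <- crossing_time(g$time_s, g$x_c, 0)
      t_exit <- crossing_time(g$time_s, g$x_c, L)
      complete <- !is.na(t_entry) && !is.na(t_exit) && t_exit > t_entry
      inside <- g$x_c >= 0 & g$x_c <= L
      tibble::tibble(
        t_entry_s = t_entry, t_exit_s = t_exit,
        duration_s = if (complete) t_exit - t_entry else NA_real_,
        y_mean_um = if (any(inside)) mean(g$y_c[inside]) else mean(g$y_c),
        n_frames = nrow(g), complete = complete,
        path = list(tibble::tibble(t_s = g$time_s, x_c = g$x_c, y_c = g$y_c)))
    }) |>
    dplyr::ungroup()
}

# first upward crossing of `level` by linear interpolation
crossing_time <- function(t, x, level) {
  below <- x < level
  cross <- which(below[-length(below)] & !below[-1])
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  t[i] + (level - x[i]) / (x[i + 1] - x[i]) * (t[i + 1] - t[i])
}

#' Full imaging pipeline: detect, link, build events
#'
#' @inheritParams im_detect
#' @inheritParams link_tracks
#' @param geom A [channel_geometry()].
#' @param max_disp_px Maximum linking displacement; `NULL` chooses half the
#'   image width travelled per frame is unknown, so the default is 1/8 of
#'   the image's larger dimension.
#' @return An IM event tibble (see [im_events()]) with the detections in
#'   attribute `detections`.
#' @export
detect_im_events <- function(frames, geom, theta = NULL, connectivity = 8,
                             min_area = NULL, expected_diameter_um = NULL,
                             max_disp_px = NULL, max_frame_gap = 2) {
  det <- im_detect(frames, theta = theta, connectivity = connectivity,
                   min_area = min_area,
                   expected_diameter_um = expected_diameter_um)
  if (is.null(max_disp_px)) {
    dims <- if (length(frames$frames)) dim(frames$frames[[1]]) else c(32, 32)
    max_disp_px <- max(dims) / 8
  }
  linked <- link_tracks(det, max_disp_px, max_frame_gap)
  ev <- im_events(linked, frames$frame, geom)
  attr(ev, "detections") <- linked
  ev
}
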