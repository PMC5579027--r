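#' Build a channel coordinate frame from image corner points
#'
#' The channel's coordinate frame in an image is anchored on the four channel
#' corners (sub-pixel positions allowed). The origin is the midpoint of the
#' two entrance-side corners; the axial unit vector is the normalised mean of
#' the two entrance-to-exit corner vectors; the lateral unit vector is the
#' axial vector rotated +90 degrees, so the frame is exactly orthonormal even
#' when the clicked corners are slightly off a perfect rectangle. The scale
#' (µm per pixel) comes from the known physical channel length divided by the
#' mean pixel span between the entrance and exit corner pairs.
#'
#' @param entrance Two-row matrix (or 2-vector list) of the entrance-side
#'   corner pixel positions, columns `(x, y)`.
#' @param exit Two-row matrix of the exit-side corner positions.
#' @param physical_length_um Physical axial length of the channel (µm).
#' @return An object of class `channel_frame` with fields `origin_px`,
#'   `xhat`, `yhat` and `scale_um_px`.
#' @export
#' @examples
#' fr <- channel_frame(rbind(c(10, 20), c(10, 40)),
#'                     rbind(c(110, 20), c(110, 40)), 150)
#' fr$scale_um_px  # 1.5
channel_frame <- function(entrance, exit, physical_length_um) {
  entrance <- as_corner_pair(entrance, "entrance")
  exit <- as_corner_pair(exit, "exit")
  if (physical_length_um <= 0) stop("`physical_length_um` must be > 0", call. = FALSE)

  origin <- colMeans(entrance)
  axis_vecs <- exit - entrance          # two entrance -> exit vectors
  axis_mean <- colMeans(axis_vecs)
  span_px <- sqrt(sum(axis_mean^2))
  if (span_px < 1e-9) {
    stop("invalid geometry: entrance and exit corner pairs coincide", call. = FALSE)
  }
  xhat <- axis_mean / span_px
  yhat <- c(-xhat[2], xhat[1])          # +90 degree rotation
  structure(
    list(origin_px = unname(origin), xhat = unname(xhat), yhat = unname(yhat),
         scale_um_px = physical_length_um / span_px,
         entrance_px = entrance, exit_px = exit,
         physical_length_um = physical_length_um),
    class = "channel_frame")
}

as_corner_pair <- function(x, side) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2)) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a 2x2 numeric matrix of (x, y) pixel positions", side),
         call. = FALSE)
  }
  x
}

#' @export
print.channel_frame <- function(x, ...) {
  cat(sprintf("<channel_frame> origin (%.2f, %.2f) px, scale %.4g um/px, xhat (%.4f, %.4f)\n",
              x$origin_px[1], x$origin_px[2], x$scale_um_px, x$xhat[1], x$xhat[2]))
  invisible(x)
}

#' Convert pixel positions to channel coordinates
#'
#' Projects pixel points onto the channel frame: `x_c` is the axial distance
#' from the entrance plane, `y_c` the signed lateral displacement from the
#' axis, both in micrometres. Any point is allowed, including points outside
#' the channel.
#'
#' @param points Data frame (or matrix) with columns `x_px`, `y_px`.
#' @param frame A [channel_frame()].
#' @return A tibble with columns `x_c`, `y_c` (µm).
#' @export
to_channel_coords <- function(points, frame) {
  stopifnot(inherits(frame, "channel_frame"))
  pts <- as_px_matrix(points)
  rel_x <- pts[, 1] - frame$origin_px[1]
  rel_y <- pts[, 2] - frame$origin_px[2]
  tibble::tibble(
    x_c = frame$scale_um_px * (rel_x * frame$xhat[1] + rel_y * frame$xhat[2]),
    y_c = frame$scale_um_px * (rel_x * frame$yhat[1] + rel_y * frame$yhat[2]))
}

#' Convert channel coordinates to pixel positions
#'
#' Inverse of [to_channel_coords()].
#'
#' @param points Data frame with columns `x_c`, `y_c` (µm).
#' @param frame A [channel_frame()].
#' @return A tibble with columns `x_px`, `y_px`.
#' @export
to_pixel_coords <- function(points, frame) {
  stopifnot(inherits(frame, "channel_frame"))
  points <- as.data.frame(points)
  u <- points$x_c / frame$scale_um_px
  v <- points$y_c / frame$scale_um_px
  tibble::tibble(
    x_px = frame$origin_px[1] + u * frame$xhat[1] + v * frame$yhat[1],
    y_px = frame$origin_px[2] + u * frame$xhat[2] + v * frame$yhat[2])
}

as_px_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    return(points)
  }
  points <- as.data.frame(points)
  if (!all(c("x_px", "y_px") %in% names(points))) {
    stop("`points` needs columns `x_px` and `y_px`", call. = FALSE)
  }
  cbind(points$x_px, points$y_px)
}

#' Default channel frame for simulated imagery
#'
#' Places the channel horizontally in the image with the entrance at a fixed
#' pixel margin and the axis on the vertical midline of the frame.
#'
#' @param geom A [channel_geometry()].
#' @param scale_um_px Image scale (µm per pixel).
#' @param margin_px Pixels between the left image edge and the entrance plane.
#' @param ny_px Image height (pixels).
#' @return A [channel_frame()].
#' @export
default_channel_frame <- function(geom, scale_um_px = 2, margin_px = 30, ny_px = 40) {
  w <- if (geom$kind == "straight") geom$width_um else geom$width_narrow_um
  half_w_px <- w / 2 / scale_um_px
  len_px <- geom$length_um / scale_um_px
  y0 <- ny_px / 2
  channel_frame(
    entrance = rbind(c(margin_px, y0 - half_w_px), c(margin_px, y0 + half_w_px)),
    exit = rbind(c(margin_px + len_px, y0 - half_w_px),
                 c(margin_px + len_px, y0 + half_w_px)),
    physical_length_um = geom$length_um)
}
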