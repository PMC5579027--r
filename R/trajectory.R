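#' Simulate a particle trajectory through a channel
#'
#' Deterministic streamline transport: the particle enters the channel at
#' lateral position `y0` and keeps a constant relative lateral position
#' (`2 y / w(x)` is conserved, so `y` scales with the local width in the
#' cavity). The axial velocity in each constant-width section is
#' `v_max * (w_ref / w) * (1 - u0^2)` with `u0 = 2 y0 / w_ref` (parabolic
#' profile times 2D continuity, `w_ref` the narrowest width). Because the
#' velocity is piecewise constant in `x`, the path is piecewise linear in
#' time and is represented exactly by its breakpoints. The path extends a
#' margin before the entrance and after the exit at a reduced approach
#' velocity.
#'
#' @param geom A [channel_geometry()].
#' @param flow A [flow_model()].
#' @param y0 Lateral entry position of the particle centre (µm); must lie
#'   within the accessible range `|y0| <= (w_min - d)/2`.
#' @param t_entry Time at which the particle crosses the entrance plane
#'   `x_c = 0` (s).
#' @param d Particle diameter (µm).
#' @param margin_um Path extension outside each channel end (µm).
#' @return An object of class `rp_trajectory`: breakpoints `t_s`, `x_um`
#'   plus fields `y0`, `d`, `duration_s` (entrance-to-exit transit time).
#' @export
simulate_trajectory <- function(geom, flow, y0, t_entry, d = 10,
                                margin_um = 30) {
  stopifnot(inherits(geom, "channel_geometry"), inherits(flow, "flow_model"))
  hw <- accessible_half_width(geom, d)
  if (abs(y0) > hw) {
    stop(sprintf("`y0` = %.3f um outside accessible range [%.3f, %.3f] um",
                 y0, -hw, hw), call. = FALSE)
  }
  w_ref <- if (geom$kind == "straight") geom$width_um else geom$width_narrow_um
  u0 <- 2 * y0 / w_ref
  L <- geom$length_um

  # section boundaries and widths
  if (geom$kind == "straight") {
    bounds <- c(0, L)
    widths <- geom$width_um
  } else {
    bounds <- c(0, geom$cavity_start_um, geom$cavity_end_um, L)
    widths <- c(geom$width_narrow_um, geom$width_wide_um, geom$width_narrow_um)
  }
  v_section <- flow$v_max_um_s * (w_ref / widths) * (1 - u0^2)

  x_break <- c(-margin_um, bounds, L + margin_um)
  v_piece <- c(flow$outside_speed * v_section[1], v_section,
               flow$outside_speed * v_section[length(v_section)])
  seg_len <- diff(x_break)
  seg_dt <- seg_len / v_piece
  t_break <- cumsum(c(0, seg_dt))
  # anchor t = t_entry at x = 0 (second breakpoint)
  t_break <- t_break - t_break[2] + t_entry

  structure(list(t_s = t_break, x_um = x_break, y0 = y0, u0 = u0, d = d,
                 w_ref = w_ref,
                 t_entry = t_entry, t_exit = t_break[length(t_break) - 1],
                 duration_s = t_break[length(t_break) - 1] - t_entry,
                 geom = geom),
            class = "rp_trajectory")
}

#' Evaluate a trajectory at arbitrary times
#'
#' Linear interpolation of the exact piecewise-linear path. Lateral position
#' follows the streamline: `y = y0 * w(x) / w_ref` inside the channel and
#' `y0` outside.
#'
#' @param traj An [simulate_trajectory()] result.
#' @param t Times (s); clamped to the path's time span.
#' @return A tibble with columns `t_s`, `x_c`, `y_c` (µm).
#' @export
trajectory_position <- function(traj, t) {
  stopifnot(inherits(traj, "rp_trajectory"))
  x <- stats::approx(traj$t_s, traj$x_um, t, rule = 2)$y
  w <- width_profile(traj$geom, x)
  y <- ifelse(is.finite(w), traj$y0 * w / traj$w_ref, traj$y0)
  tibble::tibble(t_s = t, x_c = x, y_c = y)
}

#' @export
print.rp_trajectory <- function(x, ...) {
  cat(sprintf("<rp_trajectory> y0 = %.2f um, entry %.6f s, transit %.3f ms\n",
              x$y0, x$t_entry, 1e3 * x$duration_s))
  invisible(x)
}
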