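#' On-axis resistive-pulse amplitude in a cylindrical channel
#'
#' Smythe's closed form for the relative current blockade produced by an
#' insulating sphere on the axis of a long cylindrical channel:
#' \deqn{\Delta I / I_p = \frac{d^3}{L D^2}\left[1 - 0.8 (d/D)^3\right]^{-1}}
#' where `d` is the sphere diameter and `L`, `D` the channel length and
#' diameter. Dimensionless; any consistent length unit may be used.
#'
#' @param d Particle diameter.
#' @param D Channel diameter (same unit as `d`); must exceed `d`.
#' @param L Channel length (same unit).
#' @return Relative amplitude \eqn{\Delta I/I_p} (dimensionless); vectorised.
#' @export
#' @examples
#' smythe_amplitude(10, 30, 150)  # 0.0076336
smythe_amplitude <- function(d, D, L) {
  if (any(d <= 0) || any(L <= 0)) stop("`d` and `L` must be > 0", call. = FALSE)
  if (any(d >= D)) stop("particle diameter `d` must be smaller than channel diameter `D`",
                        call. = FALSE)
  d^3 / (L * D^2) / (1 - 0.8 * (d / D)^3)
}

#' Off-axis amplitude enhancement factor
#'
#' Empirical correction for particles translocating off the channel axis:
#' \deqn{\Delta V(y)/\Delta V(0) = 1 + \alpha (y_{norm}\, d / D)^3}
#' with `y_norm` the lateral displacement of the particle centre normalised by
#' the channel radius (0 on axis, 1 at the wall). The coefficient `alpha` was
#' reported in the range 5–7.5 for pressure-driven micropore experiments.
#'
#' @param y_norm Normalised lateral displacement, `0 <= y_norm <= (D-d)/D`
#'   (the particle centre cannot pass beyond wall contact); vectorised.
#' @param d,D Particle and channel diameters (same unit), `d < D`.
#' @param alpha Off-axis coefficient, `alpha >= 0`. Default 6, the midpoint of
#'   the reported range.
#' @return Enhancement ratio `>= 1`.
#' @export
offaxis_factor <- function(y_norm, d, D, alpha = 6) {
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (any(d >= D)) stop("`d` must be smaller than `D`", call. = FALSE)
  lim <- (D - d) / D
  if (any(y_norm < -1e-12) || any(y_norm > lim + 1e-12)) {
    stop(sprintf("`y_norm` must lie in [0, (D-d)/D] = [0, %.4f]", min(lim)),
         call. = FALSE)
  }
  1 + alpha * (y_norm * d / D)^3
}

#' Local resistance change caused by a particle
#'
#' Change in channel resistance when a sphere occupies a position where the
#' local (equivalent) diameter is `D`:
#' \deqn{\Delta R = \frac{4 \rho d^3}{\pi D^4}\left[1 - 0.8 (d/D)^3\right]^{-1}}
#' The form depends only on the geometry local to the particle, which is what
#' makes it applicable to channels of non-constant width.
#'
#' @param rho Solution resistivity (Ω·m).
#' @param d Particle diameter (µm).
#' @param D Local channel diameter (µm), `D > d`; vectorised.
#' @return Resistance change (Ω).
#' @export
#' @examples
#' local_delta_r(1, 10, 30)  # ~1620 ohm
local_delta_r <- function(rho, d, D) {
  if (any(rho <= 0)) stop("`rho` must be > 0", call. = FALSE)
  if (any(d <= 0)) stop("`d` must be > 0", call. = FALSE)
  if (any(d >= D)) stop("`d` must be smaller than `D`", call. = FALSE)
  d_m <- d * 1e-6
  D_m <- D * 1e-6
  4 * rho * d_m^3 / (pi * D_m^4) / (1 - 0.8 * (d / D)^3)
}

#' Predicted amplitude ratio between two channel regions
#'
#' Ratio of relative blockade amplitudes at two axial positions with local
#' diameters `D1` and `D2`. Because \eqn{\Delta R/R_0 = \Delta I/I_p}, the
#' ratio of local resistance changes equals the ratio of relative current
#' amplitudes and is independent of the solution resistivity.
#'
#' @param d Particle diameter (µm).
#' @param D1,D2 Local diameters at the two positions (µm), both `> d`.
#' @return Dimensionless ratio \eqn{\Delta R|_{D_1} / \Delta R|_{D_2}}.
#' @export
#' @examples
#' # 20/50 um cavity channel, 20 um high: cavity (wide) over narrow
#' amplitude_ratio(10, equivalent_diameter(50, 20), equivalent_diameter(20, 20))
amplitude_ratio <- function(d, D1, D2) {
  local_delta_r(1, d, D1) / local_delta_r(1, d, D2)
}

#' Theoretical wide/narrow amplitude ratio for a cavity channel
#'
#' Convenience wrapper: maps the rectangular narrow and wide sections of a
#' cavity channel to equivalent circular diameters and returns the predicted
#' ratio of the blockade in the cavity (wide) to the blockade in the narrow
#' constriction.
#'
#' @param geom A cavity [channel_geometry()].
#' @param d Particle diameter (µm).
#' @return Dimensionless ratio (wide over narrow), < 1.
#' @export
cavity_ratio_theory <- function(geom, d) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (geom$kind != "cavity") stop("`geom` must be a cavity channel", call. = FALSE)
  D_n <- equivalent_diameter(geom$width_narrow_um, geom$height_um)
  D_w <- equivalent_diameter(geom$width_wide_um, geom$height_um)
  amplitude_ratio(d, D_w, D_n)
}

#' Maximum off-axis amplitude excess for a channel
#'
#' Percentage excess of the off-axis amplitude over the on-axis value at the
#' largest lateral displacement accessible to the particle centre
#' (`y_norm = (D-d)/D` in the equivalent cylinder).
#'
#' @param d Particle diameter (µm).
#' @param w,h Rectangular channel width and height (µm), mapped to the
#'   equivalent circular diameter.
#' @param alpha Off-axis coefficient.
#' @return Excess in percent, `100 * (factor - 1)`.
#' @export
#' @examples
#' max_offaxis_excess(10, 15, 20, alpha = 7.5)
max_offaxis_excess <- function(d, w, h, alpha = 6) {
  D <- equivalent_diameter(w, h)
  y_max <- (D - d) / D
  100 * (offaxis_factor(y_max, d, D, alpha) - 1)
}
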