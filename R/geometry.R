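#' Describe a microfluidic sensing channel
#'
#' Constructs the physical description of a straight channel or a channel with
#' a single central cavity (a wider section between two narrow constrictions).
#' All lengths are in micrometres; the solution resistivity is in ohm metres.
#'
#' @param kind `"straight"` or `"cavity"`.
#' @param length_um Total axial extent `L` of the channel (µm).
#' @param width_um Channel width for a straight channel (µm).
#' @param width_narrow_um,width_wide_um Widths of the narrow constrictions and
#'   the central cavity for a cavity channel (µm); `width_wide_um` must exceed
#'   `width_narrow_um`.
#' @param cavity_start_um,cavity_end_um Axial positions bounding the cavity,
#'   with `0 < cavity_start_um < cavity_end_um < length_um`.
#' @param height_um Channel height (µm). The devices emulated here are shallow
#'   (height comparable to the particle diameter) so vertical motion is
#'   constrained and the analysis is two-dimensional.
#' @param resistivity_ohm_m Resistivity of the electrolyte (Ω·m). Default
#'   0.095 Ω·m, typical of 1 M KCl at room temperature.
#'
#' @return An object of class `channel_geometry`.
#' @export
#' @examples
#' channel_geometry("straight", length_um = 150, width_um = 30)
#' channel_geometry("cavity", length_um = 150,
#'   width_narrow_um = 20, width_wide_um = 50,
#'   cavity_start_um = 50, cavity_end_um = 100)
channel_geometry <- function(kind = c("straight", "cavity"),
                             length_um,
                             width_um = NULL,
                             width_narrow_um = NULL,
                             width_wide_um = NULL,
                             cavity_start_um = NULL,
                             cavity_end_um = NULL,
                             height_um = 20,
                             resistivity_ohm_m = 0.095) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(length_um), length(length_um) == 1)
  if (length_um <= 0) stop("`length_um` must be > 0", call. = FALSE)
  if (height_um <= 0) stop("`height_um` must be > 0", call. = FALSE)
  if (resistivity_ohm_m <= 0) stop("`resistivity_ohm_m` must be > 0", call. = FALSE)

  if (kind == "straight") {
    if (is.null(width_um) || width_um <= 0) {
      stop("straight channels need `width_um` > 0", call. = FALSE)
    }
    geom <- list(kind = kind, length_um = length_um, width_um = width_um,
                 height_um = height_um, resistivity_ohm_m = resistivity_ohm_m)
  } else {
    if (is.null(width_narrow_um) || is.null(width_wide_um) ||
        width_narrow_um <= 0 || width_wide_um <= 0) {
      stop("cavity channels need positive `width_narrow_um` and `width_wide_um`",
           call. = FALSE)
    }
    if (width_wide_um <= width_narrow_um) {
      stop("`width_wide_um` must exceed `width_narrow_um`", call. = FALSE)
    }
    if (is.null(cavity_start_um) || is.null(cavity_end_um) ||
        cavity_start_um <= 0 || cavity_end_um <= cavity_start_um ||
        cavity_end_um >= length_um) {
      stop("cavity bounds must satisfy 0 < cavity_start_um < cavity_end_um < length_um",
           call. = FALSE)
    }
    geom <- list(kind = kind, length_um = length_um,
                 width_narrow_um = width_narrow_um, width_wide_um = width_wide_um,
                 cavity_start_um = cavity_start_um, cavity_end_um = cavity_end_um,
                 height_um = height_um, resistivity_ohm_m = resistivity_ohm_m)
  }
  structure(geom, class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  if (x$kind == "straight") {
    cat(sprintf("<channel_geometry> straight, L = %g um, w = %g um, h = %g um\n",
                x$length_um, x$width_um, x$height_um))
  } else {
    cat(sprintf(
      "<channel_geometry> cavity, L = %g um, w = %g/%g um (narrow/wide), cavity [%g, %g] um, h = %g um\n",
      x$length_um, x$width_narrow_um, x$width_wide_um,
      x$cavity_start_um, x$cavity_end_um, x$height_um))
  }
  invisible(x)
}

#' Local channel width along the axis
#'
#' Piecewise width profile `w(x_c)`. Positions outside the channel
#' (`x_c < 0` or `x_c > L`) return `Inf`, the "unbounded" sentinel for the
#' open reservoirs on either side.
#'
#' @param geom A [channel_geometry()].
#' @param x_c Axial positions (µm); vectorised.
#' @return Numeric vector of widths (µm), `Inf` outside the channel.
#' @export
width_profile <- function(geom, x_c) {
  stopifnot(inherits(geom, "channel_geometry"))
  w <- if (geom$kind == "straight") {
    rep(geom$width_um, length(x_c))
  } else {
    ifelse(x_c >= geom$cavity_start_um & x_c <= geom$cavity_end_um,
           geom$width_wide_um, geom$width_narrow_um)
  }
  w[x_c < 0 | x_c > geom$length_um] <- Inf
  w
}

#' Equivalent circular diameter of a rectangular cross-section
#'
#' Diameter of the circle with the same area as a `w` by `h` rectangle,
#' `D_eq = sqrt(4 w h / pi)`. Used to apply cylindrical-channel amplitude
#' formulas to rectangular microchannels.
#'
#' @param w,h Cross-section width and height (µm); vectorised.
#' @return Equivalent diameters (µm).
#' @export
#' @examples
#' equivalent_diameter(20, 20)  # 22.568
equivalent_diameter <- function(w, h) {
  if (any(w <= 0) || any(h <= 0)) {
    stop("cross-section dimensions must be > 0", call. = FALSE)
  }
  sqrt(4 * w * h / pi)
}

#' Local equivalent diameter along the axis
#'
#' `equivalent_diameter(width_profile(geom, x_c), h)`; `Inf` outside the
#' channel.
#'
#' @inheritParams width_profile
#' @return Numeric vector of diameters (µm).
#' @export
diameter_profile <- function(geom, x_c) {
  w <- width_profile(geom, x_c)
  out <- rep(Inf, length(w))
  inside <- is.finite(w)
  out[inside] <- equivalent_diameter(w[inside], geom$height_um)
  out
}

#' Baseline resistance of the open channel
#'
#' Series-resistance integral `R0 = rho * integral(1/A(x) dx)` over the
#' channel's piecewise-rectangular cross-sections (equal to the
#' equivalent-diameter cylindrical value, since the equivalent diameter
#' preserves cross-sectional area).
#'
#' @param geom A [channel_geometry()].
#' @return Baseline resistance (Ω).
#' @export
channel_resistance <- function(geom) {
  stopifnot(inherits(geom, "channel_geometry"))
  h <- geom$height_um * 1e-6
  rho <- geom$resistivity_ohm_m
  if (geom$kind == "straight") {
    rho * (geom$length_um * 1e-6) / (geom$width_um * 1e-6 * h)
  } else {
    l_cav <- (geom$cavity_end_um - geom$cavity_start_um) * 1e-6
    l_nar <- geom$length_um * 1e-6 - l_cav
    rho * (l_nar / (geom$width_narrow_um * 1e-6 * h) +
             l_cav / (geom$width_wide_um * 1e-6 * h))
  }
}

#' Lateral range accessible to a particle centre
#'
#' Half-range of lateral positions available to the centre of a particle of
#' diameter `d` in the narrowest section the particle traverses:
#' `(w_min - d) / 2`.
#'
#' @param geom A [channel_geometry()].
#' @param d Particle diameter (µm).
#' @return Half-range (µm).
#' @export
accessible_half_width <- function(geom, d) {
  w_min <- if (geom$kind == "straight") geom$width_um else geom$width_narrow_um
  if (d >= w_min) stop("particle diameter must be smaller than the narrowest width",
                       call. = FALSE)
  (w_min - d) / 2
}
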