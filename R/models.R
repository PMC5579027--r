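#' Flow model for particle transport
#'
#' Plane-Poiseuille transport in the channel's width dimension: the axial
#' velocity profile is parabolic across the width, particles follow
#' streamlines (no lateral drift), and the centreline velocity rescales with
#' local width by 2D continuity (flux conservation). The vertical dimension
#' is ignored because the channel height is comparable to the particle
#' diameter, constraining vertical motion.
#'
#' @param v_max_um_s Centreline axial velocity in the reference (narrowest)
#'   section, µm/s.
#' @param outside_speed Fraction of the entrance-section velocity used for
#'   the approach/departure path outside the channel.
#' @return An object of class `flow_model`.
#' @export
flow_model <- function(v_max_um_s = 1e5, outside_speed = 0.5) {
  stopifnot(v_max_um_s > 0, outside_speed > 0)
  structure(list(v_max_um_s = v_max_um_s, outside_speed = outside_speed),
            class = "flow_model")
}

#' Theory parameters for the off-axis amplitude model
#'
#' @param alpha Off-axis coefficient of the cubic enhancement term
#'   (dimensionless, reported range 5–7.5; default 6).
#' @return An object of class `theory_params`.
#' @export
theory_params <- function(alpha = 6) {
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  structure(list(alpha = alpha), class = "theory_params")
}

#' Entrance/exit transition and access-resistance model
#'
#' Phenomenological description of the amplitude envelope near the channel
#' mouths: inside each end the blockade ramps smoothly (cubic smoothstep)
#' from a fraction `access_frac` of its plateau value up to the plateau over
#' a length `ell_t_um`; outside the channel the access-resistance
#' contribution decays exponentially with distance. An optional cavity mode
#' tapers the blockade for off-axis particles inside the cavity
#' (`"suppressed_near_wall"`), reproducing the inverted lateral dependence
#' observed in cavity channels without claiming a physical field model.
#'
#' @param ell_t_um Transition length inside each channel end (µm).
#' @param access_frac Blockade fraction at the channel mouth (relative to the
#'   local plateau). With the default 0.5 the entrance/exit amplitudes sit at
#'   half maximum, so FWHM duration tracks the physical transit.
#' @param access_decay_um Exponential decay length of the access blockade
#'   outside the channel (µm).
#' @param cavity_mode `"none"` (default) or `"suppressed_near_wall"`.
#' @param cavity_magnitude Fractional amplitude suppression at the wall for
#'   the suppressed mode (default 0.4, i.e. a 40% centre-to-wall difference).
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(ell_t_um = 15, access_frac = 0.5,
                             access_decay_um = 20,
                             cavity_mode = c("none", "suppressed_near_wall"),
                             cavity_magnitude = 0.4) {
  cavity_mode <- match.arg(cavity_mode)
  stopifnot(ell_t_um >= 0, access_frac >= 0, access_frac <= 1,
            access_decay_um > 0, cavity_magnitude >= 0, cavity_magnitude <= 1)
  structure(list(ell_t_um = ell_t_um, access_frac = access_frac,
                 access_decay_um = access_decay_um, cavity_mode = cavity_mode,
                 cavity_magnitude = cavity_magnitude),
            class = "transition_model")
}

#' Acquisition model for the two measurement streams
#'
#' Sampling, clock and noise parameters of the current (DAQ) and imaging
#' (camera) streams. The camera is treated as the reference clock; the
#' current stream may run with a relative rate mismatch `clock_skew` and a
#' global `stream_offset` (its recorded timestamps are
#' `stream_offset + k * sample_period` while true sample times are
#' `k * sample_period * (1 + clock_skew)`).
#'
#' @param sample_period_s Current sampling period (s); default 4 µs.
#' @param frame_period_s Frame period (s); default 20 µs (50,000 frames/s).
#' @param exposure_s Camera exposure (s); default 5 µs.
#' @param clock_skew Relative clock-rate mismatch of the current stream
#'   (dimensionless, |skew| < 1e-3).
#' @param stream_offset_s Global offset of the current stream's recorded
#'   timestamps (s).
#' @param baseline_current_A Open-channel current `I0` (A).
#' @param noise_sd_A Gaussian current-noise standard deviation (A).
#' @param drift_amplitude Relative amplitude of the slow sinusoidal baseline
#'   drift (dimensionless).
#' @param drift_period_s Drift period (s).
#' @param image_nx_px,image_ny_px Image size in pixels.
#' @param scale_um_px Image scale (µm per pixel).
#' @param background_level Background grey level (0–255).
#' @param particle_depth Grey-level depth of a particle disk below background.
#' @param pixel_noise_sd Gaussian pixel-noise standard deviation (grey
#'   levels).
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(sample_period_s = 4e-6,
                              frame_period_s = 2e-5,
                              exposure_s = 5e-6,
                              clock_skew = 0,
                              stream_offset_s = 0,
                              baseline_current_A = 5e-8,
                              noise_sd_A = 0,
                              drift_amplitude = 0,
                              drift_period_s = 1,
                              image_nx_px = 120,
                              image_ny_px = 36,
                              scale_um_px = 2,
                              background_level = 200,
                              particle_depth = 120,
                              pixel_noise_sd = 2.5) {
  stopifnot(sample_period_s > 0, frame_period_s > 0, exposure_s > 0,
            abs(clock_skew) < 1e-3, noise_sd_A >= 0, pixel_noise_sd >= 0,
            baseline_current_A > 0)
  structure(list(sample_period_s = sample_period_s,
                 frame_period_s = frame_period_s, exposure_s = exposure_s,
                 clock_skew = clock_skew, stream_offset_s = stream_offset_s,
                 baseline_current_A = baseline_current_A,
                 noise_sd_A = noise_sd_A,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 image_nx_px = image_nx_px, image_ny_px = image_ny_px,
                 scale_um_px = scale_um_px,
                 background_level = background_level,
                 particle_depth = particle_depth,
                 pixel_noise_sd = pixel_noise_sd),
            class = "acquisition_model")
}

#' Closed-form instantaneous blockade for a particle at a given position
#'
#' Ground-truth relative blockade `a = dI/I_p` for a particle of diameter `d`
#' whose centre sits at axial position `x_c` on the streamline entering at
#' lateral position `y0`: the local-resistance form evaluated at the local
#' equivalent diameter and normalised by the open-channel resistance,
#' multiplied by the off-axis enhancement (narrow/straight sections), an
#' optional cavity lateral taper, and the entrance/exit transition envelope;
#' outside the channel the access blockade decays exponentially.
#'
#' @param geom A [channel_geometry()].
#' @param d Particle diameter (µm).
#' @param x_c Axial positions of the particle centre (µm); vectorised.
#' @param y0 Lateral entry position of the streamline (µm).
#' @param theory A [theory_params()].
#' @param transition A [transition_model()].
#' @return Numeric vector of relative blockades (dimensionless, >= 0).
#' @export
blockade_theory <- function(geom, d, x_c, y0 = 0,
                            theory = theory_params(),
                            transition = transition_model()) {
  stopifnot(inherits(geom, "channel_geometry"))
  L <- geom$length_um
  hw <- accessible_half_width(geom, d)
  if (abs(y0) > hw + 1e-9) {
    stop("`y0` outside the lateral range accessible to the particle centre",
         call. = FALSE)
  }
  frac <- abs(y0) / hw
  r0 <- channel_resistance(geom)

  base_at <- function(x) {
    D <- diameter_profile(geom, x)
    base <- local_delta_r(geom$resistivity_ohm_m, d, D) / r0
    in_cavity <- if (geom$kind == "cavity") {
      x >= geom$cavity_start_um & x <= geom$cavity_end_um
    } else rep(FALSE, length(x))
    fac <- numeric(length(x))
    # off-axis enhancement in narrow/straight sections
    y_norm <- frac * (D - d) / D
    fac[!in_cavity] <- offaxis_factor(y_norm[!in_cavity], d, D[!in_cavity],
                                      theory$alpha)
    if (any(in_cavity)) {
      taper <- if (transition$cavity_mode == "suppressed_near_wall") {
        1 - transition$cavity_magnitude * (1 - cos(pi * frac)) / 2
      } else 1
      fac[in_cavity] <- taper
    }
    base * fac
  }

  a <- numeric(length(x_c))
  inside <- x_c >= 0 & x_c <= L
  if (any(inside)) {
    x_in <- x_c[inside]
    env <- if (transition$ell_t_um > 0) {
      transition$access_frac + (1 - transition$access_frac) *
        smoothstep(x_in / transition$ell_t_um) *
        smoothstep((L - x_in) / transition$ell_t_um)
    } else 1
    a[inside] <- base_at(x_in) * env
  }
  if (any(!inside)) {
    x_out <- x_c[!inside]
    edge_x <- ifelse(x_out < 0, 0, L)
    dist <- ifelse(x_out < 0, -x_out, x_out - L)
    a[!inside] <- transition$access_frac * base_at(edge_x) *
      exp(-dist / transition$access_decay_um)
  }
  a
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  3 * u^2 - 2 * u^3
}
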