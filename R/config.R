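#' Read and validate a run configuration
#'
#' YAML (or JSON) configuration for the full pipeline. Unknown keys are
#' rejected with field-level messages so typos cannot silently fall back to
#' defaults. Sections: `geometry` (required), and optional `simulate`,
#' `acquisition`, `detect_rp`, `detect_im`, `sync`, `analyze`, `seed`.
#'
#' @param path YAML/JSON file path.
#' @return A validated `run_config` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

config_schema <- list(
  geometry = c("kind", "length_um", "width_um", "width_narrow_um",
               "width_wide_um", "cavity_start_um", "cavity_end_um",
               "height_um", "resistivity_ohm_m", "corners_px",
               "scale_um_px"),
  simulate = c("n_particles", "duration_s", "d_um", "v_max_um_s", "y_frac",
               "min_gap_s", "margin_um", "alpha", "ell_t_um", "access_frac",
               "access_decay_um", "cavity_mode", "cavity_magnitude",
               "render"),
  acquisition = c("sample_period_s", "frame_period_s", "exposure_s",
                  "clock_skew", "stream_offset_s", "baseline_current_A",
                  "noise_sd_A", "drift_amplitude", "drift_period_s",
                  "image_nx_px", "image_ny_px", "scale_um_px",
                  "background_level", "particle_depth", "pixel_noise_sd"),
  detect_rp = c("lowpass_hz", "detrend_window_s", "k", "hysteresis",
                "min_duration_s", "max_duration_s", "pad_s", "smooth_window",
                "amplitude_range", "duration_range"),
  detect_im = c("theta", "k_theta", "connectivity", "min_area",
                "max_disp_px", "max_frame_gap"),
  sync = c("tol", "max_fine_offset_s", "refine_ip", "ip_halfwidth_um"),
  analyze = c("map_bin_um", "profile_window_um", "lateral_bin_um"),
  seed = NULL)

#' Validate a configuration list
#'
#' @param cfg A named list (as parsed from YAML).
#' @return The validated `run_config`.
#' @export
validate_config <- function(cfg) {
  bad_sections <- setdiff(names(cfg), names(config_schema))
  if (length(bad_sections)) {
    stop(sprintf("unknown config section(s): %s",
                 paste(bad_sections, collapse = ", ")), call. = FALSE)
  }
  for (sec in setdiff(names(cfg), "seed")) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in `%s`: %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(cfg$geometry)) stop("config needs a `geometry` section", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Build a channel geometry from a config
#'
#' @param cfg A `run_config`.
#' @return A [channel_geometry()].
#' @export
config_geometry <- function(cfg) {
  g <- cfg$geometry
  args <- g[intersect(names(g), c("kind", "length_um", "width_um",
                                  "width_narrow_um", "width_wide_um",
                                  "cavity_start_um", "cavity_end_um",
                                  "height_um", "resistivity_ohm_m"))]
  do.call(channel_geometry, args)
}

config_acquisition <- function(cfg) {
  do.call(acquisition_model, cfg$acquisition %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
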