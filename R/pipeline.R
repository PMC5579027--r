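#' Run the full pipeline from one configuration
#'
#' simulate -> detect-rp -> detect-im -> sync -> analyze, writing every
#' intermediate product into `out_dir`: trace CSV + sidecar, TIFF stack +
#' timestamps, ground truth JSONL, RP/IM/matched event JSONL, map TSV and
#' profile CSV. Counts per stage are reported as structured messages. The
#' whole run is reproducible from the config's `seed`.
#'
#' @param cfg A `run_config` (see [read_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(cfg, out_dir) {
  cfg <- validate_config(unclass(cfg))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- config_geometry(cfg)
  sim <- cfg$simulate %||% list()
  acq <- config_acquisition(cfg)
  ds <- generate_dataset(
    geom,
    n_particles = sim$n_particles %||% 50,
    duration_s = sim$duration_s %||% 1,
    seed = cfg$seed %||% 1L,
    d = sim$d_um %||% 10,
    flow = flow_model(sim$v_max_um_s %||% 1e5),
    acq = acq,
    theory = theory_params(sim$alpha %||% 6),
    transition = transition_model(
      ell_t_um = sim$ell_t_um %||% 15,
      access_frac = sim$access_frac %||% 0.5,
      access_decay_um = sim$access_decay_um %||% 20,
      cavity_mode = sim$cavity_mode %||% "none",
      cavity_magnitude = sim$cavity_magnitude %||% 0.4),
    y_frac = sim$y_frac %||% 1,
    min_gap_s = sim$min_gap_s %||% 5e-3,
    margin_um = sim$margin_um %||% 30,
    render = sim$render %||% TRUE)
  write_trace(ds$trace, file.path(out_dir, "trace.csv"))
  if (!is.null(ds$frames)) write_frames(ds$frames, file.path(out_dir, "frames.tif"))
  write_events(ds$truth, file.path(out_dir, "ground_truth.jsonl"))
  message(sprintf("simulate: %d particles, %d samples, %d frames",
                  nrow(ds$truth), nrow(ds$trace),
                  if (is.null(ds$frames)) 0L else length(ds$frames$frames)))

  drp <- cfg$detect_rp %||% list()
  trace <- rp_preprocess(ds$trace,
                         lowpass_hz = drp$lowpass_hz %||% 1e4,
                         detrend_window_s = drp$detrend_window_s %||% 0.05,
                         k = drp$k %||% 6)
  rp <- rp_detect_events(trace, k = drp$k %||% 6,
                         hysteresis = drp$hysteresis %||% 0.5,
                         min_duration_s = drp$min_duration_s %||% 1e-4,
                         max_duration_s = drp$max_duration_s %||% 0.5,
                         pad_s = drp$pad_s %||% 5e-4)
  rp <- rp_characterize(rp, trace, smooth_window = drp$smooth_window %||% 15)
  if (!is.null(drp$amplitude_range) || !is.null(drp$duration_range)) {
    rp <- rp_gate_events(rp, amplitude_range = drp$amplitude_range,
                         duration_range = drp$duration_range)
  }
  write_events(dplyr::select(rp, -"samples"), file.path(out_dir, "rp_events.jsonl"))
  message(sprintf("detect-rp: %d events", nrow(rp)))

  res <- list(dataset = ds, trace = trace, rp_events = rp)
  if (!is.null(ds$frames)) {
    dim_cfg <- cfg$detect_im %||% list()
    im <- detect_im_events(ds$frames, geom,
                           theta = dim_cfg$theta,
                           connectivity = dim_cfg$connectivity %||% 8,
                           min_area = dim_cfg$min_area,
                           expected_diameter_um = sim$d_um %||% 10,
                           max_disp_px = dim_cfg$max_disp_px,
                           max_frame_gap = dim_cfg$max_frame_gap %||% 2)
    write_events(im, file.path(out_dir, "im_events.jsonl"))
    message(sprintf("detect-im: %d events (%d complete)",
                    nrow(im), sum(im$complete)))

    sy <- cfg$sync %||% list()
    matched <- match_events(rp, im, trace, geom,
                            tol = sy$tol %||% 2e-3,
                            max_fine_offset_s = sy$max_fine_offset_s %||% 5e-3,
                            refine_ip = sy$refine_ip %||% TRUE,
                            ip_halfwidth_um = sy$ip_halfwidth_um %||% 50)
    write_events(dplyr::select(matched, -"samples", -"extrema"),
                 file.path(out_dir, "matched_events.jsonl"))
    message(sprintf("sync: %d matched, %d/%d unpaired (rp/im), coarse offset %.6f s",
                    nrow(matched), length(attr(matched, "unmatched_rp")),
                    length(attr(matched, "unmatched_im")),
                    attr(matched, "coarse_offset")))

    if (nrow(matched)) {
      an <- cfg$analyze %||% list()
      map <- build_map(matched, bin_um = an$map_bin_um %||% 1)
      write_map(map, file.path(out_dir, "resistance_map.tsv"))
      prof <- axial_profile(matched,
                            half_window_um = an$profile_window_um %||% 1)
      utils::write.csv(as.data.frame(prof),
                       file.path(out_dir, "axial_profile.csv"),
                       row.names = FALSE)
      message(sprintf("analyze: %d map bins, saturation at x_c = %.1f um",
                      nrow(map), attr(prof, "saturation_x")))
      res$matched <- matched
      res$map <- map
      res$profile <- prof
    }
  }
  invisible(res)
}
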