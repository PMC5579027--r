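#' Generate a complete ground-truthed synthetic dataset
#'
#' Draws particle arrivals and lateral entry positions, simulates their
#' streamline trajectories, and synthesizes the two measurement streams
#' (current trace and frame sequence) with a shared physical ground truth
#' but independent clocks. Fully reproducible from `seed`: all stochastic
#' draws (lateral positions, then entry times, then current noise, then
#' per-frame pixel noise) flow from one generator in that order.
#'
#' @param geom A [channel_geometry()].
#' @param n_particles Number of translocations.
#' @param duration_s Recording length (s, true time).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param d Particle diameter (µm).
#' @param flow A [flow_model()].
#' @param acq An [acquisition_model()].
#' @param theory A [theory_params()].
#' @param transition A [transition_model()].
#' @param y_frac Fraction of the accessible lateral range used for the
#'   uniform `y0` draw (1 = full range); set 0 for on-axis particles.
#' @param min_gap_s Minimum spacing enforced between successive entrance
#'   times (s); arrivals are drawn uniformly (a Poisson process conditioned
#'   on its count) and then pushed apart to this spacing.
#' @param margin_um Trajectory extension outside the channel ends (µm).
#' @param render Render the imaging stream (set `FALSE` for current-only
#'   studies).
#' @param frame Optional [channel_frame()]; default derived from `acq`.
#' @return An object of class `rp_dataset`: list with elements `trace`
#'   (`rp_trace`), `frames` (`frame_sequence` or `NULL`), `truth` (tibble),
#'   `trajectories`, `geom`, `acq`, `theory`, `transition`, `d`.
#' @export
generate_dataset <- function(geom, n_particles, duration_s, seed = NULL,
                             d = 10,
                             flow = flow_model(),
                             acq = acquisition_model(),
                             theory = theory_params(),
                             transition = transition_model(),
                             y_frac = 1, min_gap_s = 5e-3,
                             margin_um = 30,
                             render = TRUE, frame = NULL) {
  stopifnot(inherits(geom, "channel_geometry"), n_particles >= 0,
            duration_s > 0, y_frac >= 0, y_frac <= 1)
  if (!is.null(seed)) set.seed(seed)

  hw <- accessible_half_width(geom, d) * y_frac
  trajs <- list()
  if (n_particles > 0) {
    y0s <- if (hw > 0) stats::runif(n_particles, -hw, hw) else rep(0, n_particles)
    # worst-case pre/post path times bound the admissible entry window
    probe <- simulate_trajectory(geom, flow, max(abs(y0s)), 0, d, margin_um)
    t_pre <- probe$t_entry - probe$t_s[1]
    t_post <- probe$t_s[length(probe$t_s)] - probe$t_entry
    lo <- t_pre + 1e-4
    hi <- max(lo + 1e-4, duration_s - t_post - 1e-4)
    t_entry <- sort(stats::runif(n_particles, lo, hi))
    if (n_particles > 1) {
      for (i in 2:n_particles) {
        t_entry[i] <- max(t_entry[i], t_entry[i - 1] + min_gap_s)
      }
    }
    if (max(t_entry) > hi) {
      warning("entry times pushed past the requested duration to honour `min_gap_s`")
    }
    trajs <- lapply(seq_len(n_particles), function(i) {
      simulate_trajectory(geom, flow, y0s[i], t_entry[i], d, margin_um)
    })
  }

  total_dur <- max(duration_s,
                   if (length(trajs)) {
                     max(vapply(trajs, function(tr) max(tr$t_s), numeric(1))) + 1e-3
                   } else 0)
  trace <- synthesize_current(geom, trajs, acq, theory, transition, total_dur)
  frames <- if (render) {
    render_frames(trajs, geom, acq, frame = frame, t_end = total_dur)
  } else NULL

  structure(list(trace = trace, frames = frames, truth = ground_truth(trace),
                 trajectories = trajs, geom = geom, acq = acq,
                 theory = theory, transition = transition, d = d),
            class = "rp_dataset")
}

#' @export
print.rp_dataset <- function(x, ...) {
  cat(sprintf("<rp_dataset> %d particles, %d current samples%s\n",
              length(x$trajectories), nrow(x$trace),
              if (!is.null(x$frames)) sprintf(", %d frames", length(x$frames$frames))
              else ""))
  invisible(x)
}
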