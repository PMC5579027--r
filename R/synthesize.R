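#' Synthesize an ionic-current trace for a set of translocations
#'
#' Generates the current stream implied by the closed-form blockade model:
#' at every sample the total relative resistance change `a(t)` is the sum of
#' each in-flight particle's [blockade_theory()] value at its instantaneous
#' position, and the current follows Ohm's law
#' `I = I0 * (1 + drift(t)) / (1 + a(t)) + noise`, so the measured relative
#' blockade `(I0 - I)/I` recovers `a` exactly in the noise-free limit.
#' Sample times are generated on the current stream's clock: true sample
#' times are `k * dt * (1 + skew)` while recorded timestamps are
#' `offset + k * dt`.
#'
#' @param geom A [channel_geometry()].
#' @param trajectories List of [simulate_trajectory()] objects.
#' @param acq An [acquisition_model()].
#' @param theory A [theory_params()].
#' @param transition A [transition_model()].
#' @param duration_s Length of the trace (s, in true time).
#' @return An `rp_trace` tibble with columns `time_s` (recorded clock) and
#'   `current_A`, and attributes `sample_period_s`, `i0_A`, `truth` (a
#'   tibble of per-particle ground truth: true entry/exit times, `y0`,
#'   transit duration, plateau blockades per region).
#' @export
synthesize_current <- function(geom, trajectories, acq,
                               theory = theory_params(),
                               transition = transition_model(),
                               duration_s) {
  stopifnot(inherits(geom, "channel_geometry"),
            inherits(acq, "acquisition_model"))
  dt <- acq$sample_period_s
  n <- floor(duration_s / (dt * (1 + acq$clock_skew))) + 1L
  k <- seq_len(n) - 1L
  t_true <- k * dt * (1 + acq$clock_skew)
  t_rec <- acq$stream_offset_s + k * dt

  a_tot <- numeric(n)
  for (traj in trajectories) {
    t0 <- traj$t_s[1]
    t1 <- traj$t_s[length(traj$t_s)]
    i0 <- findInterval(t0, t_true) + 1L
    i1 <- findInterval(t1, t_true)
    if (i1 < i0) next
    idx <- i0:i1
    pos <- trajectory_position(traj, t_true[idx])
    a_tot[idx] <- a_tot[idx] +
      blockade_theory(geom, traj$d, pos$x_c, traj$y0, theory, transition)
  }

  drift <- if (acq$drift_amplitude != 0) {
    acq$drift_amplitude * sin(2 * pi * t_true / acq$drift_period_s)
  } else 0
  current <- acq$baseline_current_A * (1 + drift) / (1 + a_tot)
  if (acq$noise_sd_A > 0) {
    current <- current + stats::rnorm(n, 0, acq$noise_sd_A)
  }

  truth <- particle_truth(geom, trajectories, theory, transition)
  new_rp_trace(tibble::tibble(time_s = t_rec, current_A = current),
               sample_period_s = dt, i0_A = acq$baseline_current_A,
               truth = truth)
}

new_rp_trace <- function(data, sample_period_s, i0_A, truth = NULL) {
  structure(data, class = c("rp_trace", class(tibble::tibble())),
            sample_period_s = sample_period_s, i0_A = i0_A, truth = truth)
}

particle_truth <- function(geom, trajectories, theory, transition) {
  if (length(trajectories) == 0) return(NULL)
  L <- geom$length_um
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    row <- tibble::tibble(
      particle_id = i, t_entry_s = tr$t_entry, t_exit_s = tr$t_exit,
      duration_s = tr$duration_s, y0_um = tr$y0, d_um = tr$d,
      a_plateau = blockade_theory(geom, tr$d, L / 2, tr$y0, theory, transition))
    if (geom$kind == "cavity") {
      row$a_narrow <- blockade_theory(geom, tr$d, geom$cavity_start_um / 2,
                                      tr$y0, theory, transition)
      row$a_cavity <- blockade_theory(
        geom, tr$d, (geom$cavity_start_um + geom$cavity_end_um) / 2,
        tr$y0, theory, transition)
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Ground truth attached to a simulated trace or dataset
#'
#' @param x An `rp_trace` or `rp_dataset`.
#' @return A tibble of per-particle ground truth, or `NULL`.
#' @export
ground_truth <- function(x) {
  if (inherits(x, "rp_dataset")) return(x$truth)
  attr(x, "truth")
}
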