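# shared fixtures: standard channel geometries and small simulated datasets

straight_30 <- function() channel_geometry("straight", 150, width_um = 30)

cavity_2050 <- function() {
  channel_geometry("cavity", 150, width_narrow_um = 20, width_wide_um = 50,
                   cavity_start_um = 50, cavity_end_um = 100)
}

cavity_1730 <- function() {
  channel_geometry("cavity", 150, width_narrow_um = 17.5, width_wide_um = 30,
                   cavity_start_um = 50, cavity_end_um = 100)
}

# plateau amplitude of a 10 um bead in the 150 x 30 um (h = 20) channel
a30 <- function() smythe_amplitude(10, equivalent_diameter(30, 20), 150)

# quick current-only dataset
quick_dataset <- function(geom, n = 5, duration = 0.15, seed = 1, snr = 20,
                          y_frac = 1, render = FALSE, ...) {
  noise <- if (is.finite(snr)) {
    a <- blockade_theory(geom, 10, geom$length_um / 2, 0,
                         transition = transition_model())
    a * 5e-8 / snr
  } else 0
  generate_dataset(geom, n_particles = n, duration_s = duration, seed = seed,
                   acq = acquisition_model(noise_sd_A = noise),
                   y_frac = y_frac, render = render, ...)
}

detect_rp_pipeline <- function(ds, ...) {
  tr <- rp_preprocess(ds$trace)
  ev <- rp_detect_events(tr, ...)
  list(trace = tr, events = rp_characterize(ev, tr))
}

# brute-force minimum-total-distance assignment between two detection sets
# (test oracle for the greedy linker); returns matrix of pairs (i, j)
brute_force_assignment <- function(xy_a, xy_b, max_disp) {
  na <- nrow(xy_a); nb <- nrow(xy_b)
  if (na == 0 || nb == 0) return(matrix(integer(0), ncol = 2))
  k <- min(na, nb)
  best <- NULL
  best_cost <- Inf
  best_n <- -1L
  dist <- sqrt(outer(xy_a[, 1], xy_b[, 1], `-`)^2 +
                 outer(xy_a[, 2], xy_b[, 2], `-`)^2)
  # enumerate all injective partial assignments via recursion
  rec <- function(i, used_b, pairs, cost) {
    if (i > na) {
      n_p <- nrow(pairs)
      if (n_p > best_n || (n_p == best_n && cost < best_cost)) {
        best <<- pairs; best_cost <<- cost; best_n <<- n_p
      }
      return(invisible())
    }
    rec(i + 1L, used_b, pairs, cost)  # leave i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && dist[i, j] <= max_disp) {
        used_b[j] <- TRUE
        rec(i + 1L, used_b, rbind(pairs, c(i, j)), cost + dist[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), matrix(integer(0), ncol = 2), 0)
  best[order(best[, 1]), , drop = FALSE]
}
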