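#' Build a channel resistance map
#'
#' Accumulates every synchronized per-sample `(x_c, y_c, a)` tuple into a
#' 2D grid over channel coordinates and reports per-bin mean, standard
#' deviation and count of the relative blockade. Samples recorded while
#' more than one particle was inside the channel are excluded by default
#' (they superimpose blockades and do not represent the local resistance).
#' Bins never touched by a sample are absent from the table, not
#' zero-filled.
#'
#' @param matched A `matched_events` tibble from [match_events()].
#' @param bin_um Bin size (µm).
#' @param extent Optional `c(xmin, xmax, ymin, ymax)` crop (µm).
#' @param drop_multi Exclude multi-particle samples.
#' @return A `resistance_map` tibble: `x_c`, `y_c` (bin centres), `mean_a`,
#'   `sd_a`, `n`; attributes `bin_um`, `n_dropped_multi`.
#' @export
build_map <- function(matched, bin_um = 1, extent = NULL, drop_multi = TRUE) {
  if (!nrow(matched)) stop("no matched events", call. = FALSE)
  smp <- tidyr::unnest(matched[, c("rp_id", "samples")], "samples")
  n_multi <- sum(smp$n_in_channel > 1)
  if (drop_multi) smp <- dplyr::filter(smp, .data$n_in_channel <= 1)
  if (!is.null(extent)) {
    smp <- dplyr::filter(smp, .data$x_c >= extent[1], .data$x_c <= extent[2],
                         .data$y_c >= extent[3], .data$y_c <= extent[4])
  }
  # x bins are edge-anchored at the entrance plane, y bins centre-anchored on
  # the channel axis (the natural symmetry of channel coordinates)
  map <- smp |>
    dplyr::mutate(x_c = (floor(.data$x_c / bin_um) + 0.5) * bin_um,
                  y_c = round(.data$y_c / bin_um) * bin_um) |>
    dplyr::group_by(.data$x_c, .data$y_c) |>
    dplyr::summarise(mean_a = mean(.data$a), sd_a = stats::sd(.data$a),
                     n = dplyr::n(), .groups = "drop")
  class(map) <- c("resistance_map", class(map))
  attr(map, "bin_um") <- bin_um
  attr(map, "n_dropped_multi") <- if (drop_multi) n_multi else 0L
  map
}

#' Axial amplitude profile
#'
#' Moving average of the relative blockade over axial position: at each grid
#' centre the mean and standard deviation of all samples within
#' `half_window_um` are reported (windows with fewer than `min_count`
#' samples are excluded). Also locates the entrance/exit amplitudes, the
#' profile maximum, and the saturation position — the smallest in-channel
#' `x_c` at which the profile first reaches `(1 - sat_tol)` of its maximum,
#' a measure of how far into the channel the blockade keeps developing.
#'
#' @param matched A `matched_events` tibble.
#' @param half_window_um Half-width of the moving window (µm).
#' @param step_um Grid spacing (µm).
#' @param min_count Minimum samples per window.
#' @param sat_tol Relative tolerance defining amplitude saturation.
#' @param drop_multi Exclude multi-particle samples.
#' @return An `axial_profile` tibble `x_c`, `mean_a`, `sd_a`, `n`;
#'   attributes `entrance_a`, `exit_a`, `x_max`, `saturation_x`.
#' @export
axial_profile <- function(matched, half_window_um = 1, step_um = 0.5,
                          min_count = 5, sat_tol = 0.01, drop_multi = TRUE) {
  smp <- tidyr::unnest(matched[, c("rp_id", "samples")], "samples")
  if (drop_multi) smp <- dplyr::filter(smp, .data$n_in_channel <= 1)
  smp <- dplyr::arrange(smp, .data$x_c)
  geom <- attr(matched, "geom")
  centres <- seq(floor(min(smp$x_c)), ceiling(max(smp$x_c)), by = step_um)
  lo <- findInterval(centres - half_window_um, smp$x_c) + 1L
  hi <- findInterval(centres + half_window_um, smp$x_c)
  cs <- c(0, cumsum(smp$a))
  cs2 <- c(0, cumsum(smp$a^2))
  n <- hi - lo + 1L
  mean_a <- (cs[hi + 1L] - cs[lo]) / n
  var_a <- pmax((cs2[hi + 1L] - cs2[lo]) / n - mean_a^2, 0)
  prof <- tibble::tibble(x_c = centres, mean_a = mean_a,
                         sd_a = sqrt(var_a * n / pmax(n - 1, 1)), n = n)
  prof <- dplyr::filter(prof, .data$n >= min_count)

  at <- function(x) {
    i <- which.min(abs(prof$x_c - x))
    if (length(i)) prof$mean_a[i] else NA_real_
  }
  L <- if (!is.null(geom)) geom$length_um else max(prof$x_c)
  inside <- prof$x_c >= 0 & prof$x_c <= L
  a_max <- max(prof$mean_a[inside])
  sat_x <- prof$x_c[inside][which(prof$mean_a[inside] >= (1 - sat_tol) * a_max)[1]]
  class(prof) <- c("axial_profile", class(prof))
  attr(prof, "entrance_a") <- at(0)
  attr(prof, "exit_a") <- at(L)
  attr(prof, "x_max") <- prof$x_c[inside][which.max(prof$mean_a[inside])]
  attr(prof, "saturation_x") <- sat_x
  prof
}

#' Entrance/exit amplitude relative to the pulse peak
#'
#' For each completed event, compares the blockade at the particle's
#' entrance (`x_c = 0`) and exit (`x_c = L`) with the event's peak
#' amplitude. Ratios near one half indicate that the FWHM of the pulse is a
#' good estimator of the physical transit (entrance and exit sit at the
#' half-peak level); ratios near one indicate a sharp amplitude onset.
#'
#' @param matched A `matched_events` tibble.
#' @return A tibble per event: `rp_id`, `a_entrance`, `a_exit`, `a_peak`,
#'   `entrance_ratio`, `exit_ratio`.
#' @export
fwhm_vs_entrance_check <- function(matched) {
  geom <- attr(matched, "geom")
  L <- geom$length_um
  purrr::map_dfr(seq_len(nrow(matched)), function(k) {
    s <- matched$samples[[k]]
    a_ent <- stats::approx(s$x_c, s$a, 0, rule = 2, ties = mean)$y
    a_ext <- stats::approx(s$x_c, s$a, L, rule = 2, ties = mean)$y
    inside <- s$x_c >= 0 & s$x_c <= L
    a_pk <- max(s$a[inside])
    tibble::tibble(rp_id = matched$rp_id[k], a_entrance = a_ent,
                   a_exit = a_ext, a_peak = a_pk,
                   entrance_ratio = a_ent / a_pk, exit_ratio = a_ext / a_pk)
  })
}
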