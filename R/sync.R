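#' Coarsely align two event-time sequences
#'
#' Finds the global time shift that maximises the number of matched events:
#' candidate offsets are the pairwise differences `rp_i - im_j` (evenly
#' subsampled if there are more than `max_candidates` pairs); for each
#' candidate the shifted sequences are matched greedily by nearest time
#' within `tol`, and the offset with the highest match count wins (ties go
#' to the smallest absolute offset). Events left unmatched on either side
#' are reported so they can be removed.
#'
#' @param rp_times,im_times Sorted event times (s) from the two streams.
#' @param tol Matching tolerance (s).
#' @param max_candidates Cap on the number of candidate offsets scanned.
#' @return A list with `offset` (add to `im_times` to reach the RP clock),
#'   `pairs` (tibble `rp_idx`, `im_idx`, `dt_s`), `unmatched_rp`,
#'   `unmatched_im` (integer indices).
#' @export
coarse_align <- function(rp_times, im_times, tol = 2e-3,
                         max_candidates = 1e4) {
  if (!length(rp_times) || !length(im_times)) {
    stop("both event-time lists must be non-empty", call. = FALSE)
  }
  if (is.unsorted(rp_times) || is.unsorted(im_times)) {
    stop("event times must be sorted", call. = FALSE)
  }
  cand <- as.numeric(outer(rp_times, im_times, `-`))
  if (length(cand) > max_candidates) {
    cand <- cand[round(seq(1, length(cand), length.out = max_candidates))]
  }
  # scan a tol/2 grid of the candidate offsets, then refine the winner to the
  # median residual of its matched pairs
  step <- tol / 2
  cand <- sort(unique(round(cand / step) * step))
  counts <- vapply(cand, function(off) {
    nrow(greedy_nearest_match(rp_times, im_times + off, tol))
  }, numeric(1))
  best <- max(counts)
  # a single coincidental pair is no alignment when both streams hold more
  min_support <- if (length(rp_times) > 1 && length(im_times) > 1) 2 else 1
  if (best < min_support) {
    stop("no alignment: too few matches at every candidate offset", call. = FALSE)
  }
  winners <- cand[counts == best]
  offset <- winners[which.min(abs(winners))]
  pairs <- greedy_nearest_match(rp_times, im_times + offset, tol)
  offset <- offset + stats::median(pairs$dt_s)
  pairs <- greedy_nearest_match(rp_times, im_times + offset, tol)
  list(offset = offset, pairs = pairs,
       unmatched_rp = setdiff(seq_along(rp_times), pairs$rp_idx),
       unmatched_im = setdiff(seq_along(im_times), pairs$im_idx))
}

# greedy matching by increasing |time difference|; both inputs sorted
greedy_nearest_match <- function(a, b, tol) {
  # candidate pairs: for each b, the a's bracketing it
  j <- findInterval(b, a)
  cand_i <- c(pmax(j, 1L), pmin(j + 1L, length(a)))
  cand_j <- c(seq_along(b), seq_along(b))
  d <- abs(a[cand_i] - b[cand_j])
  keep <- d <= tol
  cand_i <- cand_i[keep]; cand_j <- cand_j[keep]; d <- d[keep]
  ord <- order(d)
  used_a <- logical(length(a)); used_b <- logical(length(b))
  ri <- integer(0); ij <- integer(0); dd <- numeric(0)
  for (k in ord) {
    i <- cand_i[k]; jj <- cand_j[k]
    if (used_a[i] || used_b[jj]) next
    used_a[i] <- TRUE; used_b[jj] <- TRUE
    ri <- c(ri, i); ij <- c(ij, jj); dd <- c(dd, a[i] - b[jj])
  }
  o <- order(ri)
  tibble::tibble(rp_idx = ri[o], im_idx = ij[o], dt_s = dd[o])
}

#' Representative time of an RP event for coarse matching
#'
#' Time of the peak of the smoothed blockade — stable under noise.
#'
#' @param events Characterized RP event tibble.
#' @param trace The preprocessed trace.
#' @return Numeric vector of times (s, RP clock).
#' @export
rp_event_times <- function(events, trace) {
  vapply(seq_len(nrow(events)), function(r) {
    s <- events$samples[[r]]
    ext <- events$extrema[[r]]
    if (nrow(ext)) {
      mx <- ext[ext$type == "max", ]
      if (nrow(mx)) return(mx$time_s[which.max(mx$value)])
    }
    s$time_s[which.max(s$a)]
  }, numeric(1))
}

#' Representative time of an IM event for coarse matching
#'
#' Interpolated time at which the particle sits at the channel midpoint
#' `x_c = L/2`.
#'
#' @param events IM event tibble.
#' @param geom A [channel_geometry()].
#' @return Numeric vector of times (s, camera clock); `NA` for tracks that
#'   never reach the midpoint.
#' @export
im_event_times <- function(events, geom) {
  L2 <- geom$length_um / 2
  vapply(events$path, function(p) crossing_time(p$t_s, p$x_c, L2), numeric(1))
}

#' Per-event fine alignment offset
#'
#' Anchors the frame in which the particle sits at the exact middle of the
#' channel (interpolated time at `x_c = L/2`) to the middle-most (median
#' index) sample of the RP event's above-threshold span. The fine offset is
#' the anchor mismatch left after coarse alignment and is applied to this
#' event's frame times only — compensating the slow accumulated clock-rate
#' discrepancy between the streams without a global clock model.
#'
#' @param rp_event One-row characterized RP event.
#' @param im_event One-row IM event (must be complete).
#' @param trace The preprocessed trace.
#' @param geom A [channel_geometry()].
#' @param coarse_offset Global offset from [coarse_align()].
#' @return Fine offset (s).
#' @export
fine_align <- function(rp_event, im_event, trace, geom, coarse_offset) {
  if (!isTRUE(im_event$complete)) {
    warning("incomplete IM event: fine alignment skipped")
    return(NA_real_)
  }
  p <- im_event$path[[1]]
  anchor_im <- crossing_time(p$t_s, p$x_c, geom$length_um / 2)
  span <- rp_event$start_idx:rp_event$end_idx
  anchor_rp <- trace$time_s[span[ceiling(length(span) / 2)]]
  anchor_rp - (anchor_im + coarse_offset)
}

#' Pair every frame of a matched event with the current at that instant
#'
#' Shifts the event's frame times into the RP clock (coarse plus fine
#' offset) and linearly interpolates the filtered current at each, yielding
#' per-sample tuples of time, position and relative blockade
#' `a = (I0 - I)/I_p`.
#'
#' @param rp_event One-row characterized RP event.
#' @param im_event One-row IM event.
#' @param trace The preprocessed trace.
#' @param fine_offset Fine offset (s) from [fine_align()].
#' @param coarse_offset Coarse offset (s).
#' @return A tibble `t_s` (RP clock), `x_c`, `y_c`, `a`.
#' @export
pair_samples <- function(rp_event, im_event, trace, coarse_offset,
                         fine_offset) {
  p <- im_event$path[[1]]
  t_rp <- p$t_s + coarse_offset + fine_offset
  cur <- stats::approx(trace$time_s, trace$filtered_A, t_rp, rule = 2)$y
  tibble::tibble(t_s = t_rp, x_c = p$x_c, y_c = p$y_c,
                 a = (rp_event$i0_A - cur) / rp_event$ip_A)
}

#' Match RP and IM events and synchronize their clocks
#'
#' Full event-matching protocol: coarse alignment of the two event-time
#' sequences, per-event fine offsets anchored at the channel midpoint, and
#' per-frame sample pairing. Samples acquired while more than one particle
#' was inside the channel are counted in `n_in_channel` so analytics can
#' exclude them. When `refine_ip = TRUE` the in-pulse current `I_p` of each
#' event is re-estimated as the mean current over samples within
#' `ip_halfwidth_um` of the channel centre (the position-gated estimator)
#' and the blockades are renormalised.
#'
#' @param rp_events Characterized RP events.
#' @param im_events IM events (from [im_events()] / [detect_im_events()]).
#' @param trace The preprocessed trace.
#' @param geom A [channel_geometry()].
#' @param tol Coarse matching tolerance (s).
#' @param max_fine_offset_s Reject events whose fine offset exceeds this (s).
#' @param refine_ip Re-estimate `I_p` from position-gated samples.
#' @param ip_halfwidth_um Half-width of the centre gate for `I_p` (µm).
#' @return A `matched_events` tibble: identifiers, offsets, event summaries
#'   (`duration_s`, `y_mean_um`, amplitude columns, `extrema`) and a
#'   `samples` list-column of per-frame `(t_s, x_c, y_c, a, n_in_channel)`;
#'   attributes `coarse_offset`, `unmatched_rp`, `unmatched_im`.
#' @export
match_events <- function(rp_events, im_events, trace, geom,
                         tol = 2e-3, max_fine_offset_s = 5e-3,
                         refine_ip = TRUE, ip_halfwidth_um = 50) {
  rp_t <- rp_event_times(rp_events, trace)
  im_t <- im_event_times(im_events, geom)
  ok_im <- which(!is.na(im_t))
  al <- coarse_align(sort(rp_t), sort(im_t[ok_im]), tol = tol)
  rp_ord <- order(rp_t)
  im_ord <- ok_im[order(im_t[ok_im])]

  occupancy <- dplyr::filter(im_events, .data$complete)
  rows <- list()
  for (k in seq_len(nrow(al$pairs))) {
    ri <- rp_ord[al$pairs$rp_idx[k]]
    ii <- im_ord[al$pairs$im_idx[k]]
    rp_ev <- rp_events[ri, ]
    im_ev <- im_events[ii, ]
    if (!isTRUE(im_ev$complete)) next
    fine <- fine_align(rp_ev, im_ev, trace, geom, al$offset)
    if (is.na(fine) || abs(fine) > max_fine_offset_s) next
    smp <- pair_samples(rp_ev, im_ev, trace, al$offset, fine)
    smp$n_in_channel <- occupancy_count(im_ev$path[[1]]$t_s, occupancy)
    if (refine_ip) {
      centre <- abs(smp$x_c - geom$length_um / 2) <= ip_halfwidth_um
      if (any(centre)) {
        cur <- stats::approx(trace$time_s, trace$filtered_A,
                             smp$t_s, rule = 2)$y
        ip_new <- mean(cur[centre])
        smp$a <- (rp_ev$i0_A - cur) / ip_new
        rp_ev$peak_amplitude <- rp_ev$peak_amplitude * rp_ev$ip_A / ip_new
        rp_ev$plateau_amplitude <- (rp_ev$i0_A - ip_new) / ip_new
        rp_ev$ip_A <- ip_new
      }
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      rp_id = rp_ev$event_id, im_track = im_ev$track,
      coarse_offset_s = al$offset, fine_offset_s = fine,
      t_event_s = rp_t[ri],
      duration_s = im_ev$duration_s, y_mean_um = im_ev$y_mean_um,
      fwhm_s = rp_ev$fwhm_s,
      peak_amplitude = rp_ev$peak_amplitude,
      plateau_amplitude = rp_ev$plateau_amplitude,
      ip_A = rp_ev$ip_A, i0_A = rp_ev$i0_A,
      n_extrema = rp_ev$n_extrema,
      extrema = rp_ev$extrema,
      samples = list(smp))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  class(out) <- c("matched_events", class(out))
  attr(out, "coarse_offset") <- al$offset
  attr(out, "unmatched_rp") <- al$unmatched_rp
  attr(out, "unmatched_im") <- al$unmatched_im
  attr(out, "geom") <- geom
  out
}

# number of IM events whose in-channel span covers each time
occupancy_count <- function(times, events) {
  if (!nrow(events)) return(rep(1L, length(times)))
  counts <- integer(length(times))
  for (k in seq_len(nrow(events))) {
    counts <- counts +
      as.integer(times >= events$t_entry_s[k] & times <= events$t_exit_s[k])
  }
  pmax(counts, 1L)
}
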