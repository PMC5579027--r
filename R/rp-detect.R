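#' Filter a current trace and estimate its baseline
#'
#' Zero-phase low-pass filtering followed by a running-median baseline over
#' the detrend window. The default filter is a centred moving average with
#' an effective cutoff at `lowpass_hz` (linear phase and a monotone step
#' response, so the abrupt resistance transitions at cavity boundaries are
#' smeared but never over- or undershot); `filter_type = "butter"` selects
#' a 4th-order Butterworth run forward-backward instead. The baseline is estimated in two passes: a provisional
#' event detection masks pulse spans, the masked samples are bridged by
#' linear interpolation, and the running median is recomputed so deep pulses
#' do not drag the baseline down. The robust noise scale `sigma` is the
#' MAD-based estimate of the filtered-minus-baseline residual on event-free
#' samples.
#'
#' @param trace An `rp_trace` (tibble with `time_s`, `current_A`).
#' @param lowpass_hz Low-pass cutoff (Hz); must be below Nyquist. `NULL`
#'   skips filtering.
#' @param detrend_window_s Running-median window (s); must cover at least 10
#'   samples.
#' @param k Provisional detection threshold multiplier used when masking
#'   events for the second baseline pass.
#' @param filter_type `"ma"` (moving average, default) or `"butter"`.
#' @return The trace with added columns `filtered_A`, `baseline_A` and
#'   attributes `noise_sd_A`, `sample_period_s`.
#' @export
rp_preprocess <- function(trace, lowpass_hz = 1e4, detrend_window_s = 0.05,
                          k = 6, filter_type = c("ma", "butter")) {
  filter_type <- match.arg(filter_type)
  dt <- attr(trace, "sample_period_s")
  if (is.null(dt)) dt <- stats::median(diff(trace$time_s))
  fs <- 1 / dt
  n <- nrow(trace)
  if (detrend_window_s / dt < 10) {
    stop("`detrend_window_s` must span at least 10 samples", call. = FALSE)
  }
  filtered <- trace$current_A
  if (!is.null(lowpass_hz)) {
    if (lowpass_hz >= fs / 2) stop("`lowpass_hz` must be below Nyquist", call. = FALSE)
    if (filter_type == "butter") {
      bf <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
      filtered <- signal::filtfilt(bf, trace$current_A)
    } else {
      # centred moving average whose first spectral null sits at lowpass_hz
      filtered <- running_mean(trace$current_A,
                               max(1L, round(fs / lowpass_hz / 2)))
    }
  }

  win <- min(odd_window(detrend_window_s / dt), odd_window(n - 1))
  base1 <- stats::runmed(filtered, win, endrule = "median")
  resid <- filtered - base1
  sigma1 <- mad_sigma(resid)
  mask <- resid < -k * sigma1
  mask <- grow_mask(mask, max(50L, round(5e-4 / dt)))
  if (any(mask) && !all(mask)) {
    bridged <- filtered
    bridged[mask] <- stats::approx(which(!mask), filtered[!mask], xout = which(mask),
                                   rule = 2)$y
    baseline <- stats::runmed(bridged, win, endrule = "median")
  } else {
    baseline <- base1
  }
  resid2 <- filtered - baseline
  sigma <- if (mean(mask) < 0.8) mad_sigma(resid2[!mask]) else mad_sigma(resid2)

  out <- trace
  out$filtered_A <- filtered
  out$baseline_A <- baseline
  attr(out, "sample_period_s") <- dt
  attr(out, "noise_sd_A") <- sigma
  attr(out, "preprocessed") <- TRUE
  out
}

# centred running mean with half-width h; window shrinks at the edges
running_mean <- function(x, h) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

odd_window <- function(w) {
  w <- max(3L, as.integer(round(w)))
  if (w %% 2L == 0L) w + 1L else w
}

mad_sigma <- function(x) {
  1.4826 * stats::median(abs(x - stats::median(x)))
}

grow_mask <- function(mask, by) {
  if (by <= 0 || !any(mask)) return(mask)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- mask
  for (i in which(r$values)) {
    out[max(1, starts[i] - by):min(length(mask), ends[i] + by)] <- TRUE
  }
  out
}

#' Detect resistive-pulse events by hysteresis thresholding
#'
#' A pulse opens when the baseline-subtracted current excursion
#' `e = baseline - filtered` exceeds `k * sigma` and closes when it falls
#' back below `hysteresis * k * sigma`; two pulses whose excursion never
#' drops below the closing threshold between them are merged. Events shorter
#' than `min_duration_s` or longer than `max_duration_s` are discarded.
#' Spans are padded by `pad_s` on each side for downstream amplitude work.
#'
#' @param trace A preprocessed trace from [rp_preprocess()].
#' @param k Threshold multiplier of the robust noise scale.
#' @param hysteresis Closing threshold as a fraction of the opening one.
#' @param min_duration_s,max_duration_s Duration gates (s).
#' @param pad_s Padding added to each side of the detected span (s).
#' @return A tibble of events: `event_id`, core span `start_idx`/`end_idx`,
#'   padded span `pad_start_idx`/`pad_end_idx`, `t_start_s`, `t_end_s`,
#'   `threshold_duration_s`, with attributes `threshold_A`, `sigma_A`.
#' @export
rp_detect_events <- function(trace, k = 6, hysteresis = 0.5,
                             min_duration_s = 1e-4, max_duration_s = 0.5,
                             pad_s = 5e-4) {
  if (!isTRUE(attr(trace, "preprocessed"))) {
    stop("run `rp_preprocess()` before `rp_detect_events()`", call. = FALSE)
  }
  stopifnot(k > 0, hysteresis > 0, hysteresis <= 1)
  dt <- attr(trace, "sample_period_s")
  sigma <- attr(trace, "noise_sd_A")
  e <- trace$baseline_A - trace$filtered_A
  open_thr <- k * sigma
  close_thr <- hysteresis * open_thr

  above_close <- e > close_thr
  r <- rle(above_close)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  rows <- list()
  pad_n <- round(pad_s / dt)
  n <- nrow(trace)
  for (i in cand) {
    s <- starts[i]; en <- ends[i]
    if (!any(e[s:en] > open_thr)) next
    dur <- (en - s + 1) * dt
    if (dur < min_duration_s || dur > max_duration_s) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      start_idx = s, end_idx = en,
      pad_start_idx = max(1L, s - pad_n), pad_end_idx = min(n, en + pad_n),
      t_start_s = trace$time_s[s], t_end_s = trace$time_s[en],
      threshold_duration_s = dur)
  }
  events <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    start_idx = integer(), end_idx = integer(),
    pad_start_idx = integer(), pad_end_idx = integer(),
    t_start_s = numeric(), t_end_s = numeric(),
    threshold_duration_s = numeric())
  events <- dplyr::mutate(events, event_id = dplyr::row_number(),
                          .before = 1)
  attr(events, "threshold_A") <- open_thr
  attr(events, "sigma_A") <- sigma
  events
}

#' Characterize detected events: amplitudes, durations, extrema
#'
#' For each event the blockade is normalised as `a(t) = (I0 - I(t)) / I_p`
#' with `I0` the local baseline and `I_p` the attenuated (in-pulse) current.
#' Without synchronized position data `I_p` is estimated as the mean
#' filtered current over the pulse's top region (samples whose smoothed
#' depth is at least 90% of the peak depth), an averaging estimator that is
#' unbiased on plateau-shaped pulses; the position-gated alternative
#' (`I_p` from samples within ±50 µm of the channel centre) is applied by
#' [refine_amplitudes()] once events are synchronized. Peak amplitude is the
#' maximum of the Savitzky–Golay-smoothed blockade; `plateau_amplitude` is
#' the top-region mean; FWHM is measured between linearly interpolated
#' half-peak crossings; extrema are zero crossings of the smoothed
#' derivative pruned by persistence (pairs closer in amplitude than
#' `3 * sigma_a` are removed).
#'
#' @param events Event table from [rp_detect_events()].
#' @param trace The preprocessed trace.
#' @param smooth_window Savitzky–Golay window (samples, odd).
#' @return The event table with added columns `i0_A`, `ip_A`,
#'   `peak_amplitude`, `plateau_amplitude`, `fwhm_s`, `truncated`,
#'   `n_extrema`, and list-columns `extrema` (tibble `idx`, `time_s`,
#'   `value`, `type`) and `samples` (tibble `time_s`, `a`).
#' @export
rp_characterize <- function(events, trace, smooth_window = 15) {
  dt <- attr(trace, "sample_period_s")
  sigma <- attr(trace, "noise_sd_A")
  n <- nrow(trace)
  out <- events
  cols <- lapply(seq_len(nrow(events)), function(r) {
    i0r <- events$pad_start_idx[r]; i1r <- events$pad_end_idx[r]
    idx <- i0r:i1r
    cur <- trace$filtered_A[idx]
    i0_loc <- mean(trace$baseline_A[idx])
    win <- min(odd_window(smooth_window), odd_window(length(idx) - 2))
    smoothed <- if (length(idx) > win + 2) {
      signal::sgolayfilt(cur, p = min(3, win - 2), n = win)
    } else cur
    depth <- i0_loc - smoothed
    pk <- which.max(depth)
    # top region: within 2% of the peak depth, widened by the smoothed-noise
    # scale so the selection stays symmetric in the noise
    sigma_sm_A <- sigma * sg_noise_gain(min(3, win - 2), win)
    top <- depth >= 0.98 * depth[pk] - 3 * sigma_sm_A
    if (sum(top) < 5) top <- depth >= 0.9 * depth[pk]
    ip <- mean(cur[top])
    a_raw <- (i0_loc - cur) / ip
    a_sm <- (i0_loc - smoothed) / ip
    sigma_a <- sigma / ip

    # cap by the raw maximum: polynomial smoothing can overshoot sharp edges
    peak_amplitude <- min(a_sm[pk], max(a_raw))
    plateau_amplitude <- mean(a_raw[top])
    fwhm <- fwhm_duration(a_sm, peak_amplitude, dt)
    # extrema live on the above-threshold core span; the padded tails are
    # baseline and only contribute noise turns
    core <- (events$start_idx[r] - i0r + 1L):(events$end_idx[r] - i0r + 1L)
    prominence <- max(5 * sigma_a, 0.02 * peak_amplitude)
    sigma_sm <- sigma_a * sg_noise_gain(min(3, win - 2), win)
    ext <- find_extrema(a_sm[core], cur[core], i0_loc, prominence, sigma_sm)
    ext$idx <- ext$idx + core[1] - 1L
    ext$time_s <- trace$time_s[idx[ext$idx]]
    truncated <- (i0r == 1L) || (i1r == n)
    tibble::tibble(
      i0_A = i0_loc, ip_A = ip,
      peak_amplitude = peak_amplitude, plateau_amplitude = plateau_amplitude,
      fwhm_s = fwhm, truncated = truncated, n_extrema = nrow(ext),
      extrema = list(ext),
      samples = list(tibble::tibble(time_s = trace$time_s[idx], a = a_raw)))
  })
  dplyr::bind_cols(out, dplyr::bind_rows(cols))
}

# linear-interpolated width at half the peak amplitude
fwhm_duration <- function(a, peak, dt) {
  half <- peak / 2
  above <- a >= half
  if (!any(above)) return(NA_real_)
  i_first <- which(above)[1]
  i_last <- which(above)[sum(above)]
  t_left <- if (i_first == 1) 0 else {
    (i_first - 1) - (a[i_first] - half) / (a[i_first] - a[i_first - 1])
  }
  t_right <- if (i_last == length(a)) i_last - 1 else {
    (i_last - 1) + (a[i_last] - half) / (a[i_last] - a[i_last + 1])
  }
  (t_right - t_left) * dt
}

# white-noise gain of the central Savitzky-Golay smoothing coefficient row
sg_noise_gain <- function(p, n) {
  if (n < p + 2) return(1)
  h <- signal::sgolay(p, n)[(n + 1) / 2, ]
  sqrt(sum(h^2))
}

# extrema of the smoothed blockade with persistence pruning; each extremum
# value is the blockade averaged over its plateau: samples between the
# midpoints towards the neighbouring extrema whose smoothed value lies within
# a band around the local median level (a selection that is symmetric in the
# noise, avoiding argmax/argmin bias), normalised by the local attenuated
# current so region values equal the local dR/R0 without cross-region
# normalisation distortion
find_extrema <- function(a_sm, cur, i0_loc, prominence, sigma_sm) {
  d <- diff(a_sm)
  s <- sign(d)
  s[s == 0] <- 1
  turns <- which(diff(s) != 0) + 1L
  if (!length(turns)) {
    return(tibble::tibble(idx = integer(), value = numeric(), type = character()))
  }
  type <- ifelse(s[turns - 1L] > 0, "max", "min")
  idx <- turns
  val <- a_sm[idx]
  # persistence pruning: repeatedly drop the adjacent max/min pair with the
  # smallest amplitude difference below the prominence threshold
  repeat {
    if (length(idx) < 2) break
    gaps <- abs(diff(val))
    j <- which.min(gaps)
    if (gaps[j] >= prominence) break
    keep <- setdiff(seq_along(idx), c(j, j + 1L))
    idx <- idx[keep]; val <- val[keep]; type <- type[keep]
  }
  # drop leading/trailing extrema that are not prominent against the edges
  ok <- rep(TRUE, length(idx))
  if (length(idx)) {
    edge_ref <- c(a_sm[1], a_sm[length(a_sm)])
    for (j in seq_along(idx)) {
      neigh <- c(if (j > 1) val[j - 1] else edge_ref[1],
                 if (j < length(idx)) val[j + 1] else edge_ref[2])
      if (all(abs(val[j] - neigh) < prominence)) ok[j] <- FALSE
    }
  }
  idx <- idx[ok]; type <- type[ok]
  band <- max(prominence / 4, 3 * sigma_sm, 1e-12)
  n_s <- length(a_sm)
  value <- vapply(seq_along(idx), function(j) {
    i <- idx[j]
    interior <- j > 1 && j < length(idx)
    if (interior) {
      # interior extremum (e.g. the cavity plateau between the two narrow
      # maxima): average the central half between the flanking extrema — a
      # purely positional selection, so the estimate carries no
      # argmin/argmax noise bias
      l0 <- idx[j - 1]; r0 <- idx[j + 1]
      trim <- (r0 - l0) %/% 4L
      sel <- (l0 + trim):(r0 - trim)
    } else {
      # edge extremum: symmetric region around it, anchored on the
      # extremal-side quantile (estimated over many noise-decorrelation
      # lengths, insensitive to the slope/transition samples at the edges)
      lb <- if (j > 1) (idx[j - 1] + i) %/% 2L else 1L
      rb <- if (j < length(idx)) (idx[j + 1] + i) %/% 2L else n_s
      half <- max(min(i - lb, rb - i), 3L)
      region <- max(1L, i - half):min(n_s, i + half)
      a0 <- stats::quantile(a_sm[region], if (type[j] == "max") 0.8 else 0.2,
                            names = FALSE)
      sel <- region[abs(a_sm[region] - a0) <= band]
      if (!length(sel)) sel <- max(1L, i - 3L):min(n_s, i + 3L)
    }
    ip_loc <- mean(cur[sel])
    (i0_loc - ip_loc) / ip_loc
  }, numeric(1))
  tibble::tibble(idx = idx, value = value, type = type)
}

#' Gate events in amplitude–duration space
#'
#' Removes events outside rectangular amplitude/duration ranges and, when
#' given, outside a polygon in (duration, amplitude) space — the standard
#' cleanup that excludes small noise-born events and very-high-amplitude
#' aggregates. Counts removed per gate are recorded in the `gate_log`
#' attribute and reported as a message.
#'
#' @param events Characterized event table.
#' @param amplitude_range,duration_range Numeric `c(min, max)` or `NULL`.
#' @param polygon Data frame with columns `duration_s`, `amplitude` tracing
#'   a closed polygon; events inside are kept. `NULL` skips.
#' @param amplitude_col Column used as the event amplitude.
#' @return The gated subset (attributes `gate_log`).
#' @export
rp_gate_events <- function(events, amplitude_range = NULL,
                           duration_range = NULL, polygon = NULL,
                           amplitude_col = "peak_amplitude") {
  amp <- events[[amplitude_col]]
  dur <- events$fwhm_s
  keep <- rep(TRUE, nrow(events))
  log <- list()
  if (!is.null(amplitude_range)) {
    drop <- !(amp >= amplitude_range[1] & amp <= amplitude_range[2])
    log$amplitude <- sum(drop & keep)
    keep <- keep & !drop
  }
  if (!is.null(duration_range)) {
    drop <- !(dur >= duration_range[1] & dur <= duration_range[2])
    log$duration <- sum(drop & keep)
    keep <- keep & !drop
  }
  if (!is.null(polygon)) {
    inside <- point_in_polygon(dur, amp, polygon$duration_s, polygon$amplitude)
    log$polygon <- sum(!inside & keep)
    keep <- keep & inside
  }
  if (length(log)) {
    message("rp_gate_events: removed ",
            paste(sprintf("%s=%d", names(log), unlist(log)), collapse = ", "))
  }
  out <- events[keep, , drop = FALSE]
  attr(out, "gate_log") <- log
  out
}

# even-odd ray casting
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
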