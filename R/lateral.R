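#' Event-level amplitudes per channel region
#'
#' Summarises each matched event with its lateral position, transit
#' duration, and the amplitude relevant to a channel region: `"whole"` uses
#' the event's plateau/peak amplitude; `"narrow"` uses the mean of the two
#' blockade maxima (the particle in the narrow constrictions of a cavity
#' channel; the entrance-side maximum alone with `narrow = "entrance"`);
#' `"cavity"` uses the interior blockade minimum (the particle inside the
#' cavity). Cavity-channel regions require events with the three-extrema
#' pulse morphology.
#'
#' @param matched A `matched_events` tibble.
#' @param region `"whole"`, `"narrow"` or `"cavity"`.
#' @param narrow For `region = "narrow"`: `"mean"` of the two maxima
#'   (default, lower variance) or `"entrance"` side only.
#' @return A tibble per event: `rp_id`, `y_mean_um`, `duration_s`,
#'   `amplitude`.
#' @export
region_amplitudes <- function(matched, region = c("whole", "narrow", "cavity"),
                              narrow = c("mean", "entrance")) {
  region <- match.arg(region)
  narrow <- match.arg(narrow)
  amp <- vapply(seq_len(nrow(matched)), function(k) {
    if (region == "whole") return(matched$plateau_amplitude[k])
    ext <- matched$extrema[[k]]
    maxima <- ext[ext$type == "max", ]
    minima <- ext[ext$type == "min", ]
    if (nrow(maxima) < 2 || nrow(minima) < 1) return(NA_real_)
    # interior minimum flanked by the two largest maxima
    m2 <- maxima[order(-maxima$value), ][1:2, ]
    span <- range(m2$idx)
    interior <- minima[minima$idx > span[1] & minima$idx < span[2], ]
    if (!nrow(interior)) return(NA_real_)
    if (region == "cavity") {
      min(interior$value)
    } else if (narrow == "mean") {
      mean(m2$value)
    } else {
      m2$value[which.min(m2$idx)]
    }
  }, numeric(1))
  out <- tibble::tibble(rp_id = matched$rp_id, y_mean_um = matched$y_mean_um,
                        duration_s = matched$duration_s, amplitude = amp)
  dropped <- sum(is.na(amp))
  if (dropped) {
    message(sprintf("region_amplitudes: %d event(s) without the required pulse morphology dropped",
                    dropped))
  }
  dplyr::filter(out, !is.na(.data$amplitude))
}

#' Lateral-position statistics of duration and amplitude
#'
#' Binned profiles of transit duration and blockade amplitude versus the
#' event's mean lateral position, with a convexity diagnostic (the
#' quadratic coefficient of a degree-2 polynomial fit) for each. A positive
#' duration coefficient with minimum near the axis is the plane-Poiseuille
#' signature; the sign of the amplitude coefficient distinguishes the
#' wall-enhanced (narrow/straight) from the wall-suppressed (cavity)
#' lateral dependence.
#'
#' @param matched A `matched_events` tibble.
#' @param region Passed to [region_amplitudes()].
#' @param bin_um Lateral bin width (µm).
#' @param min_count Minimum events per bin.
#' @return A list of class `lateral_stats`: `events` (per-event table),
#'   `profile_duration`, `profile_amplitude` (binned mean ± sd),
#'   `quad_duration`, `quad_amplitude` (lm fits of value on `y + y^2`).
#' @export
lateral_stats <- function(matched, region = "whole", bin_um = 1,
                          min_count = 3) {
  ev <- region_amplitudes(matched, region)
  profile_of <- function(value) {
    tibble::tibble(y = ev$y_mean_um, v = value) |>
      dplyr::mutate(y_bin = round(.data$y / bin_um) * bin_um) |>
      dplyr::group_by(.data$y_bin) |>
      dplyr::summarise(mean = mean(.data$v), sd = stats::sd(.data$v),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::filter(.data$n >= min_count)
  }
  quad_of <- function(value) {
    stats::lm(v ~ y + I(y^2), data = data.frame(y = ev$y_mean_um, v = value))
  }
  structure(list(events = ev,
                 profile_duration = profile_of(ev$duration_s),
                 profile_amplitude = profile_of(ev$amplitude),
                 quad_duration = quad_of(ev$duration_s),
                 quad_amplitude = quad_of(ev$amplitude)),
            class = "lateral_stats")
}

#' Quadratic (convexity) coefficients of a lateral profile
#'
#' @param x A `lateral_stats` object.
#' @return A tibble with the quadratic coefficient and its standard error
#'   for the duration and amplitude profiles.
#' @export
convexity <- function(x) {
  stopifnot(inherits(x, "lateral_stats"))
  one <- function(fit, what) {
    co <- summary(fit)$coefficients
    tibble::tibble(profile = what, quad_coef = co["I(y^2)", 1],
                   se = co["I(y^2)", 2])
  }
  dplyr::bind_rows(one(x$quad_duration, "duration"),
                   one(x$quad_amplitude, "amplitude"))
}

#' Recover the off-axis coefficient from synchronized events
#'
#' Linearised fit of the off-axis amplitude model: with
#' `g = (y_norm d / D)^3` computed from each event's measured lateral
#' position (accessible-range fraction mapped onto the equivalent
#' cylinder), the model `a = a0 (1 + alpha g)` is fit by ordinary least
#' squares of `a` on `g`; `alpha` is the slope over the intercept.
#'
#' @param events Event table from [region_amplitudes()] (straight/narrow
#'   region amplitudes).
#' @param geom A [channel_geometry()].
#' @param d Particle diameter (µm).
#' @return An object of class `offaxis_fit` with `alpha`, `a0`, the `lm`
#'   fit, and `n`.
#' @export
fit_offaxis_alpha <- function(events, geom, d) {
  hw <- accessible_half_width(geom, d)
  w <- if (geom$kind == "straight") geom$width_um else geom$width_narrow_um
  D <- equivalent_diameter(w, geom$height_um)
  frac <- pmin(abs(events$y_mean_um) / hw, 1)
  g <- (frac * (D - d) / D * d / D)^3
  fit <- stats::lm(a ~ g, data = data.frame(a = events$amplitude, g = g))
  a0 <- unname(stats::coef(fit)[1])
  alpha <- unname(stats::coef(fit)[2]) / a0
  structure(list(alpha = alpha, a0 = a0, fit = fit, n = nrow(events)),
            class = "offaxis_fit")
}

#' @export
print.offaxis_fit <- function(x, ...) {
  cat(sprintf("<offaxis_fit> alpha = %.3f, a0 = %.5g (n = %d events)\n",
              x$alpha, x$a0, x$n))
  invisible(x)
}

#' Linear fit of amplitude on duration
#'
#' Ordinary least squares of event amplitude on transit duration — the
#' classic amplitude–duration correlation. A positive slope reflects the
#' off-axis enhancement (slow wall-hugging particles blockade more); a
#' negative slope in the cavity region reflects the inverted lateral
#' dependence there.
#'
#' @param events Event table from [region_amplitudes()].
#' @return An object of class `amp_duration_fit`: `slope`, `intercept`,
#'   `r` (Pearson correlation, `NA` with a `degenerate` flag when the
#'   events are identical), `n`, and the underlying `lm` fit.
#' @export
amp_duration_fit <- function(events) {
  if (nrow(events) < 10) stop("need at least 10 events", call. = FALSE)
  degenerate <- stats::sd(events$duration_s) == 0 ||
    stats::sd(events$amplitude) == 0
  if (degenerate) {
    return(structure(list(slope = 0, intercept = mean(events$amplitude),
                          r = NA_real_, n = nrow(events), fit = NULL,
                          degenerate = TRUE),
                     class = "amp_duration_fit"))
  }
  fit <- stats::lm(amplitude ~ duration_s, data = events)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(events$duration_s, events$amplitude),
                 n = nrow(events), fit = fit, degenerate = FALSE),
            class = "amp_duration_fit")
}

#' @export
print.amp_duration_fit <- function(x, ...) {
  cat(sprintf("<amp_duration_fit> slope = %.4g /s, intercept = %.4g, r = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' Per-event wide/narrow amplitude ratios in a cavity channel
#'
#' For each event with the cavity pulse morphology (two blockade maxima and
#' an interior minimum), the ratio of the blockade in the cavity to the
#' blockade in the narrow region, compared with the closed-form prediction
#' from the local-resistance model and equivalent diameters.
#'
#' @param matched A `matched_events` tibble or characterized RP event table
#'   (only the `extrema` column is needed).
#' @param geom The cavity [channel_geometry()].
#' @param d Particle diameter (µm).
#' @param narrow `"mean"` of the two maxima or `"entrance"` side only.
#' @return A `ratio_distribution` tibble with one `ratio` per event;
#'   attribute `theory` holds the predicted ratio.
#' @export
ratio_distribution <- function(matched, geom, d, narrow = c("mean", "entrance")) {
  narrow <- match.arg(narrow)
  if (geom$kind != "cavity") {
    stop("`geom` must be a cavity channel", call. = FALSE)
  }
  if (!"rp_id" %in% names(matched)) matched$rp_id <- matched$event_id
  if (!"y_mean_um" %in% names(matched)) matched$y_mean_um <- NA_real_
  if (!"duration_s" %in% names(matched)) matched$duration_s <- NA_real_
  wide <- region_amplitudes(matched, "cavity")
  nar <- region_amplitudes(matched, "narrow", narrow = narrow)
  joined <- dplyr::inner_join(wide, nar, by = "rp_id",
                              suffix = c("_wide", "_narrow"))
  if (!nrow(joined)) {
    stop("no events with cavity pulse morphology (two maxima and an interior minimum)",
         call. = FALSE)
  }
  out <- tibble::tibble(rp_id = joined$rp_id,
                        a_wide = joined$amplitude_wide,
                        a_narrow = joined$amplitude_narrow,
                        ratio = joined$amplitude_wide / joined$amplitude_narrow)
  class(out) <- c("ratio_distribution", class(out))
  attr(out, "theory") <- cavity_ratio_theory(geom, d)
  out
}
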