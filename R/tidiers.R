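#' Tidy an amplitude–duration fit
#'
#' @param x An `amp_duration_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.amp_duration_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    return(tibble::tibble(term = c("(Intercept)", "duration_s"),
                          estimate = c(x$intercept, x$slope),
                          std.error = NA_real_, statistic = NA_real_,
                          p.value = NA_real_))
  }
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
                 statistic = co[, 3], p.value = co[, 4])
}

#' @rdname tidy.amp_duration_fit
#' @export
glance.amp_duration_fit <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = if (is.na(x$r)) NA_real_ else x$r^2,
                 n = x$n, degenerate = isTRUE(x$degenerate))
}

#' Tidy an off-axis coefficient fit
#'
#' @param x An `offaxis_fit`.
#' @param ... Unused.
#' @return A tibble with the recovered coefficient and baseline amplitude.
#' @export
tidy.offaxis_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  # delta-method standard error for alpha = slope / intercept
  se_alpha <- abs(x$alpha) * sqrt((co[2, 2] / co[2, 1])^2 +
                                    (co[1, 2] / co[1, 1])^2)
  tibble::tibble(term = c("a0", "alpha"),
                 estimate = c(x$a0, x$alpha),
                 std.error = c(co[1, 2], se_alpha))
}

#' @rdname tidy.offaxis_fit
#' @export
glance.offaxis_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(alpha = x$alpha, a0 = x$a0, r.squared = s$r.squared,
                 sigma = s$sigma, n = x$n)
}
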