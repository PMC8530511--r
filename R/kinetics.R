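# Growth kinetics: linear volume-vs-time slopes over stated windows, fold
# changes, and slope ratios.

#' Fit a linear growth slope over a time window
#'
#' Ordinary least squares of volume (or any metric) against time for the
#' frames falling inside the closed window `[t_start, t_end]` — frames
#' exactly at a boundary belong to the window. Plain linear trend, no
#' weighting.
#'
#' @param times Frame times (hpf).
#' @param volumes Metric values, same length (µm³ for volumes).
#' @param window Length-2 `c(t_start, t_end)`; defaults to the full range.
#' @return An object of class `growth_fit` with `slope` (units/hr),
#'   `intercept`, `r_squared`, `window` and `n_frames`; supports
#'   [coef()], [predict()], `print()` and `plot()`.
#' @export
fit_growth_slope <- function(times, volumes, window = range(times)) {
  stopifnot(length(times) == length(volumes))
  window <- sort(as.numeric(window))
  if (window[1] >= window[2])
    stop("window must satisfy t_start < t_end", call. = FALSE)
  keep <- times >= window[1] & times <= window[2] &
    is.finite(times) & is.finite(volumes)
  if (sum(keep) < 2)
    stop("fewer than 2 frames inside the window", call. = FALSE)
  t_w <- times[keep]; v_w <- volumes[keep]
  fit <- lm(v_w ~ t_w)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((v_w - mean(v_w))^2)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    window = window, n_frames = sum(keep),
    times = t_w, values = v_w,
    fitted = unname(fit$fitted.values)), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> slope %.4g per hr over [%g, %g] hpf (%d frames, R² = %.3f)\n",
              x$slope, x$window[1], x$window[2], x$n_frames, x$r_squared))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.growth_fit <- function(object, times = object$times, ...) {
  object$intercept + object$slope * times
}

#' @export
plot.growth_fit <- function(x, xlab = "time (hpf)", ylab = "volume (µm³)",
                            ...) {
  graphics::plot(x$times, x$values, xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Fold change of a metric series
#'
#' Last value divided by the first; e.g. a surface series doubling over the
#' recording gives 2, and a thickness series 24 -> 8 µm gives 1/3 (a
#' flattening fold of 3).
#'
#' @param series Numeric vector; the first value must be strictly positive.
#' @return `series[last] / series[first]`.
#' @export
fold_change <- function(series) {
  series <- series[is.finite(series)]
  if (length(series) < 1 || series[1] <= 0)
    stop("fold change needs a positive first value", call. = FALSE)
  series[length(series)] / series[1]
}

#' Ratio of two growth slopes
#'
#' @param fit_a,fit_b [fit_growth_slope()] results (or bare slopes).
#' @return `slope_a / slope_b`.
#' @export
slope_ratio <- function(fit_a, fit_b) {
  sa <- if (inherits(fit_a, "growth_fit")) fit_a$slope else as.numeric(fit_a)
  sb <- if (inherits(fit_b, "growth_fit")) fit_b$slope else as.numeric(fit_b)
  if (sb == 0) stop("slope ratio undefined for zero denominator",
                    call. = FALSE)
  sa / sb
}
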