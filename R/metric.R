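#' Paired-slice ROI signal container
#'
#' Holds the per-measurement ROI signals of the two adjacent target slices.
#' The first `n_discard` measurements (default 5, the protocol's dummy
#' scans) are dropped before any downstream computation.
#'
#' @param s_lower,s_upper Numeric vectors of equal length: ROI signal of the
#'   lower slice (i-1) and upper slice (i) per measurement, in acquisition
#'   order.
#' @param n_discard Number of initial measurements to exclude.
#' @return Object of class `slice_signals` with the retained series and
#'   1-based original measurement numbers.
#' @export
slice_signals <- function(s_lower, s_upper, n_discard = 5) {
  if (length(s_lower) != length(s_upper))
    stop_csf("`s_lower` and `s_upper` must have equal length.", "csfpulse_input_error")
  n_total <- length(s_lower)
  if (n_discard < 0 || n_discard >= n_total)
    stop_csf("`n_discard` must be in [0, n_total).", "csfpulse_input_error")
  keep <- seq.int(n_discard + 1, n_total)
  bad <- keep[!is.finite(s_lower[keep]) | s_lower[keep] <= 0 |
                !is.finite(s_upper[keep]) | s_upper[keep] <= 0]
  if (length(bad))
    stop_csf(
      sprintf("Non-positive or non-finite ROI signal at measurement(s) %s.",
              paste(head(bad, 5), collapse = ", ")),
      "csfpulse_data_error", measurements = bad
    )
  structure(
    list(s_lower = s_lower[keep], s_upper = s_upper[keep],
         measurement = keep, n_total = n_total, n_discard = n_discard),
    class = "slice_signals"
  )
}

#' Per-measurement pulsed CSF volume (CSFpulse series)
#'
#' Applies the pulsed-volume estimator to paired-slice ROI signals:
#'
#' `raw(n) = (1/alpha - 1) * (S_i(n) / S_{i-1}(n) - 1) * ROIvolume`
#'
#' where `alpha` is the saturation ratio from [calibrate_alpha()] and
#' `ROIvolume` the ROI volume in mm^3. Measurements with `raw < 0`
#' (descending or out-of-range flow) are clamped to 0 in the `clamped`
#' series; summaries are computed by [glance()] / [summarize_series()].
#'
#' @param signals A [slice_signals()].
#' @param alpha An [calibrate_alpha()] result (or a bare number in (0,1)).
#' @param roi_volume_mm3 ROI volume scale, mm^3 (`> 0`).
#' @return Object of class `pulse_series`: tibble accessor via [tidy()],
#'   summaries via [glance()].
#' @examples
#' sig <- slice_signals(rep(100, 10), c(rep(100, 5), rep(110, 5)), n_discard = 0)
#' ps <- compute_csfpulse_series(sig, 0.5, roi_volume_mm3 = 30.25)
#' glance(ps)
#' @export
compute_csfpulse_series <- function(signals, alpha, roi_volume_mm3) {
  stopifnot(inherits(signals, "slice_signals"))
  a <- if (inherits(alpha, "alpha_calibration")) alpha$alpha else alpha
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a == 0)
    stop_csf("`alpha` must be a single non-zero number.", "csfpulse_input_error")
  if (abs(a - 1) < 1e-12)
    stop_csf("alpha = 1 makes the pulsed-volume estimator undefined.",
             "csfpulse_calibration_error")
  if (!is.numeric(roi_volume_mm3) || roi_volume_mm3 <= 0)
    stop_csf("`roi_volume_mm3` must be positive.", "csfpulse_input_error")
  raw <- (1 / a - 1) * (signals$s_upper / signals$s_lower - 1) * roi_volume_mm3
  structure(
    list(measurement = signals$measurement, raw = raw, clamped = pmax(raw, 0),
         alpha = a, roi_volume_mm3 = roi_volume_mm3,
         n_total = signals$n_total, n_discard = signals$n_discard),
    class = "pulse_series"
  )
}

#' @export
print.pulse_series <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pulse_series> %d retained measurements (of %d; first %d discarded)\n",
              length(x$raw), x$n_total, x$n_discard))
  cat(sprintf("  mean CSFpulse %.3f, |z| mean %s, positive ratio %.3f\n",
              g$mean_pulse,
              if (is.na(g$abs_z_mean)) "NA" else sprintf("%.3f", g$abs_z_mean),
              g$positive_ratio))
  invisible(x)
}

#' @method tidy pulse_series
#' @export
tidy.pulse_series <- function(x, ...) {
  tibble(measurement = x$measurement, raw = x$raw, clamped = x$clamped)
}

#' Summarize a CSFpulse series
#'
#' Per-subject summaries of the dynamic series:
#' * `mean_pulse`: mean of the clamped series (pulsation strength);
#' * `abs_z_mean`: mean absolute within-subject z-score of the clamped series
#'   (pulsation variability), sample-SD denominator; `NA` with a warning when
#'   the series has zero variance;
#' * `positive_ratio`: fraction of retained measurements with raw value
#'   strictly above 0 (in-range ascending pulsation frequency).
#'
#' @param series A `pulse_series`.
#' @return One-row tibble with `n_measurements`, `mean_pulse`, `abs_z_mean`,
#'   `positive_ratio`.
#' @export
summarize_series <- function(series) {
  stopifnot(inherits(series, "pulse_series"))
  x <- series$clamped
  if (length(x) < 2)
    stop_csf("At least 2 retained measurements are required.", "csfpulse_input_error")
  s <- sd(x)
  if (s == 0) {
    rlang::warn("Zero-variance CSFpulse series: abs_z_mean is undefined (NA).")
    abs_z <- NA_real_
  } else {
    abs_z <- mean(abs((x - mean(x)) / s))
  }
  tibble(
    n_measurements = length(x),
    mean_pulse = mean(x),
    abs_z_mean = abs_z,
    positive_ratio = mean(series$raw > 0)
  )
}

#' @method glance pulse_series
#' @export
glance.pulse_series <- function(x, ...) summarize_series(x)

#' @method autoplot pulse_series
#' @export
autoplot.pulse_series <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$measurement, y = .data$clamped)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = function(d) d[d$raw <= 0, ],
                        colour = "grey60", size = 0.8) +
    ggplot2::labs(x = "measurement", y = "CSFpulse (a.u.)",
                  title = "Dynamic interslice pulsed CSF volume") +
    ggplot2::theme_minimal()
}

#' Temporal high-pass filter for drift removal
#'
#' Removes slow drift below `cutoff_hz` by regressing the series on a
#' discrete-cosine drift basis (all cosines with frequency below the cutoff)
#' plus an intercept, and returning the residual with the fitted intercept
#' re-added, so the absolute signal scale -- on which the paired-slice ratio
#' depends -- is preserved. This is the standard fMRI drift model; the cutoff
#' default used by the pipeline is 0.01 Hz.
#'
#' @param x Numeric series (one value per measurement).
#' @param cutoff_hz High-pass cutoff frequency, Hz; must be below Nyquist
#'   (`1 / (2 * tr_ms / 1000)`).
#' @param tr_ms Sampling interval (volume TR), ms.
#' @return Filtered series, same length and mean-scale as `x`.
#' @export
temporal_highpass <- function(x, cutoff_hz, tr_ms) {
  n <- length(x)
  if (n < 3) stop_csf("Series too short to filter.", "csfpulse_input_error")
  nyquist <- 1 / (2 * tr_ms / 1000)
  if (cutoff_hz >= nyquist)
    stop_csf(
      sprintf("Cutoff %.4g Hz is not below the Nyquist frequency %.4g Hz.",
              cutoff_hz, nyquist),
      "csfpulse_input_error"
    )
  if (cutoff_hz <= 0) return(x)
  # DCT-II drift basis: component k has frequency k / (2 * n * dt)
  dt_s <- tr_ms / 1000
  k_max <- floor(2 * n * dt_s * cutoff_hz)
  if (k_max < 1) return(x)
  t_idx <- seq_len(n) - 0.5
  basis <- vapply(seq_len(k_max),
                  function(k) cos(pi * k * t_idx / n),
                  numeric(n))
  fit <- lm.fit(cbind(1, basis), x)
  drift <- basis %*% fit$coefficients[-1]
  as.numeric(x - drift)
}
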