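#' CSF tissue parameters for the longitudinal Bloch model
#'
#' @param t1_ms Longitudinal relaxation time in milliseconds. Default 4300 ms,
#'   the literature-standard T1 of CSF at 3 T.
#' @param m0 Equilibrium magnetization (arbitrary units).
#' @return Object of class `tissue_params`.
#' @export
tissue_params <- function(t1_ms = 4300, m0 = 1) {
  if (t1_ms <= 0) stop_csf("`t1_ms` must be positive.", "csfpulse_input_error")
  if (m0 <= 0) stop_csf("`m0` must be positive.", "csfpulse_input_error")
  structure(list(t1_ms = t1_ms, m0 = m0), class = "tissue_params")
}

#' Steady-state longitudinal signal under periodic 90 degree excitation
#'
#' With ideal saturation (90 degree pulse, perfect spoiling) the longitudinal
#' magnetization recovered `interval_ms` after the previous excitation is
#' `m0 * (1 - exp(-interval_ms / t1_ms))`, which is also the periodic steady
#' state when the spin is excited every `interval_ms`.
#'
#' @param tissue A [tissue_params()].
#' @param interval_ms Recovery interval in ms (vectorized, `>= 0`).
#' @return Signal in the same arbitrary units as `m0`.
#' @export
steady_state_signal <- function(tissue, interval_ms) {
  stopifnot(inherits(tissue, "tissue_params"))
  if (any(interval_ms < 0))
    stop_csf("`interval_ms` must be non-negative.", "csfpulse_input_error")
  tissue$m0 * (1 - exp(-interval_ms / tissue$t1_ms))
}

# slab bounds along the slice axis, mm; slice s occupies [(s-1)*d, s*d)
slab_bounds <- function(protocol, slice_idx) {
  d <- protocol$slice_thickness_mm
  c((slice_idx - 1) * d, slice_idx * d)
}

#' Matrix-driven Bloch simulation of a moving spin column
#'
#' Propagates a 1-D column of spin packets along the slice axis through the
#' full interleaved excitation schedule. Each slice's 90 degree pulse
#' saturates (`mz = 0`) the packets inside its slab at its slot time;
#' longitudinal relaxation toward `m0` is applied between events as the exact
#' exponential operator; packets are advected at constant `velocity_mm_s`
#' (positive = ascending, toward higher slice index) with fully relaxed
#' packets entering at the upstream boundary. Per-slice signals are the slab
#' mean of `mz` sampled just before each slice's excitation in the final
#' cycle.
#'
#' The packet spacing is adjusted so that the displacement per TR is an
#' integer number of packets (a commensurate grid); the sampled slab means are
#' then exactly periodic once every in-stack packet has been excited at least
#' once, and the cycle-to-cycle convergence check is meaningful at tight
#' tolerance.
#'
#' @param protocol An [acq_protocol()] (flip angle must be 90).
#' @param tissue A [tissue_params()].
#' @param velocity_mm_s Signed through-plane velocity, mm/s.
#' @param n_cycles Maximum number of TR cycles to simulate (`>= 1`).
#' @param dz_mm Nominal packet spacing, mm.
#' @param margin_slices Upstream/downstream grid margin, in slices.
#' @param tol Convergence tolerance: max absolute change of any per-slice
#'   signal between the last two cycles.
#' @return Object of class `bloch_schedule`: list with `signals` (tibble:
#'   `slice`, `slot`, `time_ms`, `signal`), `cycles_run`, `converged`,
#'   `max_change`, and the simulation parameters.
#' @export
simulate_schedule <- function(protocol, tissue, velocity_mm_s = 0,
                              n_cycles = 20, dz_mm = 0.1,
                              margin_slices = 2, tol = 1e-8) {
  stopifnot(inherits(protocol, "acq_protocol"), inherits(tissue, "tissue_params"))
  if (n_cycles < 1) stop_csf("`n_cycles` must be >= 1.", "csfpulse_input_error")
  if (!isTRUE(all.equal(protocol$flip_deg, 90)))
    stop_csf("The saturation model requires a 90 degree flip angle.",
             "csfpulse_config_error")

  n <- protocol$n_slices
  d <- protocol$slice_thickness_mm
  tr <- protocol$tr_ms
  t1 <- tissue$t1_ms
  m0 <- tissue$m0
  v <- velocity_mm_s / 1000 # mm per ms

  # commensurate grid: displacement per TR = integer number of packets
  disp_tr <- abs(v) * tr
  dz <- if (disp_tr >= dz_mm / 2) disp_tr / round(disp_tr / dz_mm) else dz_mm

  t_total <- n_cycles * tr
  lo <- -margin_slices * d - max(v, 0) * t_total
  hi <- n * d + margin_slices * d - min(v, 0) * t_total
  z0 <- seq(lo + dz / 2, hi, by = dz) # packet centers at t = 0
  mz <- rep(m0, length(z0))

  ord <- slice_order(protocol)
  slot_ms <- tr / n
  ev_time <- (seq_len(n) - 1) * slot_ms # within-cycle event times, by slot

  sig_prev <- rep(NA_real_, n)
  sig <- numeric(n)
  max_change <- Inf
  t_prev <- 0
  cycles_run <- 0L
  for (cyc in seq_len(n_cycles)) {
    for (k in seq_len(n)) {
      t_now <- (cyc - 1) * tr + ev_time[k]
      dt <- t_now - t_prev
      if (dt > 0) mz <- m0 + (mz - m0) * exp(-dt / t1)
      s <- ord[k]
      z <- z0 + v * t_now
      in_slab <- z >= (s - 1) * d & z < s * d
      sig[s] <- mean(mz[in_slab])
      mz[in_slab] <- 0
      t_prev <- t_now
    }
    cycles_run <- cyc
    if (!anyNA(sig_prev)) {
      max_change <- max(abs(sig - sig_prev))
      if (max_change <= tol) break
    }
    sig_prev <- sig
    sig <- numeric(n)
  }
  converged <- is.finite(max_change) && max_change <= tol
  if (!converged)
    stop_csf(
      sprintf(paste0("Schedule simulation did not reach a periodic steady state: ",
                     "max per-slice change %.3e after %d cycles (tol %.1e). ",
                     "Increase `n_cycles` or loosen `tol`."),
              max_change, cycles_run, tol),
      "csfpulse_convergence_error",
      max_change = max_change, cycles_run = cycles_run
    )

  signals <- tibble(
    slice = seq_len(n),
    slot = acquisition_slot(protocol, seq_len(n)),
    time_ms = ev_time[acquisition_slot(protocol, seq_len(n))],
    signal = sig
  )
  structure(
    list(signals = signals, cycles_run = cycles_run, converged = converged,
         max_change = max_change, velocity_mm_s = velocity_mm_s,
         dz_mm = dz, protocol = protocol, tissue = tissue),
    class = "bloch_schedule"
  )
}

#' @export
print.bloch_schedule <- function(x, ...) {
  cat(sprintf("<bloch_schedule> v = %g mm/s, %d cycles, max change %.2e\n",
              x$velocity_mm_s, x$cycles_run, x$max_change))
  print(x$signals, n = 5)
  invisible(x)
}

#' @method tidy bloch_schedule
#' @export
tidy.bloch_schedule <- function(x, ...) x$signals

#' Calibrate the saturation ratio alpha for a slice pair
#'
#' `alpha` is the ratio of the pulsating CSF signal (spins whose last
#' excitation was the adjacent slice's pulse, one interTR before readout) to
#' the non-pulsated steady-state CSF signal (static spins excited one TR
#' before readout). Two routes are provided:
#'
#' * `"closed_form"` (default):
#'   `alpha = (1 - exp(-interTR/T1)) / (1 - exp(-TR/T1))`.
#' * `"schedule_simulation"`: ratio of [simulate_schedule()] upper-slice
#'   signals for a fully exchanged voxel (velocity = one slice thickness per
#'   interTR, so every spin in the upper slab was saturated by the lower
#'   slab's pulse) versus a static voxel.
#'
#' @inheritParams simulate_schedule
#' @param pair A `slice_pair` from [interslice_interval()].
#' @param method `"closed_form"` or `"schedule_simulation"`.
#' @param tol Degeneracy guard: error if `|alpha - 1| <= tol`.
#' @return Object of class `alpha_calibration` with fields `alpha`,
#'   `inter_tr_ms`, `tr_ms`, `t1_ms`, `flip_deg`, `method`.
#' @examples
#' p <- acq_protocol()
#' calibrate_alpha(p, tissue_params(), interslice_interval(p, 8))$alpha # 0.194
#' @export
calibrate_alpha <- function(protocol, tissue, pair,
                            method = c("closed_form", "schedule_simulation"),
                            tol = 1e-6) {
  stopifnot(inherits(protocol, "acq_protocol"), inherits(tissue, "tissue_params"))
  method <- match.arg(method)
  inter_tr <- pair$inter_tr_ms
  if (is.null(inter_tr) || !is.finite(inter_tr) || inter_tr <= 0)
    stop_csf("`pair` must carry a computed positive `inter_tr_ms`.",
             "csfpulse_input_error")
  if (method == "closed_form") {
    alpha <- steady_state_signal(tissue, inter_tr) /
      steady_state_signal(tissue, protocol$tr_ms)
  } else {
    v_full <- protocol$slice_thickness_mm / inter_tr * 1000 # mm/s
    moving <- simulate_schedule(protocol, tissue, velocity_mm_s = v_full)
    static <- simulate_schedule(protocol, tissue, velocity_mm_s = 0)
    up <- pair$upper_slice
    alpha <- moving$signals$signal[up] / static$signals$signal[up]
  }
  if (abs(alpha - 1) <= tol)
    stop_csf(
      "Degenerate calibration: alpha = 1 (interTR equals the effective TR); the pulsed-volume estimator is undefined.",
      "csfpulse_calibration_error"
    )
  structure(
    list(alpha = alpha, inter_tr_ms = inter_tr, tr_ms = protocol$tr_ms,
         t1_ms = tissue$t1_ms, flip_deg = protocol$flip_deg, method = method),
    class = "alpha_calibration"
  )
}

#' @export
print.alpha_calibration <- function(x, ...) {
  cat(sprintf("<alpha_calibration> alpha = %.4f (%s; interTR %g ms, TR %g ms, T1 %g ms)\n",
              x$alpha, x$method, x$inter_tr_ms, x$tr_ms, x$t1_ms))
  invisible(x)
}

#' @method tidy alpha_calibration
#' @export
tidy.alpha_calibration <- function(x, ...) {
  tibble(alpha = x$alpha, inter_tr_ms = x$inter_tr_ms, tr_ms = x$tr_ms,
         t1_ms = x$t1_ms, flip_deg = x$flip_deg, method = x$method)
}

# internal: exchanged-fraction forward model shared by the phantom generator,
# the response curve and (through the pulsed-volume estimator) the metric.
#
# An ascending velocity v exchanges the fraction
#   f = clip(v * interTR / thickness, -1, 1)
# of the upper slab per measurement, and the upper-slice signal becomes
#   S_upper = S_static * (1 + f * alpha / (1 - alpha)),
# i.e. the exchanged compartment carries the effective signal
# S_static / (1 - alpha). This convention makes the pulsed-volume estimator
# exact: applying the pulsed-volume estimator to these signals returns
# f * ROIvolume for every f in [-1, 1]. See the methods vignette for why the
# effective-signal convention (rather than the raw schedule-simulation
# signal) is used.
exchanged_fraction <- function(velocity_mm_s, inter_tr_ms, slice_thickness_mm) {
  f <- velocity_mm_s * (inter_tr_ms / 1000) / slice_thickness_mm
  pmin(pmax(f, -1), 1)
}

pair_signal_ratio <- function(f, alpha) 1 + f * alpha / (1 - alpha)

#' Simulated pulsed-volume response versus velocity
#'
#' Forward-simulates the target pair's signals under the exchanged-fraction
#' flow model for each velocity and applies the pulsed-volume estimator
#' (see [compute_csfpulse_series()]). The raw response is positive for ascending
#' velocities inside the capture range, clips once the whole slab is
#' exchanged per interTR, and is negative for descending flow.
#'
#' @inheritParams calibrate_alpha
#' @param velocities Numeric vector of through-plane velocities, mm/s.
#' @param roi_volume_mm3 ROI volume used to scale the pulsed volume
#'   (default 1: response per unit ROI volume).
#' @param alpha Optional precomputed [calibrate_alpha()]; computed closed-form
#'   if missing.
#' @return Tibble of class `pulse_response`: `velocity_mm_s`,
#'   `exchanged_fraction`, `s_lower`, `s_upper`, `csfpulse`.
#' @export
pulse_response_curve <- function(protocol, tissue, pair, velocities,
                                 roi_volume_mm3 = 1, alpha = NULL) {
  if (any(!is.finite(velocities)))
    stop_csf("`velocities` must be finite.", "csfpulse_input_error")
  if (is.null(alpha)) alpha <- calibrate_alpha(protocol, tissue, pair)
  s_static <- steady_state_signal(tissue, protocol$tr_ms)
  f <- exchanged_fraction(velocities, pair$inter_tr_ms, protocol$slice_thickness_mm)
  s_lower <- rep(s_static, length(f))
  s_upper <- s_static * pair_signal_ratio(f, alpha$alpha)
  raw <- (1 / alpha$alpha - 1) * (s_upper / s_lower - 1) * roi_volume_mm3
  out <- tibble(
    velocity_mm_s = velocities,
    exchanged_fraction = f,
    s_lower = s_lower,
    s_upper = s_upper,
    csfpulse = raw
  )
  class(out) <- c("pulse_response", class(out))
  out
}

#' @method autoplot pulse_response
#' @export
autoplot.pulse_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$velocity_mm_s, y = .data$csfpulse)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "through-plane velocity (mm/s)",
                  y = "simulated CSFpulse (a.u.)",
                  title = "Pulsed-volume response of the target slice pair") +
    ggplot2::theme_minimal()
}
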