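#' Define an EPI acquisition protocol
#'
#' Bundles the timing and geometry parameters of a 2D multislice EPI
#' acquisition. Defaults reproduce the study protocol: TR/TE/flip =
#' 2000 ms / 30 ms / 90 deg, 2.75 x 2.75 mm in-plane, 4 mm slices,
#' 31 slices, 160 measurements, Philips interleaved ascending ordering.
#'
#' @param tr_ms Repetition time (volume TR) in milliseconds.
#' @param te_ms Echo time in milliseconds (carried for provenance; the
#'   longitudinal signal model does not use it).
#' @param flip_deg Excitation flip angle in degrees. The Bloch layer models
#'   ideal 90 degree saturation pulses; other angles are rejected there.
#' @param n_slices Number of slices (positive integer).
#' @param slice_thickness_mm Slice thickness in mm.
#' @param inplane_res_mm In-plane voxel edge in mm (length 1 or 2).
#' @param n_measurements Number of dynamics (volumes).
#' @param slice_scheme Slice ordering scheme. Only
#'   `"philips_interleaved_ascending"` is supported: slices are excited
#'   starting at 1 and advancing by `1 + floor(sqrt(n_slices))`, wrapping to
#'   the next start slice.
#'
#' @return An object of class `acq_protocol` (a named list).
#' @examples
#' p <- acq_protocol()
#' slice_order(p)[1:11]
#' @export
acq_protocol <- function(tr_ms = 2000, te_ms = 30, flip_deg = 90,
                         n_slices = 31, slice_thickness_mm = 4,
                         inplane_res_mm = c(2.75, 2.75),
                         n_measurements = 160,
                         slice_scheme = "philips_interleaved_ascending") {
  if (!is.numeric(tr_ms) || length(tr_ms) != 1 || tr_ms <= 0)
    stop_csf("`tr_ms` must be a single positive number.", "csfpulse_input_error")
  if (!is.numeric(n_slices) || length(n_slices) != 1 || n_slices < 1 ||
      n_slices != round(n_slices))
    stop_csf("`n_slices` must be a positive integer.", "csfpulse_input_error")
  if (slice_thickness_mm <= 0)
    stop_csf("`slice_thickness_mm` must be positive.", "csfpulse_input_error")
  if (n_measurements < 1 || n_measurements != round(n_measurements))
    stop_csf("`n_measurements` must be a positive integer.", "csfpulse_input_error")
  if (length(inplane_res_mm) == 1) inplane_res_mm <- rep(inplane_res_mm, 2)
  if (any(inplane_res_mm <= 0))
    stop_csf("`inplane_res_mm` must be positive.", "csfpulse_input_error")
  structure(
    list(tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg,
         n_slices = as.integer(n_slices),
         slice_thickness_mm = slice_thickness_mm,
         inplane_res_mm = inplane_res_mm,
         n_measurements = as.integer(n_measurements),
         slice_scheme = slice_scheme),
    class = "acq_protocol"
  )
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat("<acq_protocol>\n")
  cat(sprintf("  TR/TE/flip: %g ms / %g ms / %g deg\n", x$tr_ms, x$te_ms, x$flip_deg))
  cat(sprintf("  geometry:   %g x %g mm in-plane, %g mm x %d slices\n",
              x$inplane_res_mm[1], x$inplane_res_mm[2],
              x$slice_thickness_mm, x$n_slices))
  cat(sprintf("  dynamics:   %d measurements, scheme '%s'\n",
              x$n_measurements, x$slice_scheme))
  invisible(x)
}

#' Slice excitation order of an interleaved multislice protocol
#'
#' For the Philips interleaved ascending scheme the interleave step is
#' `1 + floor(sqrt(n_slices))`: acquisition starts at slice 1 and advances by
#' the step, wrapping to start slice 2, 3, ... once the top of the stack is
#' exceeded. For 31 slices (step 6) the order begins
#' 1, 7, 13, 19, 25, 31, 2, 8, 14, 20, 26, ...
#'
#' @param protocol An [acq_protocol()].
#' @return Integer vector: anatomical slice indices in acquisition order
#'   (a permutation of `1:n_slices`).
#' @export
slice_order <- function(protocol) {
  stopifnot(inherits(protocol, "acq_protocol"))
  n <- protocol$n_slices
  if (!identical(protocol$slice_scheme, "philips_interleaved_ascending"))
    stop_csf(
      sprintf("Unsupported slice scheme '%s'.", protocol$slice_scheme),
      "csfpulse_config_error"
    )
  step <- 1L + floor(sqrt(n))
  as.integer(unlist(lapply(seq_len(min(step, n)), function(s) seq(s, n, by = step))))
}

#' Slice timing table
#'
#' One row per anatomical slice with its acquisition slot and excitation time
#' offset within a TR. Slots are uniform: `tr_ms / n_slices`, no dead time.
#'
#' @inheritParams slice_order
#' @return A tibble with columns `slice`, `slot`, `time_ms`.
#' @export
slice_timing <- function(protocol) {
  ord <- slice_order(protocol)
  slot_ms <- protocol$tr_ms / protocol$n_slices
  tibble(slice = ord, slot = seq_along(ord),
         time_ms = (seq_along(ord) - 1) * slot_ms) |>
    dplyr::arrange(.data$slice)
}

#' Acquisition slot of a slice
#'
#' Inverse lookup of [slice_order()]: the 1-based position at which an
#' anatomical slice is excited within one TR.
#'
#' @inheritParams slice_order
#' @param slice_idx 1-based anatomical slice index.
#' @return Integer slot position.
#' @export
acquisition_slot <- function(protocol, slice_idx) {
  n <- protocol$n_slices
  if (any(slice_idx < 1 | slice_idx > n | slice_idx != round(slice_idx)))
    stop_csf(
      sprintf("`slice_idx` must be an integer in 1..%d.", n),
      "csfpulse_input_error"
    )
  match(as.integer(slice_idx), slice_order(protocol))
}

#' RF interval between an adjacent slice pair
#'
#' Computes the forward distance, in acquisition slots, from the excitation of
#' `lower_slice` to the next excitation of `lower_slice + 1`, wrapping across
#' the TR boundary when the upper slice's slot precedes the lower's. The
#' interval (interTR) is `slot_gap * tr_ms / n_slices`, truncated to integer
#' milliseconds; truncation (not rounding) reproduces the protocol's printed
#' values (5 slots x 2000/31 = 322.58 -> 322 ms).
#'
#' @inheritParams slice_order
#' @param lower_slice 1-based anatomical index of the lower slice of the pair
#'   (`1 <= lower_slice < n_slices`).
#' @return An object of class `slice_pair`: a one-row tibble with columns
#'   `lower_slice`, `upper_slice`, `slot_gap`, `inter_tr_ms`, `v_max_cm_s`.
#' @examples
#' interslice_interval(acq_protocol(), 8)$inter_tr_ms  # 322
#' interslice_interval(acq_protocol(), 6)$inter_tr_ms  # 387 (wraps across TR)
#' @export
interslice_interval <- function(protocol, lower_slice) {
  n <- protocol$n_slices
  if (length(lower_slice) != 1 || lower_slice < 1 || lower_slice != round(lower_slice))
    stop_csf("`lower_slice` must be a single positive integer.", "csfpulse_input_error")
  if (lower_slice >= n)
    stop_csf(
      sprintf("`lower_slice` = %d has no adjacent upper slice in a %d-slice protocol.",
              lower_slice, n),
      "csfpulse_input_error"
    )
  slot_lo <- acquisition_slot(protocol, lower_slice)
  slot_hi <- acquisition_slot(protocol, lower_slice + 1)
  gap <- (slot_hi - slot_lo) %% n
  inter_tr <- trunc_decimal(gap * protocol$tr_ms / n, 0)
  pair <- tibble(
    lower_slice = as.integer(lower_slice),
    upper_slice = as.integer(lower_slice + 1),
    slot_gap = as.integer(gap),
    inter_tr_ms = inter_tr,
    v_max_cm_s = capture_velocity_bound(inter_tr, protocol$slice_thickness_mm)
  )
  class(pair) <- c("slice_pair", class(pair))
  pair
}

#' Captured CSF velocity bound for a slice pair
#'
#' Ascending CSF flow is registered by the interslice saturation effect while
#' spins travel at most the two-slice span (2 x slice thickness) during one
#' interTR, so the captured range is 0 to
#' `2 * thickness / interTR`, reported in cm/s truncated to two decimals
#' (8 mm / 322 ms -> 2.48 cm/s).
#'
#' @param inter_tr_ms RF interval between the pair's excitations, ms.
#' @param slice_thickness_mm Slice thickness, mm.
#' @return Upper velocity bound in cm/s (lower bound is 0).
#' @export
capture_velocity_bound <- function(inter_tr_ms, slice_thickness_mm) {
  if (any(inter_tr_ms <= 0))
    stop_csf("`inter_tr_ms` must be positive.", "csfpulse_input_error")
  v_mm_per_ms <- 2 * slice_thickness_mm / inter_tr_ms # = m/s
  trunc_decimal(v_mm_per_ms * 100, 2)                 # cm/s, 2 decimals
}

#' Slice-pair table for a whole protocol
#'
#' Convenience wrapper: [interslice_interval()] for every admissible lower
#' slice, as one tibble.
#'
#' @inheritParams slice_order
#' @param lower_slices Which lower slices to tabulate (default: all).
#' @return Tibble, one row per pair.
#' @export
slice_pairs <- function(protocol, lower_slices = seq_len(protocol$n_slices - 1)) {
  purrr::map_dfr(lower_slices, function(l) interslice_interval(protocol, l))
}
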