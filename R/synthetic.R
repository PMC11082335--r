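#' Programmable pulsatile velocity waveform
#'
#' Velocity of ventricular CSF along the slice axis as a function of scan
#' time. Positive velocities are ascending (toward higher slice index).
#' Kinds:
#' * `"constant"`: `v(t) = v0`;
#' * `"sinusoid"`: `v(t) = v0 + amplitude * sin(2*pi*freq_hz*t + phase)` --
#'   a cardiac-like oscillation; the default 1 Hz is deliberately aliased by
#'   the 2 s volume TR, as in real resting-state sampling;
#' * `"sinusoid_plus_jitter"`: sinusoid plus white Gaussian velocity jitter
#'   of SD `jitter_sd` (drawn once per evaluation grid from the phantom
#'   seed).
#'
#' @param kind Waveform family.
#' @param v0 Baseline velocity, mm/s.
#' @param amplitude Oscillation amplitude, mm/s.
#' @param freq_hz Oscillation frequency, Hz.
#' @param phase Phase offset, radians.
#' @param jitter_sd Velocity jitter SD, mm/s (jitter kind only).
#' @return Object of class `velocity_waveform`.
#' @export
velocity_waveform <- function(kind = c("constant", "sinusoid", "sinusoid_plus_jitter"),
                              v0 = 0, amplitude = 0, freq_hz = 1, phase = 0,
                              jitter_sd = 0) {
  kind <- match.arg(kind)
  vals <- c(v0, amplitude, freq_hz, phase, jitter_sd)
  if (any(!is.finite(vals)))
    stop_csf("Waveform parameters must be finite.", "csfpulse_input_error")
  structure(list(kind = kind, v0 = v0, amplitude = amplitude,
                 freq_hz = freq_hz, phase = phase, jitter_sd = jitter_sd),
            class = "velocity_waveform")
}

# evaluate the deterministic part of a waveform at times t (seconds)
eval_waveform <- function(wf, t_s) {
  base <- switch(wf$kind,
    constant = rep(wf$v0, length(t_s)),
    sinusoid = ,
    sinusoid_plus_jitter =
      wf$v0 + wf$amplitude * sin(2 * pi * wf$freq_hz * t_s + wf$phase)
  )
  if (wf$kind == "sinusoid_plus_jitter" && wf$jitter_sd > 0)
    base <- base + rnorm(length(t_s), 0, wf$jitter_sd)
  base
}

#' Specification of a synthetic 4D EPI phantom
#'
#' Describes a 4D EPI series containing a bright tubular ventricle
#' compartment whose paired-slice signals follow the interslice
#' flow-saturation forward model under a programmable pulsatile velocity.
#' Defaults emulate the study protocol (80 x 80 x 31 voxels, 160
#' measurements); tests and examples use smaller grids.
#'
#' @param protocol An [acq_protocol()].
#' @param lower_slice Lower anatomical slice of the target pair; slices at or
#'   below it inside the ventricle stay at the static steady-state signal
#'   (the pair's reference), higher ventricle slices are modulated by the
#'   flow model.
#' @param center In-plane center `c(x, y)` of the ventricle tube, voxels.
#' @param radius_vox Tube radius in voxels (`>= 1`).
#' @param slice_span `c(lo, hi)`: anatomical slices covered by the ventricle;
#'   must contain the target pair.
#' @param tissue A [tissue_params()].
#' @param background_level Tissue intensity relative to the static CSF
#'   steady-state intensity.
#' @param waveform A [velocity_waveform()].
#' @param noise_sd Additive Gaussian noise SD relative to the static CSF
#'   steady-state intensity.
#' @param drift Peak-to-peak linear intensity drift over the scan, as a
#'   fraction of the static CSF intensity (exercises the high-pass stage).
#' @param seed RNG seed for the noise (and jitter) draws.
#' @param csf_intensity Intensity assigned to static CSF (arbitrary units).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(protocol = acq_protocol(), lower_slice = 8,
                         center = NULL, radius_vox = 2,
                         slice_span = NULL, tissue = tissue_params(),
                         background_level = 0.3,
                         waveform = velocity_waveform("sinusoid", v0 = 2,
                                                      amplitude = 2),
                         noise_sd = 0, drift = 0, seed = 1,
                         csf_intensity = 1000, nx = 80, ny = 80) {
  if (is.null(center)) center <- c(ceiling(nx / 2), ceiling(ny / 2))
  if (is.null(slice_span))
    slice_span <- c(max(1, lower_slice - 2),
                    min(protocol$n_slices, lower_slice + 3))
  if (radius_vox < 1)
    stop_csf("`radius_vox` must be >= 1 voxel.", "csfpulse_input_error")
  if (noise_sd < 0)
    stop_csf("`noise_sd` must be >= 0.", "csfpulse_input_error")
  if (lower_slice < slice_span[1] || lower_slice + 1 > slice_span[2])
    stop_csf("The target slice pair must lie inside `slice_span`.",
             "csfpulse_spec_error")
  if (lower_slice >= protocol$n_slices)
    stop_csf("`lower_slice` has no adjacent upper slice.", "csfpulse_spec_error")
  structure(
    list(protocol = protocol, lower_slice = as.integer(lower_slice),
         center = center, radius_vox = radius_vox,
         slice_span = as.integer(slice_span), tissue = tissue,
         background_level = background_level, waveform = waveform,
         noise_sd = noise_sd, drift = drift, seed = seed,
         csf_intensity = csf_intensity, nx = as.integer(nx), ny = as.integer(ny)),
    class = "phantom_spec"
  )
}

# in-plane disc mask of the ventricle tube
disc_mask <- function(nx, ny, center, radius) {
  dx <- outer(seq_len(nx) - center[1], rep(1, ny))
  dy <- outer(rep(1, nx), seq_len(ny) - center[2])
  dx^2 + dy^2 <= radius^2
}

#' Generate a synthetic 4D EPI phantom with known pulsation
#'
#' Builds the 4D intensity array and the per-measurement ground truth. The
#' ventricle signal follows the exchanged-fraction forward model: at each
#' measurement the waveform velocity, evaluated at the slice's excitation
#' instant, exchanges the fraction `f = clip(v * interTR / thickness, -1, 1)`
#' of each ventricle slice above the target lower slice, scaling that slice's
#' signal by `1 + f * alpha / (1 - alpha)` relative to the slice below
#' (alpha from the pair's [calibrate_alpha()] closed form). Ventricle slices
#' at or below the target lower slice stay at the static steady-state
#' signal, so the target pair's lower member is the non-pulsated reference
#' and the pulsed-volume estimator recovers `f * ROIvolume` exactly in the
#' noise-free limit.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `csf_phantom`: list with `image` (4D array
#'   x,y,slice,measurement), `truth` (tibble: `measurement`, `time_s`,
#'   `velocity_mm_s`, `exchanged_fraction`, `pulsed_volume_mm3`,
#'   `pulsed_volume_clamped_mm3`), `n_roi_voxels`, `roi_volume_mm3`,
#'   `s_static`, and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  p <- spec$protocol
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  nx <- spec$nx; ny <- spec$ny
  nz <- p$n_slices; nt <- p$n_measurements
  s_static <- steady_state_signal(spec$tissue, p$tr_ms)
  csf0 <- spec$csf_intensity
  bg <- spec$background_level * csf0

  disc <- disc_mask(nx, ny, spec$center, spec$radius_vox)
  n_roi <- sum(disc)
  vv <- voxel_volume(p)

  # per-slice modulation of ventricle slices above the target lower slice,
  # cumulative so every adjacent pair above it is exactly invertible
  span <- spec$slice_span[1]:spec$slice_span[2]
  mod_slices <- span[span > spec$lower_slice]
  slot_ms <- p$tr_ms / nz
  ratio <- matrix(1, nrow = nz, ncol = nt) # slice x measurement intensity ratio
  truth_f <- NULL; truth_v <- NULL; truth_t <- NULL
  for (s in mod_slices) {
    pair <- interslice_interval(p, s - 1)
    alpha <- calibrate_alpha(p, spec$tissue, pair)$alpha
    t_exc <- ((seq_len(nt) - 1) * p$tr_ms +
                (acquisition_slot(p, s) - 1) * slot_ms) / 1000
    v <- eval_waveform(spec$waveform, t_exc)
    f <- exchanged_fraction(v, pair$inter_tr_ms, p$slice_thickness_mm)
    ratio[s, ] <- ratio[s - 1, ] * pair_signal_ratio(f, alpha)
    if (s == spec$lower_slice + 1) {
      truth_f <- f; truth_v <- v; truth_t <- t_exc
    }
  }

  img <- array(bg, dim = c(nx, ny, nz, nt))
  for (s in span) {
    slab <- matrix(bg, nx, ny)
    for (n in seq_len(nt)) {
      slab[disc] <- csf0 * ratio[s, n]
      img[, , s, n] <- slab
    }
  }
  if (spec$drift != 0) {
    ramp <- spec$drift * csf0 * ((seq_len(nt) - 1) / max(1, nt - 1) - 0.5)
    img <- img + rep(ramp, each = nx * ny * nz)
  }
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd * csf0), dim = dim(img))

  roi_vol <- n_roi * vv
  truth <- tibble(
    measurement = seq_len(nt),
    time_s = truth_t,
    velocity_mm_s = truth_v,
    exchanged_fraction = truth_f,
    pulsed_volume_mm3 = truth_f * roi_vol,
    pulsed_volume_clamped_mm3 = pmax(truth_f * roi_vol, 0)
  )
  structure(
    list(image = img, truth = truth, n_roi_voxels = n_roi,
         roi_volume_mm3 = roi_vol, s_static = s_static,
         csf_static_intensity = csf0, spec = spec),
    class = "csf_phantom"
  )
}

#' @export
print.csf_phantom <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<csf_phantom> %d x %d x %d voxels, %d measurements\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  ventricle: %d voxels/slice (%.2f mm^3), target pair %d-%d\n",
              x$n_roi_voxels, x$roi_volume_mm3,
              x$spec$lower_slice, x$spec$lower_slice + 1))
  invisible(x)
}

#' Default bounding box of a phantom's ventricle
#'
#' The tube's in-plane extent padded by `pad` voxels, clipped to the image.
#'
#' @param phantom A `csf_phantom`.
#' @param pad Padding in voxels.
#' @return Integer `c(x0, y0, x1, y1)`.
#' @export
phantom_bbox <- function(phantom, pad = 4) {
  s <- phantom$spec
  c(max(1, s$center[1] - s$radius_vox - pad),
    max(1, s$center[2] - s$radius_vox - pad),
    min(s$nx, s$center[1] + s$radius_vox + pad),
    min(s$ny, s$center[2] + s$radius_vox + pad))
}

#' Write a phantom to NIfTI with its ground truth
#'
#' @param phantom A `csf_phantom`.
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param truth_path Optional TSV path for the ground-truth table.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path, truth_path = NULL) {
  p <- phantom$spec$protocol
  img <- RNifti::asNifti(phantom$image,
                         pixdim = c(p$inplane_res_mm, p$slice_thickness_mm,
                                    p$tr_ms / 1000))
  RNifti::writeNifti(img, path)
  if (!is.null(truth_path))
    utils::write.table(phantom$truth, truth_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort specification mirroring the study's demographic tables
#'
#' One row per group with sample size, demographic distributions and the
#' group-level pulsation targets. Defaults reproduce the published cohort:
#' HC n = 17, PDD-L n = 16, PDD-H n = 19, with the printed age / gender /
#' education / MMSE / duration / UPDRS distributions and the group mean
#' CSFpulse values (6.6 / 11.9 / 15.6 a.u.; printed dispersions are standard
#' errors and are converted to between-subject SDs via `se * sqrt(n)`).
#'
#' @param groups Optional replacement tibble with the same columns.
#' @return Tibble of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = NULL) {
  if (is.null(groups)) {
    groups <- tibble(
      group = c("HC", "PDD-L", "PDD-H"),
      n = c(17L, 16L, 19L),
      age_mean = c(72.3, 69.2, 75.3), age_sd = c(7.4, 9.3, 7.7),
      n_male = c(10L, 11L, 13L),
      edu_mean = c(10.1, 8.3, 7.9), edu_sd = c(3.4, 5.4, 5.5),
      mmse_mean = c(NA, 26.1, 21.7), mmse_sd = c(NA, 4.0, 4.0),
      duration_mean = c(NA, 11.8, 20.7), duration_sd = c(NA, 8.5, 16.1),
      updrs_mean = c(NA, 29.4, 26.5), updrs_sd = c(NA, 6.5, 8.1),
      pulse_mean = c(6.6, 11.9, 15.6), pulse_se = c(0.86, 2.2, 2.6),
      absz_mean = c(0.83, 0.83, 0.81), absz_se = c(0.036, 0.044, 0.037),
      roi_mean = c(6.2, 10.1, 9.4), roi_sd = c(3.9, 4.3, 3.7)
    )
  }
  needed <- c("group", "n", "age_mean", "age_sd", "n_male", "pulse_mean",
              "pulse_se", "roi_mean", "roi_sd")
  if (!all(needed %in% names(groups)))
    stop_csf(sprintf("Cohort spec needs columns: %s.",
                     paste(needed, collapse = ", ")),
             "csfpulse_input_error")
  if (any(groups$n <= 0))
    stop_csf("Group sizes must be positive.", "csfpulse_input_error")
  sds <- unlist(groups[grep("_sd$|_se$", names(groups))])
  if (any(sds < 0, na.rm = TRUE))
    stop_csf("Dispersions must be >= 0.", "csfpulse_input_error")
  class(groups) <- c("cohort_spec", class(groups))
  groups
}

#' Generate a synthetic cohort (demographics plus pulsation)
#'
#' Draws per-subject demographics from the group models of a
#' [cohort_spec()] (normal draws for continuous variables; gender assigned
#' to match the group's printed male/female counts exactly) and per-subject
#' pulsation according to `mode`:
#'
#' * `"signal"`: per-subject derived measures (`mean_pulse`, `abs_z_mean`,
#'   `positive_ratio`, `n_voxels`) are drawn directly from the group-level
#'   models -- fast, used for statistical calibration at scale;
#' * `"image"`: each subject additionally receives a phantom 4D image whose
#'   constant ascending velocity is obtained by inverting the pulse response
#'   curve at the subject's target mean pulsation; images are written under
#'   `dir`.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed.
#' @param mode `"signal"` or `"image"`.
#' @param protocol Acquisition protocol (image mode).
#' @param lower_slice Target pair lower slice (image mode).
#' @param dir Output directory for image-mode NIfTI files (required then).
#' @param nx,ny In-plane matrix of image-mode phantoms.
#' @param radius_vox Ventricle radius of image-mode phantoms.
#' @param noise_sd Image-mode noise level (relative to CSF intensity).
#' @return Tibble of class `cohort_manifest`, one row per subject.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1,
                            mode = c("signal", "image"),
                            protocol = acq_protocol(), lower_slice = 8,
                            dir = NULL, nx = 32, ny = 32, radius_vox = 2,
                            noise_sd = 0.02) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  draw_group <- function(g) {
    n <- g$n
    gender <- sample(rep(c("M", "F"), c(g$n_male, n - g$n_male)))
    tibble(
      group = g$group,
      age = round(rnorm(n, g$age_mean, g$age_sd), 1),
      gender = gender,
      education = round(pmax(0, rnorm(n, g$edu_mean, g$edu_sd)), 1),
      mmse = if (is.na(g$mmse_mean)) NA_real_ else
        round(pmin(30, pmax(0, rnorm(n, g$mmse_mean, g$mmse_sd)))),
      duration = if (is.na(g$duration_mean)) NA_real_ else
        round(pmax(0, rnorm(n, g$duration_mean, g$duration_sd)), 1),
      updrs = if (is.na(g$updrs_mean)) NA_real_ else
        round(pmax(0, rnorm(n, g$updrs_mean, g$updrs_sd))),
      target_pulse = pmax(0, rnorm(n, g$pulse_mean, g$pulse_se * sqrt(n))),
      target_absz = pmax(0, rnorm(n, g$absz_mean, g$absz_se * sqrt(n))),
      target_n_voxels = pmax(3, round(rnorm(n, g$roi_mean, g$roi_sd)))
    )
  }
  subjects <- purrr::map_dfr(seq_len(nrow(spec)), function(i) draw_group(spec[i, ]))
  subjects <- dplyr::mutate(
    subjects,
    subject_id = sprintf("sub-%03d", dplyr::row_number()),
    .before = 1
  )

  if (mode == "signal") {
    out <- dplyr::mutate(
      subjects,
      image_path = NA_character_,
      lower_slice = as.integer(lower_slice),
      mean_pulse = .data$target_pulse,
      abs_z_mean = .data$target_absz,
      positive_ratio = pmin(1, pmax(0, rnorm(dplyr::n(), 0.55, 0.1))),
      n_voxels = as.integer(.data$target_n_voxels)
    )
  } else {
    if (is.null(dir))
      stop_csf("Image mode requires an output `dir`.", "csfpulse_input_error")
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pair <- interslice_interval(protocol, lower_slice)
    n_roi <- sum(disc_mask(nx, ny, c(ceiling(nx / 2), ceiling(ny / 2)), radius_vox))
    roi_vol <- n_roi * voxel_volume(protocol)
    paths <- character(nrow(subjects))
    bboxes <- character(nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      f_target <- subjects$target_pulse[i] / roi_vol
      if (f_target > 1)
        stop_csf(
          sprintf("Target pulsation %.2f mm^3 exceeds the response-curve maximum %.2f mm^3 (full slab exchange).",
                  subjects$target_pulse[i], roi_vol),
          "csfpulse_spec_error"
        )
      v0 <- f_target * protocol$slice_thickness_mm / (pair$inter_tr_ms / 1000)
      ph <- generate_phantom(phantom_spec(
        protocol = protocol, lower_slice = lower_slice,
        radius_vox = radius_vox, nx = nx, ny = ny,
        waveform = velocity_waveform("constant", v0 = v0),
        noise_sd = noise_sd, seed = seed * 1000L + i
      ))
      paths[i] <- file.path(dir, paste0(subjects$subject_id[i], ".nii.gz"))
      write_phantom(ph, paths[i])
      bboxes[i] <- paste(phantom_bbox(ph), collapse = ",")
    }
    out <- dplyr::mutate(
      subjects,
      image_path = paths,
      lower_slice = as.integer(lower_slice),
      bbox = bboxes,
      true_mean_pulse = .data$target_pulse
    )
  }
  out <- dplyr::select(out, -dplyr::starts_with("target_"))
  class(out) <- c("cohort_manifest", class(out))
  if (!is.null(dir) ) {
    utils::write.table(out, file.path(dir, "manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  out
}
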