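#' Read and validate a subject manifest
#'
#' A manifest is a TSV with one row per subject and at least the columns
#' `subject_id`, `image_path`, `group`, `lower_slice`, `bbox` (a string
#' `"x0,y0,x1,y1"`), plus any demographic columns. Validation reports every
#' offending row.
#'
#' @param path Path to the manifest TSV (or a data frame already in memory).
#' @param protocol An [acq_protocol()] used to bound `lower_slice`.
#' @return Validated manifest tibble.
#' @export
read_manifest <- function(path, protocol = acq_protocol()) {
  man <- if (is.data.frame(path)) as_tibble(path)
  else as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  required <- c("subject_id", "image_path", "group", "lower_slice", "bbox")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols))
    stop_csf(sprintf("Manifest is missing column(s): %s.",
                     paste(missing_cols, collapse = ", ")),
             "csfpulse_manifest_error")
  if (nrow(man) == 0)
    stop_csf("Manifest is empty.", "csfpulse_manifest_error")
  dup <- man$subject_id[duplicated(man$subject_id)]
  if (length(dup))
    stop_csf(sprintf("Duplicate subject_id(s): %s.",
                     paste(unique(dup), collapse = ", ")),
             "csfpulse_manifest_error")
  bad_slice <- which(!is.finite(man$lower_slice) | man$lower_slice < 1 |
                       man$lower_slice >= protocol$n_slices)
  if (length(bad_slice))
    stop_csf(
      sprintf("`lower_slice` out of range 1..%d (no adjacent upper slice) on row(s): %s.",
              protocol$n_slices - 1, paste(bad_slice, collapse = ", ")),
      "csfpulse_manifest_error"
    )
  bad_bbox <- which(vapply(man$bbox, function(b)
    inherits(try(parse_bbox(b), silent = TRUE), "try-error"), logical(1)))
  if (length(bad_bbox))
    stop_csf(sprintf("Unparseable bbox on row(s): %s.",
                     paste(bad_bbox, collapse = ", ")),
             "csfpulse_manifest_error")
  man
}

#' Parse a bounding-box string
#'
#' @param x String `"x0,y0,x1,y1"` (1-based, inclusive) or a numeric vector.
#' @return Integer vector of length 4.
#' @export
parse_bbox <- function(x) {
  v <- if (is.character(x)) suppressWarnings(as.integer(strsplit(x, ",")[[1]]))
  else as.integer(x)
  if (length(v) != 4 || any(is.na(v)) || v[1] > v[3] || v[2] > v[4] || any(v < 1))
    stop_csf(sprintf("Invalid bbox '%s': expected x0,y0,x1,y1.",
                     paste(x, collapse = ",")),
             "csfpulse_input_error")
  v
}

#' Compute per-subject CSF pulsation from a 4D image
#'
#' Runs the per-subject stages in order: load the image, discard the first
#' `n_discard` measurements, segment the CSF ROI on both target slices from
#' the temporal-mean images, extract per-measurement ROI-mean signals
#' (optionally high-pass filtered), calibrate alpha for the pair, compute the
#' pulsed-volume series and summarize it.
#'
#' @param image 4D array (x, y, slice, measurement) or a NIfTI file path.
#' @param protocol An [acq_protocol()].
#' @param lower_slice Lower anatomical slice of the target pair.
#' @param bbox Bounding box `c(x0, y0, x1, y1)` or `"x0,y0,x1,y1"`.
#' @param tissue A [tissue_params()].
#' @param n_discard Initial measurements to exclude (default 5).
#' @param threshold_policy,percentile,threshold_value ROI thresholding, see
#'   [segment_csf_roi()].
#' @param roi_volume_mode `"total"` (ROI voxel count x voxel volume, the
#'   default) or `"per_voxel"` (a single voxel's volume) as the `ROIvolume`
#'   factor of the estimator.
#' @param highpass_hz Optional temporal high-pass cutoff in Hz applied to the
#'   ROI signals before the estimator (e.g. 0.01); `NULL` to skip.
#' @param alpha Optional precomputed [calibrate_alpha()] result.
#' @return List of class `subject_result`: `summary` (one-row tibble),
#'   `series` (`pulse_series`), `roi_lower`, `roi_upper`, `alpha`, `pair`.
#' @export
compute_subject <- function(image, protocol, lower_slice, bbox,
                            tissue = tissue_params(), n_discard = 5,
                            threshold_policy = "otsu", percentile = 90,
                            threshold_value = NULL,
                            roi_volume_mode = c("total", "per_voxel"),
                            highpass_hz = NULL, alpha = NULL) {
  roi_volume_mode <- match.arg(roi_volume_mode)
  if (is.character(image)) image <- as.array(RNifti::readNifti(image))
  if (length(dim(image)) != 4)
    stop_csf("`image` must be a 4D array (x, y, slice, measurement).",
             "csfpulse_input_error")
  if (dim(image)[3] != protocol$n_slices)
    stop_csf(sprintf("Image has %d slices but the protocol declares %d.",
                     dim(image)[3], protocol$n_slices),
             "csfpulse_input_error")
  bbox <- parse_bbox(bbox)
  pair <- interslice_interval(protocol, lower_slice)
  nt <- dim(image)[4]
  if (n_discard >= nt)
    stop_csf("`n_discard` leaves no retained measurements.", "csfpulse_input_error")
  keep <- seq.int(n_discard + 1, nt)
  vv <- voxel_volume(protocol)

  seg <- function(slice_idx) {
    mean_img <- apply(image[, , slice_idx, keep, drop = FALSE], c(1, 2), mean)
    segment_csf_roi(mean_img, bbox, slice_idx = slice_idx,
                    policy = threshold_policy, percentile = percentile,
                    value = threshold_value, voxel_volume_mm3 = vv)
  }
  roi_lower <- seg(pair$lower_slice)
  roi_upper <- seg(pair$upper_slice)

  roi_mean_series <- function(slice_idx, mask) {
    vapply(seq_len(nt), function(n) mean(image[, , slice_idx, n][mask]),
           numeric(1))
  }
  s_lower <- roi_mean_series(pair$lower_slice, roi_lower$mask)
  s_upper <- roi_mean_series(pair$upper_slice, roi_upper$mask)
  if (!is.null(highpass_hz)) {
    s_lower <- temporal_highpass(s_lower, highpass_hz, protocol$tr_ms)
    s_upper <- temporal_highpass(s_upper, highpass_hz, protocol$tr_ms)
  }
  signals <- slice_signals(s_lower, s_upper, n_discard = n_discard)
  if (is.null(alpha)) alpha <- calibrate_alpha(protocol, tissue, pair)
  roi_volume <- if (roi_volume_mode == "total") roi_upper$roi_volume_mm3 else vv
  series <- compute_csfpulse_series(signals, alpha, roi_volume)
  g <- glance(series)
  summary <- tibble(
    lower_slice = pair$lower_slice, upper_slice = pair$upper_slice,
    inter_tr_ms = pair$inter_tr_ms, v_max_cm_s = pair$v_max_cm_s,
    alpha = alpha$alpha,
    n_voxels = roi_upper$n_voxels, roi_volume_mm3 = roi_volume
  ) |> dplyr::bind_cols(g)
  structure(
    list(summary = summary, series = series, roi_lower = roi_lower,
         roi_upper = roi_upper, alpha = alpha, pair = pair),
    class = "subject_result"
  )
}

#' Run the full per-subject pipeline over a manifest
#'
#' Applies [compute_subject()] to every manifest row. Stage errors are
#' caught per subject; the pipeline continues and reports failures in the
#' `problems` attribute of the result (and as a warning).
#'
#' @param manifest A manifest tibble or TSV path (see [read_manifest()]).
#' @param protocol An [acq_protocol()].
#' @param tissue A [tissue_params()].
#' @param ... Further options passed to [compute_subject()].
#' @return Tibble of class `csf_results`, one row per successful subject,
#'   carrying subject id, group, demographics and derived measures;
#'   attribute `problems` is a tibble of per-subject failures, and
#'   `provenance` records the options used.
#' @export
run_pipeline <- function(manifest, protocol = acq_protocol(),
                         tissue = tissue_params(), ...) {
  man <- read_manifest(manifest, protocol)
  demo_cols <- intersect(c("group", "age", "gender", "education", "mmse",
                           "duration", "updrs", "true_mean_pulse"),
                         names(man))
  rows <- vector("list", nrow(man))
  problems <- list()
  for (i in seq_len(nrow(man))) {
    res <- tryCatch(
      compute_subject(man$image_path[i], protocol, man$lower_slice[i],
                      man$bbox[i], tissue = tissue, ...),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      problems[[length(problems) + 1]] <-
        tibble(subject_id = man$subject_id[i], error = conditionMessage(res))
    } else {
      rows[[i]] <- dplyr::bind_cols(
        tibble(subject_id = man$subject_id[i]),
        man[i, demo_cols],
        res$summary
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  problems <- dplyr::bind_rows(problems)
  if (nrow(problems))
    rlang::warn(sprintf("%d subject(s) failed; see attr(result, 'problems').",
                        nrow(problems)))
  attr(out, "problems") <- problems
  attr(out, "provenance") <- list(
    package = "csfpulse",
    version = as.character(utils::packageVersion("csfpulse")),
    protocol = unclass(protocol), tissue = unclass(tissue),
    options = list(...)
  )
  class(out) <- c("csf_results", class(out))
  out
}

#' Write a results table to TSV
#'
#' @param results A `csf_results` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @method autoplot csf_results
#' @export
autoplot.csf_results <- function(object, measure = "mean_pulse", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data[[measure]],
                               fill = .data$group)) +
    ggplot2::stat_summary(fun = mean, geom = "col", width = 0.6, alpha = 0.8) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                          width = 0.2) +
    ggplot2::geom_jitter(width = 0.1, size = 1, alpha = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
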