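#' Volume of a single voxel
#'
#' @param protocol An [acq_protocol()].
#' @return Voxel volume in mm^3 (in-plane x * in-plane y * slice thickness).
#' @examples
#' voxel_volume(acq_protocol()) # 2.75 * 2.75 * 4 = 30.25
#' @export
voxel_volume <- function(protocol) {
  stopifnot(inherits(protocol, "acq_protocol"))
  protocol$inplane_res_mm[1] * protocol$inplane_res_mm[2] *
    protocol$slice_thickness_mm
}

#' Segment the ventricular CSF ROI on one slice by intensity thresholding
#'
#' CSF in the fourth ventricle is markedly brighter than surrounding tissue
#' on T2*-weighted EPI, so the ROI is mapped automatically inside a
#' user-supplied bounding box: voxels whose temporal-mean intensity reaches
#' the threshold are selected. Threshold policies:
#'
#' * `"otsu"` (default): Otsu's between-class variance criterion on the
#'   in-box intensity histogram -- recovers the bright CSF compartment
#'   exactly whenever its intensity is well separated from background,
#'   independent of how much of the bounding box it fills;
#' * `"percentile"`: the `percentile`-th percentile (default 90) of the
#'   in-box intensities (selects about the top `100 - percentile` percent of
#'   box voxels by count);
#' * `"fixed"`: an absolute intensity `value` (inclusive).
#'
#' @param mean_slice_image Numeric matrix: temporal-mean intensity of one
#'   slice (mean over retained measurements).
#' @param bbox Integer vector `c(x0, y0, x1, y1)` (1-based, inclusive) in
#'   voxel coordinates; must lie within the image.
#' @param slice_idx 1-based anatomical slice index (carried in the result).
#' @param policy Threshold policy, see above.
#' @param percentile Percentile (0-100) for the `"percentile"` policy.
#' @param value Absolute threshold for the `"fixed"` policy.
#' @param voxel_volume_mm3 Volume of one voxel, mm^3.
#' @return Object of class `csf_roi`: logical `mask` (same dimension as the
#'   image), `n_voxels`, `voxel_volume_mm3`, `roi_volume_mm3`, `threshold`,
#'   `bbox`, `slice_idx`.
#' @export
segment_csf_roi <- function(mean_slice_image, bbox, slice_idx = NA_integer_,
                            policy = c("otsu", "percentile", "fixed"),
                            percentile = 90, value = NULL,
                            voxel_volume_mm3 = 1) {
  policy <- match.arg(policy)
  if (!is.matrix(mean_slice_image))
    stop_csf("`mean_slice_image` must be a matrix.", "csfpulse_input_error")
  bbox <- as.integer(bbox)
  if (length(bbox) != 4 || any(is.na(bbox)))
    stop_csf("`bbox` must be c(x0, y0, x1, y1).", "csfpulse_input_error")
  if (bbox[1] > bbox[3] || bbox[2] > bbox[4] ||
      bbox[1] < 1 || bbox[2] < 1 ||
      bbox[3] > nrow(mean_slice_image) || bbox[4] > ncol(mean_slice_image))
    stop_csf("`bbox` must be ordered and lie within the image bounds.",
             "csfpulse_input_error")
  xs <- bbox[1]:bbox[3]
  ys <- bbox[2]:bbox[4]
  box <- mean_slice_image[xs, ys, drop = FALSE]
  th <- switch(policy,
    percentile = as.numeric(quantile(box, percentile / 100, names = FALSE)),
    fixed = {
      if (is.null(value))
        stop_csf("Policy 'fixed' requires `value`.", "csfpulse_input_error")
      value
    },
    otsu = otsu_threshold(box)
  )
  mask <- matrix(FALSE, nrow(mean_slice_image), ncol(mean_slice_image))
  # data-derived thresholds (percentile, otsu) are exclusive so that a flat
  # background plateau sitting exactly at the threshold is never selected;
  # a user-supplied fixed threshold is inclusive
  mask[xs, ys] <- if (policy == "fixed") box >= th else box > th
  n_vox <- sum(mask)
  if (n_vox < 1)
    stop_csf(
      "Empty CSF mask: no in-box voxel reaches the threshold. Revise the bounding box or the threshold policy.",
      "csfpulse_segmentation_error"
    )
  structure(
    list(mask = mask, n_voxels = n_vox, voxel_volume_mm3 = voxel_volume_mm3,
         roi_volume_mm3 = n_vox * voxel_volume_mm3, threshold = th,
         bbox = bbox, slice_idx = as.integer(slice_idx), policy = policy),
    class = "csf_roi"
  )
}

# Otsu's threshold on a 256-bin histogram, refined by isodata iteration
# (threshold -> midpoint of the two class means, to convergence). The
# refinement keeps the threshold mid-gap between the background and CSF
# clusters, so upper-tail background voxels are not swept into the bright
# class when the classes are very unbalanced.
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = 257)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[256]
  between <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  th <- mids[which.max(between)]
  for (i in 1:100) {
    lo <- x[x <= th]; hi <- x[x > th]
    if (!length(lo) || !length(hi)) break
    th_new <- (mean(lo) + mean(hi)) / 2
    if (abs(th_new - th) < 1e-9) break
    th <- th_new
  }
  th
}

#' @export
print.csf_roi <- function(x, ...) {
  cat(sprintf("<csf_roi> slice %s: %d voxels (%.2f mm^3), threshold %.4g (%s)\n",
              ifelse(is.na(x$slice_idx), "?", x$slice_idx),
              x$n_voxels, x$roi_volume_mm3, x$threshold, x$policy))
  invisible(x)
}

#' @method tidy csf_roi
#' @export
tidy.csf_roi <- function(x, ...) {
  tibble(slice_idx = x$slice_idx, n_voxels = x$n_voxels,
         voxel_volume_mm3 = x$voxel_volume_mm3,
         roi_volume_mm3 = x$roi_volume_mm3,
         threshold = x$threshold, policy = x$policy)
}

#' @method autoplot csf_roi
#' @export
autoplot.csf_roi <- function(object, ...) {
  df <- expand.grid(x = seq_len(nrow(object$mask)), y = seq_len(ncol(object$mask)))
  df$in_roi <- as.vector(object$mask)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$in_roi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90", `TRUE` = "firebrick"),
                               name = "CSF ROI") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("CSF ROI, slice %s (%d voxels)",
                                  object$slice_idx, object$n_voxels)) +
    ggplot2::theme_minimal()
}

#' Compare ROI sizes across groups
#'
#' Per-group mean and SD of the ROI voxel count, plus pairwise pooled
#' two-sample t-tests, mirroring the cross-sectional-area comparison of the
#' fourth-ventricle CSF ROI across cohorts.
#'
#' @param records Data frame with columns `group` and `n_voxels` (one row per
#'   subject), e.g. the output of [run_pipeline()] or [generate_cohort()].
#' @return List with `summary` (tibble: group, n, mean, sd) and `tests`
#'   (tibble of pairwise [two_sample_t()] comparisons).
#' @export
compare_roi_sizes <- function(records) {
  if (!all(c("group", "n_voxels") %in% names(records)))
    stop_csf("`records` must have columns `group` and `n_voxels`.",
             "csfpulse_input_error")
  counts <- table(records$group)
  if (any(counts < 2))
    stop_csf(
      sprintf("Every group needs >= 2 subjects (got: %s).",
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")),
      "csfpulse_stats_error"
    )
  summary <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$n_voxels),
                     sd = sd(.data$n_voxels), .groups = "drop")
  groups <- sort(unique(as.character(records$group)))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    x <- records$n_voxels[records$group == pr[1]]
    y <- records$n_voxels[records$group == pr[2]]
    two_sample_t(x, y, measure = "n_voxels",
                 group_pair = paste(pr, collapse = " vs "))
  })
  list(summary = summary, tests = tests)
}
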