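test_that("phantom generation is deterministic under a fixed seed", {
  sp <- small_phantom_spec(noise_sd = 0.05, seed = 123)
  ph1 <- generate_phantom(sp)
  ph2 <- generate_phantom(sp)
  expect_identical(ph1$image, ph2$image)
  expect_identical(ph1$truth, ph2$truth)
  # and byte-identical NIfTI output
  f1 <- tempfile(fileext = ".nii.gz"); f2 <- tempfile(fileext = ".nii.gz")
  write_phantom(ph1, f1); write_phantom(ph2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("a static noise-free phantom has constant ventricle signal", {
  sp <- small_phantom_spec(waveform = velocity_waveform("constant", v0 = 0))
  ph <- generate_phantom(sp)
  vox <- ph$image[sp$center[1], sp$center[2], 9, ]
  expect_equal(vox, rep(vox[1], length(vox)))
  expect_equal(ph$truth$exchanged_fraction, rep(0, nrow(ph$truth)))
})

test_that("noise-free phantom recovery is exact (shared forward model)", {
  sp <- small_phantom_spec(protocol = small_protocol(n_measurements = 60))
  ph <- generate_phantom(sp)
  res <- suppressWarnings(
    compute_subject(ph$image, sp$protocol, 8, phantom_bbox(ph))
  )
  truth_mean <- mean(ph$truth$pulsed_volume_clamped_mm3[-(1:5)])
  expect_lt(abs(res$summary$mean_pulse - truth_mean), 1e-6)
  expect_equal(res$summary$n_voxels, ph$n_roi_voxels)
  # per-measurement series matches the truth trace, not just the mean
  expect_equal(res$series$raw, ph$truth$pulsed_volume_mm3[-(1:5)],
               tolerance = 1e-9)
})

test_that("descending or out-of-range flow lowers the positive ratio", {
  proto <- small_protocol(n_measurements = 60)
  in_range <- generate_phantom(small_phantom_spec(
    protocol = proto, waveform = velocity_waveform("sinusoid", v0 = 3, amplitude = 1)
  ))
  descending <- generate_phantom(small_phantom_spec(
    protocol = proto, waveform = velocity_waveform("sinusoid", v0 = -3, amplitude = 1)
  ))
  r_in <- suppressWarnings(compute_subject(in_range$image, proto, 8,
                                           phantom_bbox(in_range)))
  r_desc <- suppressWarnings(compute_subject(descending$image, proto, 8,
                                             phantom_bbox(descending)))
  expect_lt(r_desc$summary$positive_ratio, r_in$summary$positive_ratio)
  expect_equal(r_in$summary$positive_ratio, 1)
})

test_that("estimator recovery degrades gracefully with noise", {
  proto <- small_protocol(n_measurements = 60)
  sp0 <- small_phantom_spec(protocol = proto)
  truth_mean <- mean(generate_phantom(sp0)$truth$pulsed_volume_clamped_mm3[-(1:5)])
  err_at <- function(noise, seed) {
    ph <- generate_phantom(small_phantom_spec(protocol = proto,
                                              noise_sd = noise, seed = seed))
    r <- compute_subject(ph$image, proto, 8, phantom_bbox(ph))
    abs(r$summary$mean_pulse - truth_mean) / truth_mean
  }
  e1 <- mean(vapply(1:5, function(s) err_at(0.01, s), numeric(1)))
  e5 <- mean(vapply(1:5, function(s) err_at(0.05, s), numeric(1)))
  expect_lt(e1, e5 + 0.02) # errors shrink (up to sampling noise) as noise drops
  expect_lt(e5, 0.15)
})

test_that("phantom spec rejects inconsistent geometry", {
  expect_csf_error(small_phantom_spec(slice_span = c(10, 12)),
                   "csfpulse_spec_error")
  expect_csf_error(small_phantom_spec(radius_vox = 0.5), "csfpulse_input_error")
  expect_csf_error(small_phantom_spec(noise_sd = -0.1), "csfpulse_input_error")
})

test_that("cohort manifest mirrors the study group structure", {
  co <- generate_cohort(seed = 2)
  expect_equal(nrow(co), 52)
  expect_equal(sum(co$group == "HC"), 17)
  expect_equal(sum(co$group == "PDD-L"), 16)
  expect_equal(sum(co$group == "PDD-H"), 19)
  expect_false(any(duplicated(co$subject_id)))
  # gender counts reproduce the printed table exactly
  expect_equal(sum(co$gender == "M" & co$group == "HC"), 10)
  expect_equal(sum(co$gender == "M" & co$group == "PDD-L"), 11)
  expect_equal(sum(co$gender == "M" & co$group == "PDD-H"), 13)
  # HC carries no disease scores
  expect_true(all(is.na(co$mmse[co$group == "HC"])))
  expect_identical(generate_cohort(seed = 2), co)
})

test_that("cohort pulsation means are recovered within two standard errors", {
  spec <- cohort_spec()
  hits <- vapply(1:5, function(s) {
    co <- generate_cohort(seed = 100 + s)
    all(vapply(seq_len(nrow(spec)), function(i) {
      got <- mean(co$mean_pulse[co$group == spec$group[i]])
      abs(got - spec$pulse_mean[i]) <= 2 * spec$pulse_se[i]
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.6) # each of 3 groups within 2 SE most of the time
})

test_that("image-mode cohorts map pulsation targets through the response curve", {
  spec <- cohort_spec()[2:3, ]
  spec$n <- c(2L, 2L); spec$n_male <- c(1L, 1L)
  td <- withr::local_tempdir()
  proto <- small_protocol(n_measurements = 30)
  man <- generate_cohort(cohort_spec(spec), seed = 8, mode = "image",
                         protocol = proto, dir = td, nx = 20, ny = 20,
                         noise_sd = 0)
  expect_true(all(file.exists(man$image_path)))
  expect_true(file.exists(file.path(td, "manifest.tsv")))
  res <- suppressWarnings(run_pipeline(man, protocol = proto))
  expect_equal(res$mean_pulse, res$true_mean_pulse, tolerance = 1e-6)
})

test_that("infeasible pulsation targets raise a spec error", {
  spec <- cohort_spec()[3, ]
  spec$n <- 2L; spec$n_male <- 1L
  spec$pulse_mean <- 1e5 # beyond full slab exchange for any small ROI
  spec$pulse_se <- 0
  td <- withr::local_tempdir()
  expect_csf_error(
    generate_cohort(cohort_spec(spec), seed = 1, mode = "image",
                    protocol = small_protocol(n_measurements = 10),
                    dir = td, nx = 20, ny = 20),
    "csfpulse_spec_error"
  )
})

test_that("linear drift is injected when requested and removed by the high-pass", {
  proto <- small_protocol(n_measurements = 60)
  sp <- small_phantom_spec(protocol = proto, drift = 0.2)
  ph <- generate_phantom(sp)
  vox <- ph$image[2, 2, 2, ] # pure background voxel: drift only
  expect_gt(var(vox), 0)
  filtered <- temporal_highpass(vox, 0.01, proto$tr_ms)
  expect_lt(var(filtered), 0.1 * var(vox))
})
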