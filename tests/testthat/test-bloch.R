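test_that("steady-state signal follows saturation-recovery closed form", {
  ti <- tissue_params(t1_ms = 4300, m0 = 1)
  expect_equal(steady_state_signal(ti, 0), 0)
  expect_equal(steady_state_signal(ti, 1e9), 1, tolerance = 1e-12)
  # frozen from an independent evaluation of 1 - exp(-2000/4300)
  expect_equal(steady_state_signal(ti, 2000), 0.3719379, tolerance = 1e-7)
  expect_equal(steady_state_signal(tissue_params(m0 = 3), 2000),
               3 * steady_state_signal(ti, 2000))
  expect_csf_error(steady_state_signal(ti, -1), "csfpulse_input_error")
})

test_that("static schedule simulation equals the closed form on every slice", {
  p <- acq_protocol()
  ti <- tissue_params()
  sim <- simulate_schedule(p, ti, velocity_mm_s = 0)
  expect_true(sim$converged)
  expect_equal(sim$signals$signal,
               rep(steady_state_signal(ti, p$tr_ms), p$n_slices),
               tolerance = 1e-9)
  # degenerate single-slice schedule
  p1 <- acq_protocol(n_slices = 1)
  sim1 <- simulate_schedule(p1, ti, 0)
  expect_equal(sim1$signals$signal, steady_state_signal(ti, p1$tr_ms),
               tolerance = 1e-12)
})

test_that("event-driven propagation matches the fine-time-step integrator", {
  # velocities chosen so one TR displacement is a packet-grid multiple,
  # making the two discretizations directly comparable
  p8 <- acq_protocol(tr_ms = 800, n_slices = 8, n_measurements = 10)
  ti <- tissue_params()
  for (v in c(0, 3, -5)) {
    ev <- simulate_schedule(p8, ti, v, n_cycles = 6)$signals$signal
    bf <- oracle_bloch_schedule(p8, ti, v, n_cycles = 6)
    expect_lt(max(abs(ev - bf)), 1e-6)
  }
})

test_that("longitudinal magnetization signals stay within [0, m0]", {
  p8 <- acq_protocol(tr_ms = 800, n_slices = 8, n_measurements = 10)
  ti <- tissue_params(m0 = 2)
  for (v in c(0, 1, 4, -4, 12)) {
    sig <- simulate_schedule(p8, ti, v, n_cycles = 8)$signals$signal
    expect_true(all(sig >= 0 & sig <= ti$m0))
  }
})

test_that("non-convergence raises a diagnostic error", {
  p <- acq_protocol(tr_ms = 800, n_slices = 8, n_measurements = 10)
  err <- expect_error(simulate_schedule(p, tissue_params(), 0, n_cycles = 1),
                      class = "csfpulse_convergence_error")
  expect_match(conditionMessage(err), "cycles")
})

test_that("alpha closed form reproduces the study calibration", {
  p <- acq_protocol()
  ti <- tissue_params(t1_ms = 4300)
  a322 <- calibrate_alpha(p, ti, interslice_interval(p, 8))
  # frozen oracle: (1 - exp(-322/4300)) / (1 - exp(-2000/4300))
  expect_equal(a322$alpha, 0.1939803, tolerance = 1e-6)
  expect_equal(round(a322$alpha, 3), 0.194)
  a387 <- calibrate_alpha(p, ti, interslice_interval(p, 6))
  expect_equal(a387$alpha, 0.2314064, tolerance = 1e-6)
  expect_identical(a322$method, "closed_form")
})

test_that("alpha is strictly increasing in interTR at fixed T1 and TR", {
  ti <- tissue_params()
  p <- acq_protocol()
  fake_pair <- function(itr) tibble::tibble(inter_tr_ms = itr, upper_slice = 9L)
  alphas <- vapply(seq(100, 1900, by = 200),
                   function(itr) calibrate_alpha(p, ti, fake_pair(itr))$alpha,
                   numeric(1))
  expect_true(all(diff(alphas) > 0))
})

test_that("alpha equal to 1 is rejected as degenerate", {
  p <- acq_protocol()
  pair_tr <- tibble::tibble(inter_tr_ms = p$tr_ms, upper_slice = 9L)
  expect_csf_error(calibrate_alpha(p, tissue_params(), pair_tr),
                   "csfpulse_calibration_error")
})

test_that("schedule-simulation alpha agrees with the closed form", {
  # full slab exchange per interTR: every upper-slab spin was saturated by
  # the lower slab's pulse, so the simulated ratio approaches the closed form
  p <- acq_protocol()
  ti <- tissue_params()
  pair <- interslice_interval(p, 8)
  a_sim <- calibrate_alpha(p, ti, pair, method = "schedule_simulation")
  a_cf <- calibrate_alpha(p, ti, pair)
  expect_equal(a_sim$alpha, a_cf$alpha, tolerance = 0.01)
  expect_identical(a_sim$method, "schedule_simulation")
})

test_that("pulse response is zero at rest, positive for in-range ascending flow,
           non-positive for descending flow", {
  p <- acq_protocol()
  ti <- tissue_params()
  pair <- interslice_interval(p, 8)
  v_max_mm_s <- pair$v_max_cm_s * 10
  curve <- pulse_response_curve(p, ti, pair,
                                velocities = c(-10, -2, 0, 2, 10, v_max_mm_s * 2),
                                roi_volume_mm3 = 30.25)
  expect_equal(curve$csfpulse[curve$velocity_mm_s == 0], 0)
  expect_true(all(curve$csfpulse[curve$velocity_mm_s > 0] > 0))
  expect_true(all(curve$csfpulse[curve$velocity_mm_s < 0] <= 0))
})

test_that("pulse response is monotone non-decreasing up to the fold and flat after", {
  p <- acq_protocol()
  ti <- tissue_params()
  pair <- interslice_interval(p, 8)
  v <- seq(0, 30, by = 0.5)
  curve <- pulse_response_curve(p, ti, pair, velocities = v)
  expect_true(all(diff(curve$csfpulse) >= -1e-12))
  # fold point: full slab exchange at thickness / interTR
  v_fold <- p$slice_thickness_mm / (pair$inter_tr_ms / 1000)
  after <- curve$csfpulse[curve$velocity_mm_s >= v_fold]
  expect_lt(max(after) - min(after), 1e-12)
})

test_that("tidy methods expose calibration and schedule tables", {
  p <- acq_protocol(tr_ms = 800, n_slices = 8, n_measurements = 10)
  ti <- tissue_params()
  td <- generics::tidy(calibrate_alpha(p, ti, interslice_interval(p, 3)))
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("alpha", "inter_tr_ms", "tr_ms", "t1_ms", "flip_deg", "method"))
  sim <- simulate_schedule(p, ti, 0)
  expect_identical(generics::tidy(sim), sim$signals)
})
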