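# shared sampled dataset: generated once at known parameters
cal_frames <- toy_frames(n_windows = 21, n_steps = 20000, seed = 202,
                         delta_alpha = 0)
cal_sch <- lambda_schedule(21)

test_that("evaluate_targets is deterministic and finite on toy data", {
  et1 <- evaluate_targets(cal_frames, evb_params(A = 15), cal_sch)
  et2 <- evaluate_targets(cal_frames, evb_params(A = 15), cal_sch)
  expect_identical(et1, et2)
  expect_true(all(is.finite(c(et1$dg_act, et1$dg_rxn))))
})

test_that("sensitivities have the physical signs near the solution", {
  base <- evaluate_targets(cal_frames, evb_params(A = 15), cal_sch)
  up_da <- evaluate_targets(cal_frames, evb_params(A = 15, delta_alpha = 1),
                            cal_sch)
  expect_gt(up_da$dg_rxn, base$dg_rxn)
  # stronger coupling lowers the seam (a large enough A removes the barrier
  # altogether, which is why the continuation mode is used here)
  up_a <- evaluate_targets(cal_frames, evb_params(A = 18), cal_sch,
                           on_no_barrier = "continue")
  expect_lt(up_a$dg_act, base$dg_act)
  # the shift moves the adiabatic reaction free energy by somewhat less
  # than its own size: the response is c2^2(PS) - c2^2(RS), attenuated by
  # state mixing at A = 15 (the exact-delta identity holds on the mapping
  # endpoint and is asserted in the FEP tests)
  expect_gt(up_da$dg_rxn - base$dg_rxn, 0.5)
  expect_lt(up_da$dg_rxn - base$dg_rxn, 1.0)
})

test_that("uncoupled analysis maximizes the barrier over A", {
  acts <- vapply(c(0, 5, 10, 15), function(a) {
    evaluate_targets(cal_frames, evb_params(A = a), cal_sch)$dg_act
  }, numeric(1))
  expect_true(all(diff(acts) < 0))
})

test_that("calibration returns the guess when targets already match", {
  guess <- c(A = 15, delta_alpha = 0)
  et <- evaluate_targets(cal_frames, evb_params(A = 15), cal_sch)
  targets <- calibration_targets(et$dg_act, et$dg_rxn)
  cal <- calibrate_evb(cal_frames, targets, cal_sch, guess = guess)
  expect_equal(cal$iterations, 0)
  expect_equal(cal$params$A, 15)
  expect_equal(cal$params$delta_alpha, 0)
  expect_true(all(abs(cal$residuals) < 1e-12))
})

test_that("calibration recovers targets from a displaced guess", {
  et <- evaluate_targets(cal_frames, evb_params(A = 15), cal_sch)
  targets <- calibration_targets(et$dg_act, et$dg_rxn)
  cal <- calibrate_evb(cal_frames, targets, cal_sch,
                       guess = c(A = 22, delta_alpha = -4))
  expect_true(cal$converged)
  expect_true(all(abs(cal$residuals) <= targets$tolerance))
  # independent audit
  re <- evaluate_targets(cal_frames, cal$params, cal_sch)
  expect_equal(re$dg_act, et$dg_act, tolerance = 0.011)
  expect_equal(re$dg_rxn, et$dg_rxn, tolerance = 0.011)
  # determinism
  cal2 <- calibrate_evb(cal_frames, targets, cal_sch,
                        guess = c(A = 22, delta_alpha = -4))
  expect_equal(cal$params$A, cal2$params$A)
  expect_equal(cal$params$delta_alpha, cal2$params$delta_alpha)
})

test_that("tidy/glance expose the calibration record and JSON round-trips", {
  et <- evaluate_targets(cal_frames, evb_params(A = 15),
                         cal_sch)
  targets <- calibration_targets(et$dg_act, et$dg_rxn)
  cal <- calibrate_evb(cal_frames, targets, cal_sch,
                       guess = c(A = 15, delta_alpha = 0))
  td <- tidy(cal)
  expect_equal(td$term, c("A", "delta_alpha"))
  gl <- glance(cal)
  expect_true(gl$converged)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  rec <- read_calibration(path)
  expect_equal(rec$A, cal$params$A)
  expect_equal(rec$delta_alpha, cal$params$delta_alpha)
  expect_equal(rec$temperature, 300)
})

test_that("unreachable targets raise a calibration error with context", {
  et <- evaluate_targets(cal_frames, evb_params(A = 15),
                         cal_sch)
  bad <- suppressWarnings(calibration_targets(et$dg_act - 200, et$dg_rxn))
  expect_error(
    suppressWarnings(calibrate_evb(cal_frames, bad, cal_sch,
                                   guess = c(A = 15, delta_alpha = 0),
                                   max_iter = 4)),
    class = "evbfep_calibration_error")
})
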