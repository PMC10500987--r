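test_that("lambda schedules are validated", {
  expect_equal(lambda_schedule(3), c(0, 0.5, 1))
  expect_error(lambda_schedule(values = c(0, 0.5)),
               class = "evbfep_domain_error")
  expect_error(lambda_schedule(values = c(0, 0.6, 0.5, 1)),
               class = "evbfep_domain_error")
  # reversed direction allowed for product-to-reactant reanalysis
  expect_equal(validate_schedule(c(1, 0.5, 0)), c(1, 0.5, 0))
})

test_that("zero-variance gaps give the exact free energy", {
  sch <- lambda_schedule(6)
  c_gap <- 3.7
  fr <- const_gap_frames(sch, c_gap, n = 25)
  mfe <- mapping_free_energies(fr, sch)
  expect_equal(dplyr::last(mfe$dg_cum), c_gap, tolerance = 1e-10)
  expect_equal(mfe$dg_fwd[-1], mfe$dg_bwd[-1], tolerance = 1e-10)
  # the gas-phase shift moves the endpoint exactly and leaves hysteresis
  delta <- 11.2
  mfe2 <- mapping_free_energies(fr, sch, delta_alpha = delta)
  expect_equal(dplyr::last(mfe2$dg_cum), c_gap + delta, tolerance = 1e-10)
  expect_equal(mfe2$dg_fwd - mfe2$dg_bwd, mfe$dg_fwd - mfe$dg_bwd,
               tolerance = 1e-10)
})

test_that("forward step reproduces the Gaussian closed form", {
  sch <- c(0, 1)
  m_gap <- 2; s_gap <- 0.5
  fr <- gauss_gap_frames(sch, m_gap, s_gap, n = 2e5, seed = 8)
  beta <- 1 / (KB_KCAL * 300)
  mfe <- mapping_free_energies(fr, sch)
  expect_equal(mfe$dg_fwd[2], m_gap - beta * s_gap^2 / 2, tolerance = 0.01)
  expect_equal(mfe$dg_bwd[2], m_gap + beta * s_gap^2 / 2, tolerance = 0.01)
})

test_that("reversing the schedule negates the total free energy", {
  sch <- lambda_schedule(6)
  fr <- toy_frames(n_windows = 6, n_steps = 4000, seed = 33)
  mfe <- mapping_free_energies(fr, sch)
  rev_fr <- dplyr::mutate(fr, window = 7L - as.integer(window))
  mfe_rev <- mapping_free_energies(rev_fr, rev(sch))
  expect_equal(dplyr::last(mfe_rev$dg_cum), -dplyr::last(mfe$dg_cum),
               tolerance = 1e-10)
})

test_that("windows are checked against the schedule", {
  sch <- lambda_schedule(4)
  fr <- const_gap_frames(sch, 1)
  expect_error(mapping_free_energies(fr, lambda_schedule(5)),
               class = "evbfep_domain_error")
  bad <- dplyr::mutate(fr, lambda = lambda + 0.01 * (window == 2))
  expect_error(mapping_free_energies(bad, sch),
               class = "evbfep_domain_error")
  expect_error(mapping_free_energies(dplyr::filter(fr, window != 2), sch),
               class = "evbfep_domain_error")
})

test_that("binning on the gap coordinate conserves frames", {
  sch <- c(0, 1)
  fr <- tibble::tibble(window = c(1, 1, 2), lambda = c(0, 0, 1),
                       step = c(1, 2, 1),
                       eps1 = c(-1, 0, 1), eps2 = 0)
  bn <- bin_frames(fr, bins = 3)
  expect_equal(sort(bn$frames$bin), 1:3)
  expect_equal(sum(bn$counts$n), 3)
  # reactants (low eps1 - eps2) sit in the low bins
  expect_equal(bn$frames$xs, c(-1, 0, 1))

  same <- dplyr::mutate(fr, eps1 = 2, eps2 = 1)
  expect_warning(bn1 <- bin_frames(same), "single bin")
  expect_equal(unique(bn1$frames$bin), 1)

  big <- toy_frames(n_windows = 5, n_steps = 3000, seed = 21)
  bn2 <- bin_frames(big, bins = 40)
  expect_equal(sum(bn2$counts$n), nrow(big))
})

test_that("umbrella contributions obey the exact algebraic identities", {
  sch <- c(0, 1)
  set.seed(14)
  # all frames have eps1 < eps2, so at lambda = 0 and A = 0: Eg = eps1 = Vm
  fr <- dplyr::bind_rows(
    tibble::tibble(window = 1, lambda = 0, step = 1:60,
                   eps1 = rnorm(60), eps2 = rnorm(60) + 20),
    tibble::tibble(window = 2, lambda = 1, step = 1:60,
                   eps1 = rnorm(60), eps2 = rnorm(60) - 20))
  p0 <- evb_params(A = 0)
  # conditional ("bin") variant: vanishing correction leaves dG(lambda_m)
  cb <- umbrella_profile(fr, p0, sch, bins = 5, normalization = "bin")
  w1 <- dplyr::filter(cb, window == 1)
  expect_equal(w1$contribution, rep(0, nrow(w1)), tolerance = 1e-10)

  # window-normalized variant against a brute-force direct average
  params <- evb_params(A = 6, delta_alpha = 2)
  cw <- umbrella_profile(fr, params, sch, bins = 5)
  beta <- 1 / (KB_KCAL * 300)
  mfe <- mapping_free_energies(fr, sch, params$delta_alpha)
  bn <- bin_frames(fr, params$delta_alpha, bins = 5)
  for (r in seq_len(nrow(cw))) {
    sub <- dplyr::filter(bn$frames, window == cw$window[r], bin == cw$bin[r])
    n_tot <- sum(bn$frames$window == cw$window[r])
    h11 <- sub$eps1; h22 <- sub$eps2 + params$delta_alpha
    eg <- ground_state_energy(h11, h22, params$A)
    vm <- (1 - sub$lambda) * h11 + sub$lambda * h22
    direct <- mfe$dg_cum[cw$window[r]] -
      log(sum(exp(-beta * (eg - vm))) / n_tot) / beta
    expect_equal(cw$contribution[r], direct, tolerance = 1e-10)
  }
})

test_that("bin combination is the count-weighted average with flagging", {
  mk_contrib <- function(df, breaks) {
    out <- tibble::new_tibble(df, class = "evb_contributions")
    attr(out, "breaks") <- breaks
    attr(out, "centers") <- (breaks[-1] + breaks[-length(breaks)]) / 2
    attr(out, "temperature") <- 300
    out
  }
  breaks <- seq(0, 3, 1)
  df <- tibble::tibble(
    window = c(1L, 1L, 2L, 1L, 2L),
    bin = c(1L, 2L, 2L, 3L, 3L),
    xs = c(0.5, 1.5, 1.5, 2.5, 2.5),
    n = c(100L, 50L, 50L, 10L, 30L),
    contribution = c(1, 2, 4, 8, 10))
  prof <- combine_bins(mk_contrib(df, breaks), min_count = 40)
  expect_equal(nrow(prof), 3)
  # single window: its own value; equal counts: plain mean; weighted else
  raw <- c(1, (2 + 4) / 2, (10 * 8 + 30 * 10) / 40)
  expect_equal(prof$dg, raw - min(raw[prof$valid]), tolerance = 1e-12)
  expect_equal(prof$valid, c(TRUE, TRUE, TRUE))
  prof2 <- combine_bins(mk_contrib(df, breaks), min_count = 60)
  expect_equal(prof2$valid, c(TRUE, TRUE, FALSE))
})

test_that("barrier extraction reads the discrete profile", {
  expect_equal(extract_barriers(manual_profile(c(0, 5, 2)))$dg_act, 5)
  expect_equal(extract_barriers(manual_profile(c(0, 5, 2)))$dg_rxn, 2)
  expect_equal(extract_barriers(manual_profile(c(0, 5, 0)))$dg_rxn, 0)
  expect_error(extract_barriers(manual_profile(c(0, 1, 2, 3))),
               class = "evbfep_profile_error")
  expect_error(extract_barriers(manual_profile(c(0, 5))),
               class = "evbfep_profile_error")
  # refinement reproduces a quadratic barrier exactly
  xs <- seq(-3, 3, 0.5)
  prof <- manual_profile(5 - xs^2, xs = xs)
  s <- extract_barriers(prof, refine = "parabolic")
  expect_equal(s[["xs_ts"]], 0, tolerance = 1e-9)
})

test_that("profiles are invariant to a rigid energy shift of both diabats", {
  sch <- lambda_schedule(5)
  fr <- toy_frames(n_windows = 5, n_steps = 5000, seed = 55)
  params <- evb_params(A = 15)
  p1 <- gap_profile(fr, params, sch, min_count = 10)
  fr2 <- dplyr::mutate(fr, eps1 = eps1 + 123.4, eps2 = eps2 + 123.4)
  p2 <- gap_profile(fr2, params, sch, min_count = 10)
  expect_equal(p1$dg, p2$dg, tolerance = 1e-9)
  expect_equal(p1$xs, p2$xs, tolerance = 1e-9)
})

test_that("stored frames can be reanalyzed at new EVB parameters", {
  sch <- lambda_schedule(5)
  fr <- toy_frames(n_windows = 5, n_steps = 5000, seed = 56)
  s1 <- extract_barriers(gap_profile(fr, evb_params(A = 15), sch,
                                     min_count = 10))
  s2 <- extract_barriers(gap_profile(fr, evb_params(A = 5, delta_alpha = 2),
                                     sch, min_count = 10))
  expect_true(is.finite(s1$dg_act) && is.finite(s2$dg_act))
  # weaker coupling -> higher seam
  expect_gt(s2$dg_act, s1$dg_act)
})
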