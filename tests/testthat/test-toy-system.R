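test_that("diabatic energies follow the closed forms", {
  m <- toy_model(harmonic_diabat(k = 1, x0 = 0), harmonic_diabat(k = 1, x0 = 1))
  en <- diabatic_energies(0, m)
  expect_equal(en$eps1, 0)
  expect_equal(en$eps2, 0.5)

  mp <- morse_params(D = 80, a = 1.5, r_eq = 1.1)
  mm <- toy_model(morse_diabat(mp, offset = 2),
                  harmonic_diabat(k = 50, x0 = 1), range = c(0.2, 3))
  x <- seq(0.3, 2.9, length.out = 41)
  en <- diabatic_energies(x, mm)
  expect_equal(en$eps1, 80 * (1 - exp(-1.5 * (x - 1.1)))^2 + 2)
  expect_error(diabatic_energies(5, mm), class = "evbfep_domain_error")

  # offsets shift a diabat rigidly
  m2 <- toy_model(harmonic_diabat(k = 1, x0 = 0, offset = 3),
                  harmonic_diabat(k = 1, x0 = 1))
  expect_equal(diabatic_energies(0.3, m2)$eps1,
               diabatic_energies(0.3, m)$eps1 + 3)
})

test_that("sampler is deterministic under the seed and mixes to the right variance", {
  m <- default_toy_model()
  cfg <- sampler_config(n_steps = 5000, burn_in = 500, seed = 9)
  w1 <- sample_window(m, 0.3, 0, cfg)
  w2 <- sample_window(m, 0.3, 0, cfg)
  expect_identical(w1$x, w2$x)
  w3 <- sample_window(m, 0.3, 0, cfg, seed = 10)
  expect_false(identical(w1$x, w3$x))

  # at lambda = 0 the mapping potential is the k = 100 reactant well:
  # Var(x) = kB T / k; batch-means standard error over 20 batches
  cfg2 <- sampler_config(n_steps = 2e5, burn_in = 2e4, seed = 3)
  w <- sample_window(m, 0, 0, cfg2)
  v_exp <- KB_KCAL * 300 / 100
  batches <- split(w$x, cut(seq_along(w$x), 20))
  bv <- vapply(batches, var, numeric(1))
  se <- sd(bv) / sqrt(length(bv))
  expect_lt(abs(var(w$x) - v_exp), 3 * se + 1e-6)
})

test_that("samples collapse onto the mapping-potential minimum as T -> 0", {
  m <- default_toy_model()
  cfg <- sampler_config(n_steps = 20000, burn_in = 5000, seed = 4,
                        temperature = 5, step_size = 0.02)
  w <- sample_window(m, 0, 0, cfg)
  expect_lt(max(abs(w$x)), 0.1)
})

test_that("window histograms match the Boltzmann weight of the mapping potential", {
  m <- default_toy_model()
  cfg <- sampler_config(n_steps = 2e5, burn_in = 2e4, seed = 12)
  lam <- 0.4
  w <- sample_window(m, lam, 0, cfg)
  beta <- 1 / (KB_KCAL * 300)
  edges <- seq(quantile(w$x, 0.005), quantile(w$x, 0.995), length.out = 21)
  obs <- table(cut(w$x, edges))
  centers <- (edges[-1] + edges[-21]) / 2
  en <- diabatic_energies(centers, m)
  v <- (1 - lam) * en$eps1 + lam * en$eps2
  p_exp <- exp(-beta * (v - min(v)))
  p_exp <- p_exp / sum(p_exp)
  p_obs <- as.numeric(obs) / sum(obs)
  keep <- p_exp * sum(obs) > 500
  # generous: autocorrelation inflates multinomial noise
  expect_lt(max(abs(p_obs[keep] - p_exp[keep]) / p_exp[keep]), 0.15)
})

test_that("FEP schedules chain windows and replicate deterministically", {
  m <- default_toy_model()
  cfg <- sampler_config(n_steps = 2000, burn_in = 200, seed = 5)
  sch <- lambda_schedule(51)
  fr <- run_fep_schedule(m, sch, 0, cfg)
  expect_equal(sort(unique(fr$window)), 1:51)
  expect_equal(unique(fr$lambda), sch)
  fr2 <- run_fep_schedule(m, sch, 0, cfg)
  expect_identical(fr, fr2)

  # a single-window schedule is plain sampling of that state
  one <- run_fep_schedule(m, 0, 0, cfg)
  expect_equal(unique(one$window), 1)
  expect_equal(unique(one$lambda), 0)

  reps <- run_replicas(m, lambda_schedule(5), 0, cfg, n_replicas = 2)
  expect_equal(unique(reps$replica), 1:2)
  r1 <- dplyr::filter(reps, replica == 1)
  r2 <- dplyr::filter(reps, replica == 2)
  expect_false(identical(r1$x, r2$x))
})

test_that("quadrature oracle is symmetric for a mirror-symmetric model", {
  m <- toy_model(harmonic_diabat(k = 100, x0 = 0),
                 harmonic_diabat(k = 100, x0 = 1),
                 coupling = evb_params(A = 10), range = c(-1, 2))
  # even grid_n keeps cell centers off the mirror point x = 0.5
  prof <- exact_gap_profile(m, grid_n = 4000,
                            breaks = seq(-120, 120, length.out = 51))
  # x -> 1 - x maps Xs -> -Xs; profile must be even in Xs
  dg <- prof$dg[prof$valid]
  xs <- prof$xs[prof$valid]
  ord <- order(xs)
  expect_equal(dg[ord], rev(dg[ord]), tolerance = 1e-8)
  s <- extract_barriers(prof)
  expect_equal(s$dg_rxn, 0, tolerance = 1e-8)
})

test_that("uncoupled oracle barrier equals the diabatic crossing height", {
  m <- default_toy_model()
  temperature <- 30  # low T: free energy ~ potential energy
  prof <- exact_gap_profile(m, coupling = evb_params(A = 0),
                            temperature = temperature, bins = 200,
                            grid_n = 20001)
  s <- extract_barriers(prof)
  x <- seq(-1, 2, length.out = 200001)
  en <- diabatic_energies(x, m)
  e_low <- pmin(en$eps1, en$eps2)
  # direct minimization on the grid: seam height above the reactant minimum
  seam <- min(pmax(en$eps1, en$eps2))
  expect_equal(s$dg_act, seam - min(e_low), tolerance = 0.15)
})

test_that("oracle is converged in the quadrature grid", {
  m <- default_toy_model()
  bk <- seq(-140, 130, length.out = 51)
  a1 <- extract_barriers(exact_gap_profile(m, breaks = bk, grid_n = 4001))
  a2 <- extract_barriers(exact_gap_profile(m, breaks = bk, grid_n = 8001))
  expect_lt(abs(a1$dg_act - a2$dg_act), 1e-3)
  expect_lt(abs(a1$dg_rxn - a2$dg_rxn), 1e-3)
})
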