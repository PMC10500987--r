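test_that("ground-state energy matches the 2x2 secular solution", {
  expect_identical(ground_state_energy(0, 0, 0), 0)
  expect_identical(ground_state_energy(0, 10, 0), 0)
  expect_equal(ground_state_energy(5, 5, 3), 2)
  expect_equal(ground_state_energy(5, 9, 2), 7 - sqrt(8))

  # generic 2x2 eigenvalue solver as the independent oracle
  set.seed(42)
  for (i in 1:200) {
    h11 <- runif(1, -50, 50); h22 <- runif(1, -50, 50)
    h12 <- runif(1, -30, 30)
    lam_min <- min(eigen(matrix(c(h11, h12, h12, h22), 2),
                         symmetric = TRUE)$values)
    expect_equal(ground_state_energy(h11, h22, h12), lam_min,
                 tolerance = 1e-12)
  }
  expect_error(ground_state_energy(NaN, 0, 0), class = "evbfep_domain_error")
})

test_that("ground state is bounded by the lower diabat, with equality iff uncoupled", {
  set.seed(7)
  h11 <- runif(500, -100, 100)
  h22 <- runif(500, -100, 100)
  h12 <- runif(500, -50, 50)
  eg <- ground_state_energy(h11, h22, h12)
  expect_true(all(eg <= pmin(h11, h22) + 1e-12))
  nz <- abs(h12) > 1e-8
  expect_true(all(eg[nz] < pmin(h11, h22)[nz]))
  expect_equal(ground_state_energy(h11, h22, 0), pmin(h11, h22))
  # symmetric under diabat swap, invariant under the coupling sign
  expect_equal(eg, ground_state_energy(h22, h11, h12))
  expect_equal(eg, ground_state_energy(h11, h22, -h12))
  # adding c to both diabats adds exactly c
  expect_equal(ground_state_energy(h11 + 3.7, h22 + 3.7, h12), eg + 3.7,
               tolerance = 1e-12)
})

test_that("coupling element covers constant, exponential and Gaussian forms", {
  const <- evb_params(A = 92.66)
  r <- seq(-5, 5, length.out = 101)
  expect_equal(coupling_value(r, const), rep(92.66, 101))
  p <- evb_params(A = 7, mu = 0.3, eta = 0.2, r0 = 1.5)
  expect_equal(coupling_value(1.5, p), 7)
  expect_equal(coupling_value(1, evb_params(A = 1, mu = 1, eta = 0, r0 = 0)),
               exp(-1))
  expect_equal(coupling_value(2, evb_params(A = 1, mu = 0, eta = 1, r0 = 0)),
               exp(-4))
  expect_error(evb_params(A = -1), class = "evbfep_domain_error")
  expect_error(evb_params(eta = -0.1), class = "evbfep_domain_error")
})

test_that("mapping potential is the linear diabat mix with the shifted product state", {
  expect_equal(mapping_potential(2, 4, 0), 2)
  expect_equal(mapping_potential(2, 4, 1, delta_alpha = 1), 5)
  expect_equal(mapping_potential(2, 4, 0.5), 3)
  expect_error(mapping_potential(2, 4, 1.2), class = "evbfep_domain_error")
  expect_error(mapping_potential(2, 4, -0.1), class = "evbfep_domain_error")
  # adding c to both diabats adds exactly c at every lambda
  lam <- seq(0, 1, 0.1)
  expect_equal(mapping_potential(2 + 9.3, 4 + 9.3, lam),
               mapping_potential(2, 4, lam) + 9.3)
})

test_that("Morse potential has its well at r_eq and plateau D", {
  p <- morse_params(D = 100, a = 2, r_eq = 1)
  expect_equal(morse_energy(1, p), 0)
  expect_equal(morse_energy(1e6, p), 100, tolerance = 1e-9)
  expect_equal(morse_energy(1.5, p), 100 * (1 - exp(-1))^2)
  expect_error(morse_energy(0, p), class = "evbfep_domain_error")
  expect_error(morse_params(D = -1, a = 1, r_eq = 1),
               class = "evbfep_domain_error")
})

test_that("soft repulsion is positive and strictly decreasing", {
  p <- soft_repulsion_params(C = 1, beta_rep = 1)
  expect_equal(soft_repulsion_energy(0, p), 1)
  expect_equal(soft_repulsion_energy(1, p), exp(-1))
  r <- seq(0, 10, 0.1)
  e <- soft_repulsion_energy(r, soft_repulsion_params(C = 4.3, beta_rep = 2))
  expect_true(all(e > 0))
  expect_true(all(diff(e) < 0))
})

test_that("gas-phase shift lands on the product diabat only", {
  fr <- tibble::tibble(eps1 = c(1, 2), eps2 = c(2, 5))
  d0 <- diagonal_energies(fr, evb_params())
  expect_equal(d0$h11, c(1, 2))
  expect_equal(d0$h22, c(2, 5))
  d1 <- diagonal_energies(fr, evb_params(delta_alpha = 96.70))
  expect_equal(d1$h11, c(1, 2))
  expect_equal(d1$h22, c(2, 5) + 96.70)
})
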