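#' Boltzmann constant in kcal mol-1 K-1
#'
#' All energies in this package are kcal/mol internally; kJ/mol appears only
#' at file-format boundaries (conversion factor 4.184).
#' @export
KB_KCAL <- 0.0019872041

#' kcal/mol to kJ/mol conversion factor
#' @export
KCAL_TO_KJ <- 4.184

.assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    rlang::abort(paste0("`", name, "` must be finite numeric"),
                 class = "evbfep_domain_error")
  }
  invisible(x)
}

#' EVB coupling and gas-shift parameters
#'
#' The off-diagonal coupling element is H12(r) = A exp(-mu (r - r0) -
#' eta (r - r0)^2), evaluated on a caller-chosen coordinate r (an interatomic
#' distance or the energy gap).  With `mu = eta = 0` the coupling is the flat
#' constant A, which is the form used for calibration.  `delta_alpha` is the
#' gas-phase shift: a constant added to the product diabat only, accounting
#' for the difference in formation free energy between the two valence
#' states, which plain force fields do not capture.
#'
#' @param A Coupling amplitude (kcal/mol), must be >= 0.
#' @param mu Linear decay coefficient (per coordinate unit).
#' @param eta Gaussian decay coefficient (per squared coordinate unit),
#'   must be >= 0.
#' @param r0 Reference coordinate value.
#' @param delta_alpha Gas-phase shift (kcal/mol), added to the product diabat.
#' @return An object of class `evb_params`.
#' @examples
#' evb_params(A = 15)
#' @export
evb_params <- function(A = 0, mu = 0, eta = 0, r0 = 0, delta_alpha = 0) {
  for (nm in c("A", "mu", "eta", "r0", "delta_alpha")) {
    .assert_finite(get(nm), nm)
  }
  if (A < 0) rlang::abort("`A` must be >= 0", class = "evbfep_domain_error")
  if (eta < 0) rlang::abort("`eta` must be >= 0", class = "evbfep_domain_error")
  structure(
    list(A = A, mu = mu, eta = eta, r0 = r0, delta_alpha = delta_alpha),
    class = "evb_params"
  )
}

#' @export
print.evb_params <- function(x, ...) {
  cat("<evb_params>\n")
  cat(sprintf("  H12: A = %g, mu = %g, eta = %g, r0 = %g\n",
              x$A, x$mu, x$eta, x$r0))
  cat(sprintf("  gas-phase shift delta_alpha = %g kcal/mol\n", x$delta_alpha))
  invisible(x)
}

#' Morse bond parameters
#'
#' V(r) = D (1 - exp(-a (r - r_eq)))^2: zero at the equilibrium distance and
#' approaching the dissociation plateau D at large separation.  Used for
#' bonds that break or form during the reaction, where a harmonic term would
#' diverge.
#'
#' @param D Well depth (kcal/mol), > 0.
#' @param a Stiffness (1/distance), > 0.
#' @param r_eq Equilibrium distance, > 0.
#' @return An object of class `morse_params`.
#' @export
morse_params <- function(D, a, r_eq) {
  .assert_finite(D, "D"); .assert_finite(a, "a"); .assert_finite(r_eq, "r_eq")
  if (D <= 0 || a <= 0 || r_eq <= 0) {
    rlang::abort("`D`, `a`, `r_eq` must all be > 0",
                 class = "evbfep_domain_error")
  }
  structure(list(D = D, a = a, r_eq = r_eq), class = "morse_params")
}

#' Soft exponential repulsion parameters
#'
#' V(r) = C exp(-beta_rep r), the soft repulsion that replaces the 6-12 van
#' der Waals term between atoms whose bonding pattern changes; strictly
#' positive and strictly decreasing in r.
#'
#' @param C Prefactor (kcal/mol), > 0.
#' @param beta_rep Exponential decay constant (1/distance), > 0.
#' @return An object of class `soft_repulsion_params`.
#' @export
soft_repulsion_params <- function(C = 1, beta_rep = 1) {
  .assert_finite(C, "C"); .assert_finite(beta_rep, "beta_rep")
  if (C <= 0 || beta_rep <= 0) {
    rlang::abort("`C` and `beta_rep` must be > 0",
                 class = "evbfep_domain_error")
  }
  structure(list(C = C, beta_rep = beta_rep), class = "soft_repulsion_params")
}

#' Ground-state (adiabatic) energy of the two-state EVB Hamiltonian
#'
#' Lowest eigenvalue of the 2x2 secular problem:
#' Eg = (H11 + H22)/2 - sqrt((H11 - H22)^2 + 4 H12^2)/2.
#' Always <= min(H11, H22), with equality iff H12 = 0.
#'
#' @param h11,h22 Diagonal (diabatic) energies, kcal/mol.  `h22` must already
#'   include the gas-phase shift.
#' @param h12 Off-diagonal coupling, kcal/mol.
#' @return Ground-state energy (kcal/mol); vectorized over its arguments.
#' @examples
#' ground_state_energy(5, 9, 2)  # 7 - sqrt(8)
#' @export
ground_state_energy <- function(h11, h22, h12) {
  .assert_finite(h11, "h11"); .assert_finite(h22, "h22")
  .assert_finite(h12, "h12")
  0.5 * (h11 + h22) - 0.5 * sqrt((h11 - h22)^2 + 4 * h12^2)
}

#' Coupling element H12 as a function of the coupling coordinate
#'
#' @param r Coordinate value(s): an interatomic distance or the generalized
#'   reaction coordinate, depending on how the model was parameterized.
#' @param params An [evb_params()] object.
#' @return H12(r) = A exp(-mu (r - r0) - eta (r - r0)^2), kcal/mol.
#' @examples
#' coupling_value(3.1, evb_params(A = 92.66))  # constant coupling
#' @export
coupling_value <- function(r, params) {
  stopifnot(inherits(params, "evb_params"))
  .assert_finite(r, "r")
  dr <- r - params$r0
  params$A * exp(-params$mu * dr - params$eta * dr^2)
}

#' Mapping potential V(lambda)
#'
#' The driving potential for FEP sampling: a linear combination of the two
#' diabats, V(lambda) = (1 - lambda) eps1 + lambda (eps2 + delta_alpha).
#' lambda = 0 is the pure reactant state, lambda = 1 the pure (shifted)
#' product state.
#'
#' @param eps1 Reactant diabatic energy (kcal/mol).
#' @param eps2 Product diabatic energy before the gas-phase shift (kcal/mol).
#' @param lambda Coupling parameter in \[0, 1\].
#' @param delta_alpha Gas-phase shift (kcal/mol).
#' @return V(lambda), kcal/mol; vectorized.
#' @export
mapping_potential <- function(eps1, eps2, lambda, delta_alpha = 0) {
  .assert_finite(eps1, "eps1"); .assert_finite(eps2, "eps2")
  .assert_finite(lambda, "lambda")
  if (any(lambda < 0 | lambda > 1)) {
    rlang::abort("`lambda` must lie in [0, 1]", class = "evbfep_domain_error")
  }
  (1 - lambda) * eps1 + lambda * (eps2 + delta_alpha)
}

#' Morse potential energy
#'
#' @param r Distance(s), > 0.
#' @param p A [morse_params()] object.
#' @return D (1 - exp(-a (r - r_eq)))^2, kcal/mol.
#' @export
morse_energy <- function(r, p) {
  stopifnot(inherits(p, "morse_params"))
  .assert_finite(r, "r")
  if (any(r <= 0)) {
    rlang::abort("Morse potential requires r > 0",
                 class = "evbfep_domain_error")
  }
  p$D * (1 - exp(-p$a * (r - p$r_eq)))^2
}

#' Soft exponential repulsion energy
#'
#' @param r Distance(s), >= 0.
#' @param p A [soft_repulsion_params()] object.
#' @return C exp(-beta_rep r), kcal/mol.
#' @export
soft_repulsion_energy <- function(r, p) {
  stopifnot(inherits(p, "soft_repulsion_params"))
  .assert_finite(r, "r")
  if (any(r < 0)) {
    rlang::abort("repulsion requires r >= 0", class = "evbfep_domain_error")
  }
  p$C * exp(-p$beta_rep * r)
}

#' Diagonal Hamiltonian elements from frame energies
#'
#' H11 = eps1 and H22 = eps2 + delta_alpha: the gas-phase shift lives on the
#' product diabat only, so recalibrating it never invalidates stored
#' trajectories (a constant shift leaves forces unchanged).
#'
#' @param frames A data frame with columns `eps1` and `eps2` (kcal/mol), as
#'   produced by [sample_window()] or [read_energy_xvg()].
#' @param params An [evb_params()] object (only `delta_alpha` is used).
#' @return A tibble with columns `h11` and `h22`.
#' @export
diagonal_energies <- function(frames, params) {
  stopifnot(inherits(params, "evb_params"))
  .assert_frames(frames)
  tibble::tibble(h11 = frames$eps1, h22 = frames$eps2 + params$delta_alpha)
}

# shared validation for per-frame energy tables
.assert_frames <- function(frames, need_window = FALSE) {
  if (!is.data.frame(frames)) {
    rlang::abort("`frames` must be a data frame", class = "evbfep_domain_error")
  }
  need <- c("eps1", "eps2", if (need_window) c("window", "lambda"))
  missing <- setdiff(need, names(frames))
  if (length(missing)) {
    rlang::abort(paste0("`frames` lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "evbfep_domain_error")
  }
  if (nrow(frames) && any(!is.finite(frames$eps1) | !is.finite(frames$eps2))) {
    rlang::abort("non-finite diabatic energies in `frames`",
                 class = "evbfep_domain_error")
  }
  invisible(frames)
}

# numerically stable log of mean(exp(v))
.log_mean_exp <- function(v) {
  m <- max(v)
  m + log(mean(exp(v - m)))
}
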