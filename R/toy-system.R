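#' One-dimensional diabat specifications
#'
#' The toy two-diabat model represents each valence state by a 1D potential
#' on a shared coordinate x (Angstrom): either a harmonic well
#' k/2 (x - x0)^2 or a Morse well, plus a constant energy offset, optionally
#' augmented by a soft exponential repulsion.  The offsets play the role of
#' the different formation energies of the two bonding patterns.
#'
#' @param k Force constant (kcal mol-1 A-2), > 0.
#' @param x0 Position of the minimum (Angstrom).
#' @param offset Constant energy offset (kcal/mol).
#' @return A `toy_diabat` specification.
#' @export
harmonic_diabat <- function(k, x0 = 0, offset = 0) {
  .assert_finite(k, "k"); .assert_finite(x0, "x0")
  .assert_finite(offset, "offset")
  if (k <= 0) rlang::abort("`k` must be > 0", class = "evbfep_domain_error")
  structure(list(type = "harmonic", k = k, x0 = x0, offset = offset,
                 repulsion = NULL),
            class = "toy_diabat")
}

#' @param p A [morse_params()] object.
#' @rdname harmonic_diabat
#' @export
morse_diabat <- function(p, offset = 0) {
  stopifnot(inherits(p, "morse_params"))
  .assert_finite(offset, "offset")
  structure(list(type = "morse", D = p$D, a = p$a, r_eq = p$r_eq,
                 offset = offset, repulsion = NULL),
            class = "toy_diabat")
}

#' Two-diabat toy EVB model
#'
#' A self-contained 1D stand-in for the classical-force-field diabats of a
#' real EVB setup: two diabatic potentials on a common coordinate, a coupling
#' element, and a coordinate range.  Used by the Metropolis sampler and the
#' quadrature oracle so the whole FEP/umbrella pipeline is testable without
#' an MD engine.
#'
#' @param diabat1,diabat2 [harmonic_diabat()] / [morse_diabat()] specs for
#'   the reactant and product states.
#' @param coupling An [evb_params()] object (its `delta_alpha` is ignored
#'   here; the shift is passed explicitly to samplers/analysers).
#' @param repulsion Optional [soft_repulsion_params()] added to one diabat.
#' @param repulsion_on Which diabat (1 or 2) receives `repulsion`.
#' @param range Coordinate range `c(low, high)` (Angstrom), low < high.
#' @return An object of class `toy_evb_model`.
#' @export
toy_model <- function(diabat1, diabat2, coupling = evb_params(A = 15),
                      repulsion = NULL, repulsion_on = 2L,
                      range = c(-1, 2)) {
  stopifnot(inherits(diabat1, "toy_diabat"), inherits(diabat2, "toy_diabat"),
            inherits(coupling, "evb_params"))
  if (length(range) != 2 || !all(is.finite(range)) || range[1] >= range[2]) {
    rlang::abort("`range` must be c(low, high) with low < high",
                 class = "evbfep_domain_error")
  }
  if (!is.null(repulsion)) {
    stopifnot(inherits(repulsion, "soft_repulsion_params"))
    if (!repulsion_on %in% c(1L, 2L)) {
      rlang::abort("`repulsion_on` must be 1 or 2",
                   class = "evbfep_domain_error")
    }
    if (repulsion_on == 1L) diabat1$repulsion <- repulsion
    else diabat2$repulsion <- repulsion
  }
  structure(list(diabat1 = diabat1, diabat2 = diabat2, coupling = coupling,
                 range = range),
            class = "toy_evb_model")
}

#' Default toy model
#'
#' Two harmonic diabats with k = 100 kcal mol-1 A-2 and minima at 0 and 1
#' Angstrom; the product diabat is offset by +4.6 kcal/mol and the coupling
#' is a constant 15 kcal/mol, shaped so that the ground-state profile has a
#' low-kcal/mol barrier and a reaction free energy near +4 kcal/mol.
#' Illustrative only: it emulates windowed sampling between two diabatic
#' surfaces, not any particular chemistry.
#'
#' @return A `toy_evb_model`.
#' @export
default_toy_model <- function() {
  toy_model(
    diabat1 = harmonic_diabat(k = 100, x0 = 0),
    diabat2 = harmonic_diabat(k = 100, x0 = 1, offset = 4.6),
    coupling = evb_params(A = 15),
    range = c(-1, 2)
  )
}

# vectorized evaluation of one diabat
.diabat_energy <- function(x, d) {
  e <- if (d$type == "harmonic") {
    0.5 * d$k * (x - d$x0)^2
  } else {
    d$D * (1 - exp(-d$a * (x - d$r_eq)))^2
  }
  e <- e + d$offset
  if (!is.null(d$repulsion)) {
    e <- e + d$repulsion$C * exp(-d$repulsion$beta_rep * x)
  }
  e
}

# pack a diabat for the C++ kernel
.diabat_pack <- function(d) {
  rep_c <- if (is.null(d$repulsion)) 0 else d$repulsion$C
  rep_b <- if (is.null(d$repulsion)) 0 else d$repulsion$beta_rep
  if (d$type == "harmonic") c(0, d$k, d$x0, 0, d$offset, rep_c, rep_b)
  else c(1, d$D, d$a, d$r_eq, d$offset, rep_c, rep_b)
}

#' Diabatic energies of the toy model at given coordinates
#'
#' @param x Coordinate value(s) inside the model's range.
#' @param model A [toy_model()].
#' @return A tibble with columns `x`, `eps1`, `eps2` (kcal/mol).  `eps2` is
#'   the raw product diabat; the gas-phase shift is applied downstream.
#' @export
diabatic_energies <- function(x, model) {
  stopifnot(inherits(model, "toy_evb_model"))
  .assert_finite(x, "x")
  if (any(x < model$range[1] | x > model$range[2])) {
    rlang::abort("`x` outside the model's coordinate range",
                 class = "evbfep_domain_error")
  }
  tibble::tibble(x = x,
                 eps1 = .diabat_energy(x, model$diabat1),
                 eps2 = .diabat_energy(x, model$diabat2))
}

#' Metropolis sampler configuration
#'
#' @param n_steps Steps per window (must exceed `burn_in`).
#' @param step_size Gaussian proposal width (Angstrom).  The default 0.18
#'   is about 2.4 standard deviations of the default model's wells at 300 K
#'   (the optimal-scaling rule for a 1D random-walk proposal, acceptance
#'   near 45 percent).
#' @param temperature Kelvin, > 0.
#' @param seed Integer RNG seed.
#' @param burn_in Discarded initial steps.
#' @param sample_stride Keep every `sample_stride`-th post-burn-in step.
#'   Kept small by default: thinning only discards information that the
#'   exponential averages downstream need.
#' @return A `sampler_config` object.
#' @export
sampler_config <- function(n_steps = 20000, step_size = 0.18,
                           temperature = 300, seed = 1L,
                           burn_in = 2000, sample_stride = 2L) {
  if (temperature <= 0) {
    rlang::abort("`temperature` must be > 0", class = "evbfep_domain_error")
  }
  if (step_size <= 0) {
    rlang::abort("`step_size` must be > 0", class = "evbfep_domain_error")
  }
  if (n_steps <= burn_in || burn_in < 0 || sample_stride < 1) {
    rlang::abort("need n_steps > burn_in >= 0 and sample_stride >= 1",
                 class = "evbfep_domain_error")
  }
  structure(list(n_steps = as.integer(n_steps), step_size = step_size,
                 temperature = temperature, seed = as.integer(seed),
                 burn_in = as.integer(burn_in),
                 sample_stride = as.integer(sample_stride)),
            class = "sampler_config")
}

#' Sample one FEP window of the toy model
#'
#' Metropolis random walk on the mapping potential
#' V(lambda) = (1 - lambda) eps1(x) + lambda (eps2(x) + delta_alpha) at the
#' configured temperature.  Identical seed gives a bit-identical trajectory.
#'
#' @param model A [toy_model()].
#' @param lambda Coupling parameter in \[0, 1\].
#' @param delta_alpha Gas-phase shift (kcal/mol) entering the mapping
#'   potential.
#' @param config A [sampler_config()].
#' @param x_start Starting coordinate (defaults to the minimum of the
#'   mapping potential on a coarse grid).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A tibble of frames with columns `step`, `x`, `eps1`, `eps2`, and
#'   attributes `lambda` and `accept_rate`.
#' @export
sample_window <- function(model, lambda, delta_alpha = 0, config,
                          x_start = NULL, seed = config$seed) {
  stopifnot(inherits(model, "toy_evb_model"),
            inherits(config, "sampler_config"))
  .assert_finite(lambda, "lambda")
  if (lambda < 0 || lambda > 1) {
    rlang::abort("`lambda` must lie in [0, 1]", class = "evbfep_domain_error")
  }
  if (is.null(x_start)) {
    grid <- seq(model$range[1], model$range[2], length.out = 512)
    en <- diabatic_energies(grid, model)
    v <- (1 - lambda) * en$eps1 + lambda * (en$eps2 + delta_alpha)
    x_start <- grid[which.min(v)]
  }
  beta <- 1 / (KB_KCAL * config$temperature)
  set.seed(seed)
  out <- .metropolis_chain(x_start, lambda, delta_alpha,
                           .diabat_pack(model$diabat1),
                           .diabat_pack(model$diabat2),
                           model$range[1], model$range[2],
                           config$n_steps, config$step_size, beta,
                           config$burn_in, config$sample_stride)
  if (out$accept_rate == 0) {
    rlang::abort("Metropolis sampler accepted no moves; check step_size",
                 class = "evbfep_sampler_error")
  }
  frames <- tibble::tibble(step = seq_along(out$x), x = out$x,
                           eps1 = out$eps1, eps2 = out$eps2)
  attr(frames, "lambda") <- lambda
  attr(frames, "accept_rate") <- out$accept_rate
  attr(frames, "x_last") <- out$x_last
  frames
}

# deterministic per-window / per-replica sub-seeds, kept below 2^31
.sub_seed <- function(seed, index) {
  as.integer((as.double(seed) + 7919 * as.double(index)) %% 2147483647)
}

#' Run a full FEP schedule on the toy model
#'
#' One Metropolis window per lambda value; window m + 1 starts from the final
#' coordinate of window m (consecutive-simulation semantics), and each window
#' draws from a sub-seed derived deterministically from `config$seed` and the
#' window index.
#'
#' @inheritParams sample_window
#' @param schedule Lambda schedule from [lambda_schedule()].
#' @return A tibble of frames with columns `window`, `lambda`, `step`, `x`,
#'   `eps1`, `eps2`.
#' @examples
#' cfg <- sampler_config(n_steps = 2000, burn_in = 200, seed = 7)
#' fr <- run_fep_schedule(default_toy_model(), lambda_schedule(11),
#'                        delta_alpha = 0, config = cfg)
#' @export
run_fep_schedule <- function(model, schedule, delta_alpha = 0, config) {
  # simulation accepts any monotone lambda sequence in [0, 1] (a single
  # window means plain sampling of that state); the analysis side enforces
  # the full 0-to-1 contract
  .assert_finite(schedule, "schedule")
  if (any(schedule < 0 | schedule > 1) ||
      (length(schedule) > 1 && any(diff(schedule) <= 0))) {
    rlang::abort("schedule must be strictly increasing values in [0, 1]",
                 class = "evbfep_domain_error")
  }
  x_start <- NULL
  out <- vector("list", length(schedule))
  for (m in seq_along(schedule)) {
    w <- withCallingHandlers(
      sample_window(model, schedule[m], delta_alpha, config,
                    x_start = x_start, seed = .sub_seed(config$seed, m - 1)),
      error = function(e) {
        rlang::abort(sprintf("window %d (lambda = %.4g) failed: %s",
                             m, schedule[m], conditionMessage(e)),
                     class = "evbfep_sampler_error")
      })
    x_start <- attr(w, "x_last")
    out[[m]] <- dplyr::mutate(w, window = m, lambda = schedule[m],
                              .before = 1)
  }
  dplyr::bind_rows(out)
}

#' Independent replicate FEP runs
#'
#' Replicas share the model and schedule and differ only by sub-seed,
#' mirroring replicate MD simulations started from randomized velocities.
#'
#' @inheritParams run_fep_schedule
#' @param n_replicas Number of independent replicas.
#' @return A tibble of frames with a leading `replica` column.
#' @export
run_replicas <- function(model, schedule, delta_alpha = 0, config,
                         n_replicas = 5L) {
  purrr::map_dfr(seq_len(n_replicas), function(r) {
    cfg <- config
    cfg$seed <- .sub_seed(config$seed, 104729 * r)
    dplyr::mutate(run_fep_schedule(model, schedule, delta_alpha, cfg),
                  replica = r, .before = 1)
  })
}

#' Exact free-energy profile on the gap coordinate by quadrature
#'
#' Brute-force oracle for the sampled pipeline: integrates the Boltzmann
#' weight of the ground-state surface exp(-beta Eg(x)) on a dense coordinate
#' grid, bins each grid point by its gap coordinate
#' Xs = eps1 - (eps2 + delta_alpha) exactly like the estimator, and reports
#' -kT log of the accumulated weight per bin, shifted so the reactant-side
#' minimum is zero.
#'
#' A doubling of `grid_n` should change the extracted barrier by less than
#' 1e-3 kcal/mol for smooth models (asserted in the test suite).
#'
#' @param model A [toy_model()].
#' @param delta_alpha Gas-phase shift (kcal/mol).
#' @param coupling [evb_params()] for H12; defaults to the model's coupling.
#' @param temperature Kelvin.
#' @param grid_n Number of quadrature points over the coordinate range.
#' @param bins Number of uniform gap bins (ignored when `breaks` is given).
#' @param breaks Optional explicit bin edges on the gap coordinate, e.g. the
#'   estimator's edges, so oracle and estimator are binned identically.
#' @param coupling_on Coordinate fed to [coupling_value()]: the sampled
#'   coordinate `"x"` or the gap `"gap"`.  Irrelevant for constant coupling.
#' @return An `evb_profile` tibble: `bin`, `xs`, `dg`, `count`, `valid`.
#' @export
exact_gap_profile <- function(model, delta_alpha = 0, coupling = NULL,
                              temperature = 300, grid_n = 4001, bins = 50,
                              breaks = NULL, coupling_on = c("x", "gap")) {
  stopifnot(inherits(model, "toy_evb_model"))
  coupling_on <- match.arg(coupling_on)
  if (is.null(coupling)) coupling <- model$coupling
  # cell-centered midpoint rule: symmetric grids stay symmetric under
  # mirror models and grid points avoid landing exactly on bin edges
  dx <- diff(model$range) / grid_n
  x <- model$range[1] + (seq_len(grid_n) - 0.5) * dx
  en <- diabatic_energies(x, model)
  h11 <- en$eps1
  h22 <- en$eps2 + delta_alpha
  xs <- h11 - h22
  rr <- if (coupling_on == "x") x else xs
  eg <- ground_state_energy(h11, h22, coupling_value(rr, coupling))
  if (any(!is.finite(eg))) {
    rlang::abort("non-finite ground-state energy on the quadrature grid",
                 class = "evbfep_numeric_error")
  }
  beta <- 1 / (KB_KCAL * temperature)
  if (is.null(breaks)) {
    breaks <- .gap_breaks(xs, bins)
  }
  bin <- .gap_bin(xs, breaks)
  keep <- !is.na(bin)
  # log sum of exp(-beta*eg) per bin, max-shifted
  lw <- -beta * eg[keep]
  m <- max(lw)
  w <- exp(lw - m)
  sums <- tapply(w, factor(bin[keep], levels = seq_len(length(breaks) - 1)),
                 sum, default = 0)
  dg <- ifelse(sums > 0, -(log(sums) + m) / beta, NA_real_)
  counts <- tapply(rep(1, sum(keep)),
                   factor(bin[keep], levels = seq_len(length(breaks) - 1)),
                   sum, default = 0)
  prof <- tibble::tibble(
    bin = seq_len(length(breaks) - 1),
    xs = (breaks[-1] + breaks[-length(breaks)]) / 2,
    dg = as.numeric(dg),
    count = as.integer(counts),
    valid = sums > 0
  )
  prof <- prof[prof$valid, , drop = FALSE]
  .finish_profile(prof, temperature, breaks)
}
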