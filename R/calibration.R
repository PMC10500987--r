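#' Calibration targets
#'
#' Reference activation and reaction free energies the EVB parameters must
#' reproduce, e.g. experimental or ab initio values for the uncatalyzed
#' reference reaction in water.
#'
#' @param dg_act_ref Reference activation free energy (kcal/mol).
#' @param dg_rxn_ref Reference reaction free energy (kcal/mol).
#' @param temperature Kelvin.
#' @param tolerance Convergence tolerance on both residuals (kcal/mol).
#' @return A `calibration_targets` object.
#' @export
calibration_targets <- function(dg_act_ref, dg_rxn_ref, temperature = 300,
                                tolerance = 0.01) {
  .assert_finite(dg_act_ref, "dg_act_ref")
  .assert_finite(dg_rxn_ref, "dg_rxn_ref")
  if (tolerance <= 0) {
    rlang::abort("`tolerance` must be > 0", class = "evbfep_domain_error")
  }
  if (temperature <= 0) {
    rlang::abort("`temperature` must be > 0", class = "evbfep_domain_error")
  }
  if (dg_act_ref < dg_rxn_ref) {
    rlang::warn("dg_act_ref < dg_rxn_ref: barrier below the product state")
  }
  structure(list(dg_act_ref = dg_act_ref, dg_rxn_ref = dg_rxn_ref,
                 temperature = temperature, tolerance = tolerance),
            class = "calibration_targets")
}

#' Evaluate (dG-act, dG-rxn) for given EVB parameters on stored frames
#'
#' Runs the full mapping-FEP / umbrella-sampling stack on stored trajectories
#' and extracts the barrier summary.  Deterministic for fixed inputs; no
#' resampling happens, so the same frames can be reanalyzed at any (A,
#' delta_alpha).
#'
#' @inheritParams gap_profile
#' @param on_no_barrier What to do when the reanalyzed profile has no
#'   interior maximum (which happens for parameter values far from any
#'   physical solution, e.g. a gas-phase shift that pushes the product
#'   diabat monotonically uphill): `"error"` propagates the profile error;
#'   `"continue"` falls back to a continuation convention that splits the
#'   profile at the diabat crossing (gap coordinate 0) and reports the
#'   reactant-side minimum, product-side minimum and intervening maximum of
#'   that split, which gives the calibration solver usable residuals far
#'   from the solution.  Whenever a genuine barrier exists the two modes
#'   agree exactly.
#' @return A one-row tibble with `dg_act` and `dg_rxn` (kcal/mol).
#' @export
evaluate_targets <- function(frames, params, schedule, temperature = 300,
                             bins = 50, min_count = 30, breaks = NULL,
                             on_no_barrier = c("error", "continue")) {
  on_no_barrier <- match.arg(on_no_barrier)
  prof <- gap_profile(frames, params, schedule, temperature,
                      bins = bins, min_count = min_count, breaks = breaks)
  s <- tryCatch(extract_barriers(prof), evbfep_profile_error = function(e) {
    if (on_no_barrier == "error") rlang::cnd_signal(e)
    .degenerate_summary(prof)
  })
  tibble::tibble(dg_act = s$dg_act, dg_rxn = s$dg_rxn)
}

# continuation values for barrier-less profiles: split at the diabat
# crossing Xs = 0, take side minima and the maximum between them
.degenerate_summary <- function(prof) {
  v <- which(prof$valid & is.finite(prof$dg))
  xs <- prof$xs[v]; dg <- prof$dg[v]
  left <- which(xs < 0); right <- which(xs > 0)
  i_rs <- if (length(left)) left[which.min(dg[left])] else 1L
  i_ps <- if (length(right)) right[which.min(dg[right])] else length(v)
  lo <- min(i_rs, i_ps); hi <- max(i_rs, i_ps)
  i_ts <- (lo:hi)[which.max(dg[lo:hi])]
  tibble::tibble(dg_act = dg[i_ts] - dg[i_rs],
                 dg_rxn = dg[i_ps] - dg[i_rs],
                 xs_rs = xs[i_rs], xs_ts = xs[i_ts], xs_ps = xs[i_ps])
}

#' Calibrate the coupling element and gas-phase shift
#'
#' Solves for the constant coupling A (= H12) and the gas-phase shift
#' delta_alpha such that reanalysis of the stored trajectories reproduces the
#' reference (dG-act, dG-rxn).  This is pure post-processing: for
#' constant-coupling runs neither parameter alters the mapping forces, so no
#' resampling is needed.  The 2-unknown root find is a damped quasi-root
#' iteration with numerical differences: alternating 1D secant solves of
#' the gas-phase shift against the reaction free energy and of the coupling
#' against the barrier, which stays robust even when a starting guess lies
#' in the barrier-less regime.  Negative-A excursions are clamped to zero
#' with a warning, and every successful calibration is re-verified by an
#' independent [evaluate_targets()] call before returning.
#'
#' @inheritParams evaluate_targets
#' @param targets A [calibration_targets()] object.
#' @param guess Initial `c(A, delta_alpha)` (kcal/mol).
#' @param max_iter Outer-iteration cap.
#' @param fd_step Initial secant steps in A and delta_alpha (kcal/mol).
#' @param max_step Largest parameter move per inner step (kcal/mol).
#' @return An `evb_calibration` object: calibrated [evb_params()],
#'   residuals, iteration count, and the iteration trace.  Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
calibrate_evb <- function(frames, targets, schedule,
                          guess = c(A = 10, delta_alpha = 0),
                          bins = 50, min_count = 30, breaks = NULL,
                          max_iter = 50, fd_step = c(0.5, 0.5),
                          max_step = 25) {
  stopifnot(inherits(targets, "calibration_targets"))
  temperature <- targets$temperature
  ref <- c(targets$dg_act_ref, targets$dg_rxn_ref)
  p <- as.numeric(guess)
  if (length(p) != 2 || any(!is.finite(p))) {
    rlang::abort("`guess` must be finite c(A, delta_alpha)",
                 class = "evbfep_domain_error")
  }
  if (p[1] < 0) {
    rlang::warn("negative initial A clamped to 0")
    p[1] <- 0
  }
  f <- function(p) {
    et <- evaluate_targets(frames,
                           evb_params(A = p[1], delta_alpha = p[2]),
                           schedule, temperature,
                           bins = bins, min_count = min_count,
                           breaks = breaks, on_no_barrier = "continue")
    c(et$dg_act, et$dg_rxn)
  }
  # Alternating damped-secant iteration: the gas-phase shift is solved
  # against the reaction free energy (a monotone response) and the coupling
  # against the activation barrier, repeating until the joint residual
  # vector is inside the tolerance.  Alternating 1D solves are robust far
  # from the solution, where a joint Newton step can stall on the ridge
  # where barrier and reaction values become collinear.
  secant_1d <- function(fun, x0, step0, tol, lower = -Inf) {
    x1 <- max(x0 + step0, lower)
    f0 <- fun(x0)
    if (abs(f0) <= tol) return(x0)
    f1 <- fun(x1)
    for (k in 1:30) {
      if (abs(f1) <= tol) return(x1)
      denom <- f1 - f0
      dx <- if (abs(denom) < 1e-12) step0 else -f1 * (x1 - x0) / denom
      dx <- max(min(dx, max_step), -max_step)
      x2 <- x1 + dx
      if (x2 < lower) x2 <- lower
      if (x2 == x1) return(x1)
      x0 <- x1; f0 <- f1
      x1 <- x2; f1 <- fun(x1)
    }
    x1
  }
  trace <- list()
  best <- list(p = p, res = NULL, norm = Inf)
  converged <- FALSE
  iter <- 0
  res <- f(p) - ref
  repeat {
    trace[[length(trace) + 1]] <-
      tibble::tibble(iter = iter, A = p[1], delta_alpha = p[2],
                     res_act = res[1], res_rxn = res[2])
    if (max(abs(res)) < best$norm) {
      best <- list(p = p, res = res, norm = max(abs(res)))
    }
    if (max(abs(res)) <= targets$tolerance) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1
    p[2] <- secant_1d(function(da) f(c(p[1], da))[2] - ref[2],
                      p[2], fd_step[2], targets$tolerance / 2)
    p_new <- secant_1d(function(a) f(c(a, p[2]))[1] - ref[1],
                       p[1], fd_step[1], targets$tolerance / 2, lower = 0)
    if (p_new == 0 && p[1] > 0) {
      rlang::warn("negative A excursion clamped to 0")
    }
    p[1] <- p_new
    res <- f(p) - ref
  }
  trace <- dplyr::bind_rows(trace)
  if (!converged) {
    rlang::abort(
      sprintf(paste0("calibration did not converge in %d iterations ",
                     "(best residuals %.4g, %.4g at A = %.4g, ",
                     "delta_alpha = %.4g)"),
              max_iter, best$res[1], best$res[2], best$p[1], best$p[2]),
      class = "evbfep_calibration_error",
      best_params = best$p, best_residuals = best$res, trace = trace)
  }
  params <- evb_params(A = p[1], delta_alpha = p[2])
  # post-condition audit: independent re-evaluation of the returned params
  audit <- evaluate_targets(frames, params, schedule, temperature,
                            bins = bins, min_count = min_count,
                            breaks = breaks)
  audit_res <- c(audit$dg_act, audit$dg_rxn) - ref
  if (max(abs(audit_res)) > targets$tolerance) {
    rlang::abort("calibration audit failed: re-evaluation misses targets",
                 class = "evbfep_calibration_error")
  }
  structure(list(params = params, residuals = audit_res,
                 iterations = iter, converged = TRUE, trace = trace,
                 targets = targets),
            class = "evb_calibration")
}

#' @export
print.evb_calibration <- function(x, ...) {
  cat("<evb_calibration>\n")
  cat(sprintf("  A = %.4f, delta_alpha = %.4f kcal/mol\n",
              x$params$A, x$params$delta_alpha))
  cat(sprintf("  residuals: dG-act %.2e, dG-rxn %.2e kcal/mol (%d iters)\n",
              x$residuals[1], x$residuals[2], x$iterations))
  invisible(x)
}

#' @rdname calibrate_evb
#' @param x An `evb_calibration` object.
#' @param ... Unused.
#' @export
tidy.evb_calibration <- function(x, ...) {
  tibble::tibble(term = c("A", "delta_alpha"),
                 estimate = c(x$params$A, x$params$delta_alpha),
                 residual = x$residuals)
}

#' @rdname calibrate_evb
#' @export
glance.evb_calibration <- function(x, ...) {
  tibble::tibble(A = x$params$A, delta_alpha = x$params$delta_alpha,
                 max_residual = max(abs(x$residuals)),
                 iterations = x$iterations, converged = x$converged,
                 tolerance = x$targets$tolerance)
}

#' Write / read a calibration record as JSON
#'
#' @param x An `evb_calibration` object.
#' @param path Output file.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a list with the stored fields.
#' @export
write_calibration <- function(x, path) {
  stopifnot(inherits(x, "evb_calibration"))
  rec <- list(A = x$params$A, delta_alpha = x$params$delta_alpha,
              residual_dg_act = x$residuals[1],
              residual_dg_rxn = x$residuals[2],
              iterations = x$iterations, converged = x$converged,
              dg_act_ref = x$targets$dg_act_ref,
              dg_rxn_ref = x$targets$dg_rxn_ref,
              temperature = x$targets$temperature,
              tolerance = x$targets$tolerance)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
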