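#' Lambda schedule for a FEP path
#'
#' Ordered coupling-parameter values running from the reactant state
#' (lambda = 0) to the product state (lambda = 1) in small increments.  The
#' default of 51 uniform windows matches common EVB practice.
#'
#' @param n Number of windows for a uniform schedule.
#' @param values Explicit schedule (overrides `n`); must start at 0, end at
#'   1, and be strictly increasing.
#' @return A numeric vector of lambda values.
#' @export
lambda_schedule <- function(n = 51, values = NULL) {
  if (is.null(values)) {
    if (n < 2) rlang::abort("need at least 2 windows",
                            class = "evbfep_domain_error")
    values <- seq(0, 1, length.out = n)
  }
  validate_schedule(values)
}

#' @rdname lambda_schedule
#' @details `validate_schedule()` accepts the canonical increasing 0-to-1
#'   schedule and its exact reversal (1 to 0), so stored windows can be
#'   re-analysed in the product-to-reactant direction.
#' @export
validate_schedule <- function(values) {
  .assert_finite(values, "schedule")
  n <- length(values)
  fwd <- n >= 2 && values[1] == 0 && values[n] == 1 && all(diff(values) > 0)
  rev <- n >= 2 && values[1] == 1 && values[n] == 0 && all(diff(values) < 0)
  if (!fwd && !rev) {
    rlang::abort(
      "schedule must run from 0 to 1 (or 1 to 0) strictly monotonically",
      class = "evbfep_domain_error")
  }
  values
}

# per-frame gap coordinate Xs = eps1 - (eps2 + delta_alpha); the reactant
# basin sits at negative Xs, the product basin at positive Xs
.gap_coordinate <- function(frames, delta_alpha) {
  frames$eps1 - (frames$eps2 + delta_alpha)
}

.gap_breaks <- function(xs, bins) {
  rng <- range(xs)
  if (diff(rng) == 0) {
    rlang::warn("all gap values identical; falling back to a single bin")
    rng <- rng + c(-0.5, 0.5)
    bins <- 1
  }
  seq(rng[1], rng[2], length.out = bins + 1)
}

# bin index on [breaks], closed on the right edge; NA outside
.gap_bin <- function(xs, breaks) {
  b <- findInterval(xs, breaks, rightmost.closed = TRUE)
  b[b < 1 | b > length(breaks) - 1] <- NA_integer_
  b
}

# check frames against a schedule and return the per-window frame list
.split_windows <- function(frames, schedule) {
  .assert_frames(frames, need_window = TRUE)
  schedule <- validate_schedule(schedule)
  got <- sort(unique(frames$window))
  if (!identical(as.integer(got), seq_along(schedule))) {
    rlang::abort(sprintf(
      "frames contain windows {%s} but the schedule has %d windows",
      paste(got, collapse = ","), length(schedule)),
      class = "evbfep_domain_error")
  }
  lam <- dplyr::distinct(frames, .data$window, .data$lambda)
  lam <- lam[order(lam$window), ]
  if (nrow(lam) != length(schedule) ||
      max(abs(lam$lambda - schedule)) > 1e-9) {
    rlang::abort("frame lambda values disagree with the schedule",
                 class = "evbfep_domain_error")
  }
  split(frames, frames$window)
}

#' Free energy along the mapping potential (FEP with hysteresis averaging)
#'
#' For each adjacent window pair the free-energy increment is estimated by
#' exponential averaging in both directions — forward over window n's frames
#' and backward (negated) over window n + 1's frames — and the two estimates
#' are averaged arithmetically to cancel hysteresis.  Because the mapping
#' potential is a linear combination of the diabats, the perturbation energy
#' per frame is exactly Delta-lambda times the (shifted) energy gap.
#' Exponential averages are evaluated with a max-shift (log-sum-exp), so
#' finite input always yields finite output.
#'
#' @param frames Frame tibble with columns `window`, `lambda`, `eps1`,
#'   `eps2` (e.g. from [run_fep_schedule()] or [read_energy_series()]).
#' @param schedule Lambda schedule the frames were generated under.
#' @param delta_alpha Gas-phase shift (kcal/mol).
#' @param temperature Kelvin.
#' @return A tibble with one row per window: `window`, `lambda`, `dg_fwd`,
#'   `dg_bwd`, `dg_step` (the averaged increment from the previous window;
#'   `NA` for the first) and the cumulative `dg_cum` anchored at
#'   `dg_cum[1] = 0`.
#' @export
mapping_free_energies <- function(frames, schedule, delta_alpha = 0,
                                  temperature = 300) {
  if (temperature <= 0) {
    rlang::abort("`temperature` must be > 0", class = "evbfep_domain_error")
  }
  wins <- .split_windows(frames, schedule)
  schedule <- validate_schedule(schedule)
  beta <- 1 / (KB_KCAL * temperature)
  n_win <- length(schedule)
  for (m in seq_len(n_win)) {
    if (nrow(wins[[m]]) == 0) {
      rlang::abort(sprintf("window %d has no frames", m),
                   class = "evbfep_domain_error")
    }
  }
  gaps <- lapply(wins, function(w) (w$eps2 + delta_alpha) - w$eps1)
  dg_fwd <- dg_bwd <- rep(NA_real_, n_win)
  for (m in seq_len(n_win - 1)) {
    dl <- schedule[m + 1] - schedule[m]
    # forward: -kT ln < exp(-beta dl gap) >_m
    dg_fwd[m + 1] <- -.log_mean_exp(-beta * dl * gaps[[m]]) / beta
    # backward: +kT ln < exp(+beta dl gap) >_{m+1}
    dg_bwd[m + 1] <- .log_mean_exp(beta * dl * gaps[[m + 1]]) / beta
  }
  dg_step <- (dg_fwd + dg_bwd) / 2
  dg_cum <- cumsum(ifelse(is.na(dg_step), 0, dg_step))
  tibble::tibble(window = seq_len(n_win), lambda = schedule,
                 dg_fwd = dg_fwd, dg_bwd = dg_bwd, dg_step = dg_step,
                 dg_cum = dg_cum)
}

#' Bin frames on the energy-gap reaction coordinate
#'
#' Every frame is assigned its gap value Xs = eps1 - (eps2 + delta_alpha)
#' and a bin index on a uniform grid spanning the observed gap range.
#'
#' @inheritParams mapping_free_energies
#' @param bins Number of uniform bins (ignored when `breaks` is given).
#' @param breaks Optional explicit bin edges.
#' @return A list of class `evb_binning`: `frames` (the input tibble plus
#'   `xs` and `bin` columns), `breaks`, `centers`, and `counts` (a tibble of
#'   per-(window, bin) frame counts).
#' @export
bin_frames <- function(frames, delta_alpha = 0, bins = 50, breaks = NULL) {
  .assert_frames(frames, need_window = TRUE)
  if (nrow(frames) == 0) {
    rlang::abort("no frames to bin", class = "evbfep_domain_error")
  }
  xs <- .gap_coordinate(frames, delta_alpha)
  if (is.null(breaks)) breaks <- .gap_breaks(xs, bins)
  frames <- dplyr::mutate(frames, xs = xs, bin = .gap_bin(xs, breaks))
  counts <- dplyr::count(dplyr::filter(frames, !is.na(.data$bin)),
                         .data$window, .data$bin, name = "n")
  structure(list(frames = frames, breaks = breaks,
                 centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts),
            class = "evb_binning")
}

#' Per-(window, bin) umbrella-sampling contributions
#'
#' Projects each window's sampling onto the ground-state surface: for window
#' m and gap bin s the contribution is
#' dG(lambda_m) - kT ln < delta(X - Xs) exp(-beta (Eg - V_m)) >_m,
#' where Eg is the two-state ground-state energy and V_m the window's
#' mapping potential.  The sum runs over window m's frames falling in bin s;
#' with `normalization = "window"` (default) it is divided by the window's
#' total frame count, which makes every window's contribution a consistent
#' estimate of the same bin free energy.  `normalization = "bin"` divides by
#' the bin's frame count instead (a conditional average); that variant is
#' provided for comparison but carries a spurious kT ln P_m(s) offset per
#' window and is not used by the default pipeline.  Bins a window never
#' visits are absent (not zero).
#'
#' @inheritParams mapping_free_energies
#' @param params [evb_params()] supplying the coupling and `delta_alpha`.
#' @param bins,breaks Binning control, as in [bin_frames()].
#' @param coupling_on Coordinate for [coupling_value()]: the frame gap
#'   (`"gap"`, always available) or a stored coordinate column `x` (`"x"`).
#' @return A tibble of class `evb_contributions` with columns `window`,
#'   `bin`, `xs`, `n`, `contribution`, and attributes `breaks`, `centers`,
#'   `temperature`, `mapping` (the [mapping_free_energies()] table).
#' @export
umbrella_profile <- function(frames, params, schedule, temperature = 300,
                             bins = 50, breaks = NULL,
                             coupling_on = c("gap", "x"),
                             normalization = c("window", "bin")) {
  stopifnot(inherits(params, "evb_params"))
  coupling_on <- match.arg(coupling_on)
  normalization <- match.arg(normalization)
  mfe <- mapping_free_energies(frames, schedule, params$delta_alpha,
                               temperature)
  bn <- bin_frames(frames, params$delta_alpha, bins = bins, breaks = breaks)
  fr <- bn$frames
  if (coupling_on == "x" && !"x" %in% names(fr)) {
    rlang::abort("coupling_on = 'x' needs an `x` column in `frames`",
                 class = "evbfep_domain_error")
  }
  beta <- 1 / (KB_KCAL * temperature)
  h11 <- fr$eps1
  h22 <- fr$eps2 + params$delta_alpha
  rr <- if (coupling_on == "x") fr$x else fr$xs
  eg <- ground_state_energy(h11, h22, coupling_value(rr, params))
  vm <- (1 - fr$lambda) * h11 + fr$lambda * h22
  fr$du <- eg - vm
  n_tot <- dplyr::count(fr, .data$window, name = "n_window")
  fr <- dplyr::filter(fr, !is.na(.data$bin))
  contrib <- fr |>
    dplyr::group_by(.data$window, .data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     corr = -.log_mean_exp(-beta * .data$du) / beta,
                     .groups = "drop") |>
    dplyr::left_join(mfe[, c("window", "dg_cum")], by = "window") |>
    dplyr::left_join(n_tot, by = "window") |>
    dplyr::mutate(
      xs = bn$centers[.data$bin],
      corr = if (normalization == "window") {
        # mean over bin frames -> delta-normalized sum over the window
        .data$corr + log(.data$n_window / .data$n) / beta
      } else .data$corr,
      contribution = .data$dg_cum + .data$corr) |>
    dplyr::select("window", "bin", "xs", "n", "contribution")
  contrib <- tibble::new_tibble(contrib, class = "evb_contributions")
  attr(contrib, "breaks") <- bn$breaks
  attr(contrib, "centers") <- bn$centers
  attr(contrib, "temperature") <- temperature
  attr(contrib, "mapping") <- mfe
  contrib
}

#' Combine per-window bin contributions into the final profile
#'
#' Weighted average over the windows contributing to each gap bin, the
#' weight of window m being its share of the bin's configurations.  Bins
#' whose total count falls below `min_count` are flagged invalid (kept, not
#' silently dropped) and excluded from barrier extraction.  The profile is
#' then shifted so the reactant-side minimum is zero.
#'
#' @param contributions An `evb_contributions` table from
#'   [umbrella_profile()].
#' @param min_count Minimum configurations for a bin to count as valid.
#' @return An `evb_profile` tibble: `bin`, `xs`, `dg`, `count`, `valid`.
#' @export
combine_bins <- function(contributions, min_count = 30) {
  stopifnot(inherits(contributions, "evb_contributions"))
  breaks <- attr(contributions, "breaks")
  temperature <- attr(contributions, "temperature")
  prof <- contributions |>
    dplyr::group_by(.data$bin, .data$xs) |>
    dplyr::summarise(
      count = sum(.data$n),
      dg = sum(.data$n / sum(.data$n) * .data$contribution),
      .groups = "drop") |>
    dplyr::arrange(.data$xs) |>
    dplyr::mutate(valid = .data$count >= min_count)
  if (!any(prof$valid)) {
    rlang::warn("no bin reaches min_count; flagging all bins invalid")
  }
  .finish_profile(prof[, c("bin", "xs", "dg", "count", "valid")],
                  temperature, breaks)
}

# normalize so the reactant-side minimum (or, failing a barrier, the global
# minimum) is zero, and attach the profile class
.finish_profile <- function(prof, temperature, breaks) {
  loc <- tryCatch(.locate_barrier(prof), error = function(e) NULL)
  shift <- if (is.null(loc)) min(prof$dg[prof$valid], na.rm = TRUE)
           else prof$dg[loc$rs]
  prof$dg <- prof$dg - shift
  out <- tibble::new_tibble(prof, class = "evb_profile")
  attr(out, "temperature") <- temperature
  attr(out, "breaks") <- breaks
  attr(out, "normalization") <- if (is.null(loc)) "global-minimum-zero"
                                else "reactant-minimum-zero"
  out
}

# locate TS/RS/PS on the valid-bin profile; returns row indices into `prof`.
# TS = interior local maximum with the largest prominence
# min(drop to left minimum, drop to right minimum); ties toward smaller |xs|.
.locate_barrier <- function(prof) {
  v <- which(prof$valid & is.finite(prof$dg))
  if (length(v) < 3) {
    rlang::abort("need >= 3 valid bins", class = "evbfep_profile_error")
  }
  g <- prof$dg[v]
  n <- length(g)
  int <- 2:(n - 1)
  is_max <- g[int] >= g[int - 1] & g[int] >= g[int + 1]
  cand <- int[is_max]
  if (!length(cand)) {
    rlang::abort("profile has no interior maximum (no barrier)",
                 class = "evbfep_profile_error")
  }
  prom <- vapply(cand, function(i) {
    min(g[i] - min(g[1:(i - 1)]), g[i] - min(g[(i + 1):n]))
  }, numeric(1))
  best <- cand[prom == max(prom)]
  if (length(best) > 1) best <- best[which.min(abs(prof$xs[v][best]))]
  left <- 1:(best - 1)
  right <- (best + 1):n
  pick_min <- function(idx) {
    lo <- idx[g[idx] == min(g[idx])]
    if (length(lo) > 1) lo <- lo[which.min(abs(prof$xs[v][lo]))]
    lo
  }
  list(ts = v[best], rs = v[pick_min(left)], ps = v[pick_min(right)])
}

#' Extract activation and reaction free energies from a profile
#'
#' Finds the reactant-side minimum, the intervening maximum (transition
#' state), and the product-side minimum on the valid bins of a gap-coordinate
#' profile.  The transition state is the most prominent interior local
#' maximum; ties break toward the smaller absolute gap.
#'
#' With `refine = "none"` the reported free energies are the discrete bin
#' values.  With `refine = "parabolic"` each extremum is refined by a local
#' quadratic fit over the neighbouring bins and the fitted vertex is
#' reported.  On noisy or coarsely binned profiles the raw bin extrema are
#' biased (an argmin over near-degenerate noisy bins selects the noise, and
#' bin averaging flattens curvature); the parabolic vertex removes both
#' effects and is the recommended setting when comparing profiles computed
#' with different binning or sampling noise.
#'
#' @param profile An `evb_profile` from [combine_bins()], [gap_profile()] or
#'   [exact_gap_profile()].
#' @param refine `"none"` (exact bin values) or `"parabolic"` (local
#'   quadratic vertex refinement of each extremum).
#' @param refine_halfwidth Number of valid bins on each side of an extremum
#'   included in the quadratic fit.
#' @return A one-row tibble of class `evb_summary`: `dg_act`, `dg_rxn`,
#'   `xs_rs`, `xs_ts`, `xs_ps` (kcal/mol and gap units).
#' @export
extract_barriers <- function(profile, refine = c("none", "parabolic"),
                             refine_halfwidth = 3) {
  stopifnot(inherits(profile, "evb_profile"))
  refine <- match.arg(refine)
  loc <- .locate_barrier(profile)
  val <- function(idx) {
    if (refine == "none") {
      c(profile$dg[idx], profile$xs[idx])
    } else {
      .refine_extremum(profile, idx, refine_halfwidth)
    }
  }
  rs <- val(loc$rs); ts <- val(loc$ts); ps <- val(loc$ps)
  out <- tibble::tibble(
    dg_act = ts[1] - rs[1],
    dg_rxn = ps[1] - rs[1],
    xs_rs = rs[2], xs_ts = ts[2], xs_ps = ps[2]
  )
  tibble::new_tibble(out, class = "evb_summary")
}

# quadratic vertex through the valid bins around an extremum; falls back to
# the raw bin value when the fit is degenerate or the vertex escapes the
# fitted range
.refine_extremum <- function(profile, idx, half) {
  v <- which(profile$valid & is.finite(profile$dg))
  pos <- match(idx, v)
  sel <- v[max(1, pos - half):min(length(v), pos + half)]
  if (length(sel) < 3) return(c(profile$dg[idx], profile$xs[idx]))
  cf <- stats::coef(stats::lm(dg ~ xs + I(xs^2),
                              data = profile[sel, , drop = FALSE]))
  xv <- -cf[2] / (2 * cf[3])
  if (!is.finite(xv) || xv < min(profile$xs[sel]) ||
      xv > max(profile$xs[sel])) {
    return(c(profile$dg[idx], profile$xs[idx]))
  }
  unname(c(cf[1] + cf[2] * xv + cf[3] * xv^2, xv))
}

#' One-call free-energy profile on the gap coordinate
#'
#' Convenience wrapper chaining [umbrella_profile()] and [combine_bins()].
#'
#' @inheritParams umbrella_profile
#' @inheritParams combine_bins
#' @return An `evb_profile` tibble.
#' @examples
#' cfg <- sampler_config(n_steps = 5000, burn_in = 500, seed = 3)
#' sch <- lambda_schedule(21)
#' fr <- run_fep_schedule(default_toy_model(), sch, config = cfg)
#' prof <- gap_profile(fr, evb_params(A = 15), sch)
#' extract_barriers(prof)
#' @export
gap_profile <- function(frames, params, schedule, temperature = 300,
                        bins = 50, min_count = 30, breaks = NULL,
                        coupling_on = c("gap", "x")) {
  contrib <- umbrella_profile(frames, params, schedule, temperature,
                              bins = bins, breaks = breaks,
                              coupling_on = coupling_on)
  combine_bins(contrib, min_count = min_count)
}

#' @export
print.evb_profile <- function(x, ...) {
  cat(sprintf("<evb_profile> %d bins (%d valid), T = %g K, %s\n",
              nrow(x), sum(x$valid), attr(x, "temperature"),
              attr(x, "normalization")))
  NextMethod()
}

#' Plot a free-energy profile
#'
#' @param object An `evb_profile`.
#' @param ... Unused.
#' @return A ggplot: ground-state free energy vs the gap coordinate, valid
#'   bins as a line, flagged bins as hollow points.
#' @export
autoplot.evb_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$xs, y = .data$dg)) +
    ggplot2::geom_line(data = object[object$valid, ], linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$valid), size = 1.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = expression(epsilon[1] - epsilon[2] ~ "(kcal/mol)"),
      y = expression(Delta * G ~ "(kcal/mol)")) +
    ggplot2::theme_minimal()
}
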