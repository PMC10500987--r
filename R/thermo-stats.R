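#' Arrhenius decomposition of activation free energies
#'
#' Ordinary least-squares fit of dG-act/T against 1/T over a series of
#' temperatures.  Under dG-act(T) = dH-act - T dS-act the plot is linear:
#' the slope is the activation enthalpy dH-act and the intercept is
#' -dS-act.  R-squared is the squared Pearson correlation of the plotted
#' points.
#'
#' @param data A data frame with columns `temperature` (K) and `dg_act`
#'   (kcal/mol); at least two distinct temperatures.
#' @return An `evb_arrhenius` object with elements `dh_act` (kcal/mol),
#'   `ds_act` (kcal mol-1 K-1), `r_squared`, the underlying `lm` fit, and
#'   the data.  Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' tbl <- tibble::tibble(temperature = c(273, 283, 293, 303, 313),
#'                       dg_act = c(15.46, 15.80, 16.00, 16.14, 16.19))
#' fit <- arrhenius_fit(tbl)
#' glance(fit)
#' @export
arrhenius_fit <- function(data) {
  if (!is.data.frame(data) ||
      !all(c("temperature", "dg_act") %in% names(data))) {
    rlang::abort("`data` needs columns `temperature` and `dg_act`",
                 class = "evbfep_domain_error")
  }
  tt <- data$temperature
  gg <- data$dg_act
  .assert_finite(tt, "temperature"); .assert_finite(gg, "dg_act")
  if (any(tt <= 0)) {
    rlang::abort("temperatures must be > 0", class = "evbfep_domain_error")
  }
  if (length(tt) < 2 || length(unique(tt)) < 2) {
    rlang::abort("need >= 2 distinct temperatures",
                 class = "evbfep_domain_error")
  }
  x <- 1 / tt
  y <- gg / tt
  fit <- stats::lm(y ~ x)
  r2 <- if (length(tt) == 2) 1 else stats::cor(x, y)^2
  structure(list(
    dh_act = unname(stats::coef(fit)[2]),
    ds_act = -unname(stats::coef(fit)[1]),
    r_squared = r2,
    fit = fit,
    data = tibble::as_tibble(data[, c("temperature", "dg_act")])
  ), class = "evb_arrhenius")
}

#' @export
print.evb_arrhenius <- function(x, ...) {
  cat("<evb_arrhenius>\n")
  cat(sprintf("  dH-act = %.4f kcal/mol, dS-act = %.6f kcal/(mol K)\n",
              x$dh_act, x$ds_act))
  cat(sprintf("  R^2 = %.4f over %d temperatures\n",
              x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @rdname arrhenius_fit
#' @param x An `evb_arrhenius` object.
#' @param ... Unused.
#' @export
tidy.evb_arrhenius <- function(x, ...) {
  tibble::tibble(term = c("dh_act", "ds_act"),
                 estimate = c(x$dh_act, x$ds_act),
                 unit = c("kcal/mol", "kcal/(mol K)"))
}

#' @rdname arrhenius_fit
#' @export
glance.evb_arrhenius <- function(x, ...) {
  tibble::tibble(dh_act = x$dh_act, ds_act = x$ds_act,
                 r_squared = x$r_squared, n_temperatures = nrow(x$data))
}

#' @rdname arrhenius_fit
#' @param object An `evb_arrhenius` object.
#' @export
autoplot.evb_arrhenius <- function(object, ...) {
  df <- tibble::tibble(x = 1 / object$data$temperature,
                       y = object$data$dg_act / object$data$temperature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = -object$ds_act,
                         slope = object$dh_act, linetype = 2) +
    ggplot2::labs(x = expression(1 / T ~ (K^-1)),
                  y = expression(Delta * G^{"‡"} / T),
                  subtitle = sprintf(
                    "slope = dH-act = %.2f kcal/mol, intercept = -dS-act = %.4f",
                    object$dh_act, -object$ds_act)) +
    ggplot2::theme_minimal()
}

#' Entropic contribution T dS-act at a given temperature
#'
#' @param ds_act Activation entropy (kcal mol-1 K-1).
#' @param temperature Kelvin, > 0.
#' @return T times `ds_act`, kcal/mol.
#' @export
t_delta_s <- function(ds_act, temperature) {
  .assert_finite(ds_act, "ds_act")
  if (any(temperature <= 0)) {
    rlang::abort("`temperature` must be > 0", class = "evbfep_domain_error")
  }
  temperature * ds_act
}

#' Replicate mean, SD and SEM
#'
#' Sample standard deviation (n - 1 denominator) and standard error of the
#' mean SD/sqrt(n) over independent replicate simulations — the error model
#' used for replicate EVB free energies.
#'
#' @param values Numeric vector, length >= 2.
#' @return A one-row tibble: `n`, `mean`, `sd`, `sem`.
#' @export
replicate_summary <- function(values) {
  .assert_finite(values, "values")
  n <- length(values)
  if (n < 2) {
    rlang::abort("need at least 2 replicate values",
                 class = "evbfep_domain_error")
  }
  s <- stats::sd(values)
  tibble::tibble(n = n, mean = mean(values), sd = s, sem = s / sqrt(n))
}
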