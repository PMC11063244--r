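# Quantitative assay computations: Gompertz dose-response EC50 from radial
# growth series, broth-microdilution MIC calling, delta-delta-Ct relative
# expression, and normalisation of measurements to a control.

#' Fit a decreasing Gompertz dose-response model and derive the EC50
#'
#' Fits `f(x) = A * exp(-exp(s * (x - m)))` by nonlinear least squares:
#' `A` is the asymptotic response at zero dose (response units, e.g. colony
#' diameter in cm), `s > 0` the steepness (per concentration unit) and `m`
#' the inflection location (concentration units). The half-maximal
#' concentration relative to the asymptote has the closed form
#' `EC50 = m + log(log(2)) / s`. Starting values are `A = max(response)`,
#' `m` at the concentration whose response is nearest `A/2`, and
#' `s = 4 / range(concentration)`; three deterministic jittered starts
#' guard against local minima and the lowest-RSS fit is kept.
#'
#' @param data Tibble with the dose-response series; replicate rows at the
#'   same concentration are allowed and enter the fit individually.
#' @param conc,response Column names (strings) of concentration (e.g. mM)
#'   and response (e.g. colony diameter, cm or growth fraction).
#' @param control_response Optional measured response at zero dose; when
#'   given, `ec50_control` (concentration where the fitted curve crosses
#'   half of this control) is reported alongside the asymptote-relative
#'   `ec50`.
#' @return Object of class `gompertz_fit`: list with `A`, `s`, `m`, `ec50`,
#'   `ec50_control` (or `NA`), `rss`, `fit` (the underlying `nls` object)
#'   and `data`. `tidy()` gives the parameter table, `glance()` the
#'   one-row fit summary, `autoplot()` the fitted curve over the points.
#' @export
fit_gompertz_ec50 <- function(data, conc = "concentration",
                              response = "response",
                              control_response = NULL) {
  x <- data[[conc]]
  y <- data[[response]]
  if (is.null(x) || is.null(y)) abort("concentration/response columns not found")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4L) abort("need at least 4 distinct concentrations")
  if (any(x <= 0)) abort("concentrations must be positive")
  if (any(y < 0)) abort("responses must be non-negative")
  if (length(unique(y)) == 1L) abort("responses are all equal; nothing to fit")
  mu <- tapply(y, x, mean)
  xs <- as.numeric(names(mu))
  o <- order(xs)
  if (all(diff(mu[o]) >= 0) && any(diff(mu[o]) > 0)) {
    abort("responses increase with concentration; a decreasing dose-response model is inapplicable")
  }

  A0 <- max(y)
  m0 <- xs[which.min(abs(mu - A0 / 2))]
  s0 <- 4 / diff(range(x))
  df <- tibble(x = x, y = y)
  starts <- list(c(1, 1), c(4, 0.8), c(0.25, 1.2))  # (s multiplier, m multiplier)

  best <- NULL
  best_start <- list(A = A0, s = s0, m = m0)
  for (st in starts) {
    start <- list(A = A0, s = s0 * st[1], m = m0 * st[2])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-exp(s * (x - m))), data = df,
                        start = start,
                        lower = c(A = 0, s = 1e-8, m = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort(sprintf(paste0("Gompertz fit did not converge from any start ",
                         "(best starting values: A=%.4g, s=%.4g, m=%.4g)"),
                  best_start$A, best_start$s, best_start$m))
  }
  cf <- coef(best$fit)
  ec50 <- unname(cf["m"] + log(log(2)) / cf["s"])
  ec50_control <- NA_real_
  if (!is.null(control_response)) {
    stopifnot(control_response > 0)
    ratio <- 2 * cf["A"] / control_response
    if (ratio > 1) ec50_control <- unname(cf["m"] + log(log(ratio)) / cf["s"])
  }
  structure(list(A = unname(cf["A"]), s = unname(cf["s"]), m = unname(cf["m"]),
                 ec50 = ec50, ec50_control = ec50_control, rss = best$rss,
                 fit = best$fit, data = df),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz dose-response fit: f(x) = A * exp(-exp(s * (x - m)))\n")
  cat(sprintf("  A = %.4g, s = %.4g, m = %.4g  (RSS %.3g)\n", x$A, x$s, x$m, x$rss))
  cat(sprintf("  EC50 = %.4g", x$ec50))
  if (is.finite(x$ec50_control)) cat(sprintf("  (vs control: %.4g)", x$ec50_control))
  cat("\n")
  invisible(x)
}

#' @export
tidy.gompertz_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, "Estimate"],
         std.error = sm[, "Std. Error"])
}

#' @export
glance.gompertz_fit <- function(x, ...) {
  tibble(ec50 = x$ec50, ec50_control = x$ec50_control, A = x$A, s = x$s,
         m = x$m, rss = x$rss, nobs = nrow(x$data))
}

#' @export
autoplot.gompertz_fit <- function(object, ...) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x), length.out = 200)) |>
    mutate(y = object$A * exp(-exp(object$s * (.data$x - object$m))))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$ec50, linetype = "dashed") +
    ggplot2::labs(x = "concentration", y = "response",
                  subtitle = sprintf("EC50 = %.4g", object$ec50)) +
    ggplot2::theme_minimal()
}

#' Call the MIC from a broth-microdilution series
#'
#' The minimum inhibitory concentration is the lowest tested concentration
#' showing no visible growth. If growth occurs at every concentration the
#' MIC is beyond the tested range and `NA` is returned. A non-monotone
#' pattern (growth at a concentration above a no-growth well) is reported
#' as a warning but the literal definition still applies.
#'
#' @param concentrations Strictly increasing numeric vector of tested
#'   concentrations (e.g. mg/L).
#' @param growth Logical vector, `TRUE` where visible growth occurred.
#' @return The MIC (numeric scalar), or `NA_real_` when growth persists at
#'   the highest tested concentration (MIC > max tested).
#' @export
call_mic <- function(concentrations, growth) {
  if (length(concentrations) == 0L) abort("empty dilution series")
  if (length(concentrations) < 2L) abort("need at least 2 concentrations")
  if (length(growth) != length(concentrations)) {
    abort("concentrations and growth must have the same length")
  }
  if (any(diff(concentrations) <= 0)) abort("concentrations must be strictly increasing")
  no_growth <- which(!growth)
  if (length(no_growth) == 0L) {
    inform(sprintf("growth at all concentrations: MIC > %g", max(concentrations)))
    return(NA_real_)
  }
  mic_idx <- min(no_growth)
  if (any(growth[seq_along(growth) > mic_idx])) {
    warn("non-monotone growth pattern: growth observed above a no-growth well")
  }
  concentrations[mic_idx]
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes `2^(-ddCt)` with
#' `ddCt = (Cq_target_sample - Cq_reference_sample) -
#' (Cq_target_calibrator - Cq_reference_calibrator)`, assuming 100%
#' amplification efficiency. The reference is a stably expressed internal
#' control (e.g. histone H2B); the calibrator is the baseline condition
#' (e.g. time zero or no stressor). Replicate Cq values should be averaged
#' before calling. Vectorised over its arguments.
#'
#' @param cq_target_sample,cq_reference_sample Quantification cycles of the
#'   target and reference genes in the sample condition.
#' @param cq_target_calibrator,cq_reference_calibrator The same pair in the
#'   calibrator condition.
#' @return Fold change (dimensionless); 1 when all four Cq are equal.
#' @export
ddct_fold_change <- function(cq_target_sample, cq_reference_sample,
                             cq_target_calibrator, cq_reference_calibrator) {
  args <- list(cq_target_sample, cq_reference_sample,
               cq_target_calibrator, cq_reference_calibrator)
  if (!all(purrr::map_lgl(args, ~ all(is.finite(.x))))) {
    abort("all Cq values must be finite")
  }
  ddct <- (cq_target_sample - cq_reference_sample) -
    (cq_target_calibrator - cq_reference_calibrator)
  2^(-ddct)
}

#' Normalise measurements to a control
#'
#' Rescales values so the control maps to `scale` (100 by default, as when
#' fluorescence per biomass of an untreated control is defined as 100).
#'
#' @param values Numeric measurements.
#' @param control The control measurement, same units; must be positive.
#' @param scale Value the control is mapped to (default 100).
#' @return `scale * values / control`.
#' @export
normalize_to_control <- function(values, control, scale = 100) {
  if (!is.numeric(control) || length(control) != 1L || !is.finite(control) ||
      control <= 0) {
    abort("`control` must be a single positive number")
  }
  scale * values / control
}
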