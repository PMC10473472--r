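#' Fruit surface area from three caliper dimensions
#'
#' Operationalises "assuming sphericity" as the sphere whose diameter is
#' the geometric mean of length and the two orthogonal equatorial
#' diameters: `A = pi * ((L * d1 * d2)^(1/3))^2`. Inputs in mm, result in
#' cm^2. Standard horticultural practice for near-spheroid fruit.
#'
#' @param length_mm Fruit length, mm.
#' @param diameter1_mm,diameter2_mm Two orthogonal equatorial diameters, mm.
#' @return Surface area, cm^2 (vectorised).
#' @export
surface_area <- function(length_mm, diameter1_mm, diameter2_mm) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0) ||
      any(!is.finite(diameter1_mm)) || any(diameter1_mm <= 0) ||
      any(!is.finite(diameter2_mm)) || any(diameter2_mm <= 0))
    stop("all fruit dimensions must be positive")
  d_g <- (length_mm * diameter1_mm * diameter2_mm)^(1 / 3)
  pi * d_g^2 / 100  # mm^2 -> cm^2
}

logistic_area <- function(t, a_max, k, t_mid)
  a_max / (1 + exp(-k * (t - t_mid)))
gompertz_area <- function(t, a_max, k, t_mid)
  a_max * exp(-exp(-k * (t - t_mid)))

#' Fit a sigmoidal growth model to a surface-area time series
#'
#' Least-squares fit of a 3-parameter logistic (default) or Gompertz curve
#' to surface area vs. time, with a deterministic data-driven start:
#' `a_max <- 1.05 * max(area)`, `t_mid <-` time of half-maximum
#' (interpolated), `k <- 4 * max(finite-difference slope) / a_max`. The
#' peak growth rate and its timing come from the closed-form derivative:
#' `a_max * k / 4` at `t_mid` for the logistic, `a_max * k / e` at `t_mid`
#' for the Gompertz.
#'
#' @param series Data frame with columns `dafb` and `area_cm2` (at least 4
#'   points spanning the inflection).
#' @param family `"logistic"` or `"gompertz"`.
#' @return An object of class `growth_fit`: list with `family`, `a_max`,
#'   `k`, `t_mid`, `residual_sd`, `peak_rate_cm2_per_d`, `t_peak_dafb`,
#'   and the underlying `fit`.
#' @export
fit_growth <- function(series, family = c("logistic", "gompertz")) {
  family <- match.arg(family)
  if (!all(c("dafb", "area_cm2") %in% names(series)))
    stop("`series` needs columns `dafb` and `area_cm2`")
  series <- series[order(series$dafb), , drop = FALSE]
  t <- series$dafb; y <- series$area_cm2
  if (length(t) < 4) stop("growth fit needs at least 4 points")

  a0 <- 1.05 * max(y)
  half <- a0 / 2
  above <- which(y >= half)
  t0 <- if (length(above) && min(above) > 1) {
    i <- min(above)
    t[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  } else stats::median(t)
  slopes <- diff(y) / diff(t)
  k0 <- 4 * max(slopes, 1e-6) / a0

  form <- switch(family,
    logistic = area_cm2 ~ a_max / (1 + exp(-k * (dafb - t_mid))),
    gompertz = area_cm2 ~ a_max * exp(-exp(-k * (dafb - t_mid))))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = series,
                      start = list(a_max = a0, k = k0, t_mid = t0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("growth fit (", family, ") failed to converge: ",
           conditionMessage(e)))
  p <- stats::coef(fit)
  if (p[["a_max"]] <= 0 || p[["k"]] <= 0)
    stop("growth fit (", family, ") converged to non-positive parameters")
  peak <- switch(family,
    logistic = p[["a_max"]] * p[["k"]] / 4,
    gompertz = p[["a_max"]] * p[["k"]] / exp(1))
  structure(list(
    family = family,
    a_max = p[["a_max"]], k = p[["k"]], t_mid = p[["t_mid"]],
    residual_sd = stats::sigma(fit),
    peak_rate_cm2_per_d = peak, t_peak_dafb = p[["t_mid"]],
    fit = fit), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> %s: a_max = %.4g cm^2, k = %.4g d^-1, t_mid = %.4g DAFB\n",
    x$family, x$a_max, x$k, x$t_mid))
  cat(sprintf("  peak growth rate %.4g cm^2 d^-1 at %.4g DAFB (residual sd %.3g)\n",
              x$peak_rate_cm2_per_d, x$t_peak_dafb, x$residual_sd))
  invisible(x)
}

#' Analytic growth-rate curve of a fitted sigmoid
#'
#' First derivative of the fitted curve: for the logistic,
#' `a_max k e^{-k(t - t_mid)} / (1 + e^{-k(t - t_mid)})^2`; for the
#' Gompertz, `a_max k e^{-k(t - t_mid)} exp(-e^{-k(t - t_mid)})`.
#'
#' @param fit A `growth_fit`.
#' @param times Times (DAFB) at which to evaluate the rate.
#' @return Data frame with `dafb` and `rate_cm2_per_d`.
#' @export
growth_rate_curve <- function(fit, times) {
  stopifnot(inherits(fit, "growth_fit"))
  z <- exp(-fit$k * (times - fit$t_mid))
  rate <- switch(fit$family,
    logistic = fit$a_max * fit$k * z / (1 + z)^2,
    gompertz = fit$a_max * fit$k * z * exp(-z))
  data.frame(dafb = times, rate_cm2_per_d = rate)
}

#' Lenticels per fruit from density and surface area
#'
#' The whole-fruit count is lenticel frequency per unit area times fruit
#' surface area (cm^2 converted to mm^2).
#'
#' @param frequency_per_mm2 Lenticel density, mm^-2.
#' @param surface_area_cm2 Fruit surface area, cm^2.
#' @return Lenticel count (vectorised).
#' @export
lenticels_per_fruit <- function(frequency_per_mm2, surface_area_cm2) {
  if (any(frequency_per_mm2 < 0) || any(surface_area_cm2 < 0))
    stop("frequency and surface area must be >= 0")
  frequency_per_mm2 * surface_area_cm2 * 100
}
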