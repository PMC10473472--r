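#' Generate a noisy logistic fruit-growth series
#'
#' Surface area over developmental time follows the 3-parameter logistic
#' `a_max / (1 + exp(-k (t - t_mid)))` with additive Gaussian noise. With
#' `noise_sd = 0` the series lies exactly on the curve.
#'
#' @param a_max Asymptotic surface area, cm^2.
#' @param k Relative growth-rate constant, d^-1.
#' @param t_mid Inflection time, days after full bloom (DAFB).
#' @param times Sampling times (DAFB).
#' @param noise_sd Additive noise standard deviation, cm^2.
#' @param seed Integer RNG seed.
#'
#' @return Data frame with columns `dafb` and `area_cm2`.
#' @export
generate_growth_series <- function(a_max, k, t_mid, times, noise_sd = 0,
                                   seed = 1L) {
  if (!is.numeric(a_max) || a_max <= 0 || !is.numeric(k) || k <= 0)
    stop("`a_max` and `k` must be positive")
  if (length(times) == 0L) stop("`times` must be non-empty")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  mu <- a_max / (1 + exp(-k * (times - t_mid)))
  area <- if (noise_sd > 0) {
    withr::with_seed(as.integer(seed),
                     mu + stats::rnorm(length(times), 0, noise_sd))
  } else mu
  data.frame(dafb = times, area_cm2 = area)
}

#' Generate strain samples with known true apparent strains
#'
#' Back-solves the area quintet of a skin-disc strain experiment from
#' target strain components. The excised-segment area A is the punch
#' cross-section pi (d/2)^2; the dewaxed-membrane area follows from the
#' total strain, A_DCM = A / (1 + eps_tot/100), and the isolated-membrane
#' area from the wax-extraction strain, A_CM = A_DCM (1 + eps_extr/100).
#' Square-hole-pattern areas are included so that the hole-ratio
#' reconstruction of A_DCM is exact. With `cv = 0` the strain calculus
#' recovers the true components exactly on every sample; with `cv > 0`
#' per-sample components are jittered multiplicatively before back-solving.
#'
#' @param true_eps_exc_iso True excision+isolation strain, percent.
#' @param true_eps_extr True wax-extraction strain, percent.
#' @param punch_diameter_mm Biopsy-punch diameter (default 8 mm).
#' @param cv Coefficient of variation of the per-sample strain components.
#' @param n Number of samples.
#' @param seed Integer RNG seed.
#' @param has_lenticels Flag recorded on every sample.
#' @param group Group label recorded on every sample.
#'
#' @return Data frame of strain samples: `sample_id`, `group`,
#'   `has_lenticels`, `a_initial_mm2`, `a_cm_mm2`, `a_dcm_mm2`,
#'   `holes_cm_mm2`, `holes_dcm_mm2`.
#' @export
generate_strain_samples <- function(true_eps_exc_iso, true_eps_extr,
                                    punch_diameter_mm = 8, cv = 0, n = 30,
                                    seed = 1L, has_lenticels = TRUE,
                                    group = if (has_lenticels)
                                      "with_lenticels" else "without_lenticels") {
  if (!is.numeric(punch_diameter_mm) || punch_diameter_mm <= 0)
    stop("`punch_diameter_mm` must be positive")
  if (n < 1) stop("`n` must be >= 1")
  if (true_eps_exc_iso <= -100 || true_eps_extr <= -100)
    stop("strains must exceed -100%")
  if (cv < 0) stop("`cv` must be >= 0")
  draw <- function() {
    e1 <- rep(true_eps_exc_iso, n); e2 <- rep(true_eps_extr, n)
    if (cv > 0) {
      e1 <- e1 * (1 + stats::rnorm(n, 0, cv))
      e2 <- e2 * (1 + stats::rnorm(n, 0, cv))
    }
    list(e1 = e1, e2 = e2)
  }
  e <- if (cv > 0) withr::with_seed(as.integer(seed), draw()) else draw()
  a <- pi * (punch_diameter_mm / 2)^2
  a_dcm <- a / (1 + (e$e1 + e$e2) / 100)
  a_cm <- a_dcm * (1 + e$e2 / 100)
  holes_cm <- rep(4, n)                    # nominal hole-pattern area, mm^2
  holes_dcm <- holes_cm * a_dcm / a_cm     # relaxes with the membrane
  data.frame(
    sample_id = sprintf("%s_%03d", group, seq_len(n)),
    group = group, has_lenticels = has_lenticels,
    a_initial_mm2 = a, a_cm_mm2 = a_cm, a_dcm_mm2 = a_dcm,
    holes_cm_mm2 = holes_cm, holes_dcm_mm2 = holes_dcm)
}

#' Generate a population of russeted-area fractions
#'
#' Fractions are Gaussian draws clipped to `[0, 100]` percent, with the 0-4
#' severity score attached.
#'
#' @param mean_fraction,sd Mean and SD of the russeted fraction, percent.
#' @param n Population size.
#' @param seed Integer RNG seed.
#' @return Data frame with `fruit_id`, `russet_fraction_pct`, `score`.
#' @export
generate_russet_population <- function(mean_fraction, sd, n, seed = 1L) {
  if (n < 1) stop("`n` must be >= 1")
  if (sd < 0) stop("`sd` must be >= 0")
  frac <- withr::with_seed(as.integer(seed),
                           stats::rnorm(n, mean_fraction, sd))
  frac <- pmin(pmax(frac, 0), 100)
  data.frame(fruit_id = seq_len(n), russet_fraction_pct = frac,
             score = russet_score(frac))
}
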