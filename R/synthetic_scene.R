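#' Specification of a synthetic lenticel scene
#'
#' Parameters of the generative model for a calibrated fruit-surface field:
#' lenticels are planted as non-overlapping ellipses (the core, holding a
#' concentric darker pore) at a target density, and a configurable fraction
#' carry a fluorescent halo emulating tracer infiltration through
#' microcracks around the lenticel.
#'
#' Core areas follow a lognormal distribution (areas are positive and
#' right-skewed), parameterised by mean and coefficient of variation. Pore
#' areas are a Beta-distributed fraction of the core area, centred on
#' `pore_to_core_ratio`. Halo areas are `halo_area_multiple` times the core
#' area of the lenticel they surround.
#'
#' @param field_width_mm,field_height_mm Physical extent of the imaged field.
#' @param scale_um_per_px Calibration, micrometres per pixel.
#' @param lenticel_frequency_per_mm2 Target density; the planted count is
#'   `round(frequency * field area)`.
#' @param core_area_mean_mm2 Mean lenticel core area.
#' @param core_area_cv Coefficient of variation of the core-area lognormal.
#' @param pore_to_core_ratio Mean fraction of the core occupied by the pore,
#'   in (0, 1).
#' @param halo_fraction Fraction of lenticels given a fluorescent halo, in
#'   `[0, 1]`.
#' @param halo_area_multiple Halo area as a multiple of the core area.
#' @param background_noise_sd Additive Gaussian pixel noise (intensity
#'   units, full range = 1), clipped to the dynamic range.
#' @param seed Integer RNG seed; identical spec + seed reproduce the scene
#'   bit for bit.
#'
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(field_width_mm = 10, field_height_mm = 10,
                       scale_um_per_px = 20,
                       lenticel_frequency_per_mm2 = 0.15,
                       core_area_mean_mm2 = 0.16, core_area_cv = 0.4,
                       pore_to_core_ratio = 0.3,
                       halo_fraction = 0.5, halo_area_multiple = 3,
                       background_noise_sd = 0.01, seed = 1L) {
  spec <- list(
    field_width_mm = field_width_mm, field_height_mm = field_height_mm,
    scale_um_per_px = scale_um_per_px,
    lenticel_frequency_per_mm2 = lenticel_frequency_per_mm2,
    core_area_mean_mm2 = core_area_mean_mm2, core_area_cv = core_area_cv,
    pore_to_core_ratio = pore_to_core_ratio,
    halo_fraction = halo_fraction, halo_area_multiple = halo_area_multiple,
    background_noise_sd = background_noise_sd, seed = as.integer(seed))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  with(spec, {
    if (!num1(field_width_mm) || field_width_mm <= 0 ||
        !num1(field_height_mm) || field_height_mm <= 0)
      stop("field dimensions must be positive")
    if (!num1(scale_um_per_px) || scale_um_per_px <= 0)
      stop("`scale_um_per_px` must be positive")
    if (!num1(lenticel_frequency_per_mm2) || lenticel_frequency_per_mm2 < 0)
      stop("`lenticel_frequency_per_mm2` must be >= 0")
    if (!num1(core_area_mean_mm2) || core_area_mean_mm2 <= 0 ||
        !num1(core_area_cv) || core_area_cv < 0)
      stop("core-area distribution parameters must be positive (cv >= 0)")
    if (!num1(pore_to_core_ratio) || pore_to_core_ratio <= 0 ||
        pore_to_core_ratio >= 1)
      stop("`pore_to_core_ratio` must lie in (0, 1)")
    if (!num1(halo_fraction) || halo_fraction < 0 || halo_fraction > 1)
      stop("`halo_fraction` must lie in [0, 1]")
    if (!num1(halo_area_multiple) || halo_area_multiple <= 0)
      stop("`halo_area_multiple` must be positive")
    if (!num1(background_noise_sd) || background_noise_sd < 0)
      stop("`background_noise_sd` must be >= 0")
  })
  structure(spec, class = "scene_spec")
}

# Render intensities chosen so that bright-field Otsu separates core from
# background and a within-core split separates pore from core.
.render <- list(bf_background = 0.85, bf_core = 0.35, bf_pore = 0.08,
                fl_background = 0.03, fl_halo = 0.90, edge_sd_px = 1.5)

#' Generate a synthetic calibrated surface scene with ground truth
#'
#' Draws a lenticel population from `spec`, places it on the field by
#' rejection sampling under a non-overlap constraint (bounded retries), and
#' renders two registered channels: a bright-field image (dark elliptical
#' cores with darker concentric pore openings on a bright background) and a
#' fluorescence image (soft-edged halos only around halo-assigned
#' lenticels). Lenticels are placed so that their full rendered extent lies
#' inside the field.
#'
#' @param spec A [scene_spec()].
#' @param max_tries Placement retries per lenticel before giving up.
#'
#' @return A list with elements `brightfield` and `fluorescence`
#'   ([calibrated_image()]s) and `truth`, a data frame with one row per
#'   planted lenticel: `id`, `x_mm`, `y_mm`, `core_area_mm2`,
#'   `pore_area_mm2`, `halo_area_mm2` (`NA` where no halo was assigned),
#'   plus the attribute `frequency_per_mm2` (true planted density).
#' @export
generate_surface_scene <- function(spec, max_tries = 1000L) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, .generate_surface_scene(spec, max_tries))
}

.generate_surface_scene <- function(spec, max_tries) {
  W <- spec$field_width_mm; H <- spec$field_height_mm
  n <- round(spec$lenticel_frequency_per_mm2 * W * H)

  # population draws (all made even for n = 0, so code paths stay uniform)
  sdlog <- sqrt(log(1 + spec$core_area_cv^2))
  meanlog <- log(spec$core_area_mean_mm2) - sdlog^2 / 2
  core <- stats::rlnorm(n, meanlog, sdlog)
  aspect <- stats::runif(n, 1, 2)
  theta <- stats::runif(n, 0, pi)
  conc <- 30  # Beta concentration for the pore/core fraction
  ratio <- stats::rbeta(n, spec$pore_to_core_ratio * conc,
                        (1 - spec$pore_to_core_ratio) * conc)
  pore <- ratio * core
  n_halo <- round(spec$halo_fraction * n)
  has_halo <- rep(FALSE, n)
  if (n_halo > 0) has_halo[sample.int(n, n_halo)] <- TRUE
  halo <- ifelse(has_halo, spec$halo_area_multiple * core, NA_real_)

  # exclusion radius: semi-major axis of the core ellipse, or halo radius
  # (plus its soft edge) where a halo is present, plus a small margin
  a_mm <- sqrt(core * aspect / pi)
  edge_mm <- .render$edge_sd_px * 3 * spec$scale_um_per_px / 1000
  r_excl <- pmax(a_mm, ifelse(has_halo, sqrt(halo / pi) + edge_mm, 0)) + 0.05

  xy <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    if (2 * r_excl[i] >= min(W, H))
      stop("field too crowded: lenticel ", i, " cannot fit in the field")
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(stats::runif(1, r_excl[i], W - r_excl[i]),
                stats::runif(1, r_excl[i], H - r_excl[i]))
      if (i == 1L) { ok <- TRUE } else {
        prev <- seq_len(i - 1L)
        d2 <- (xy[prev, 1] - cand[1])^2 + (xy[prev, 2] - cand[2])^2
        ok <- all(d2 > (r_excl[prev] + r_excl[i])^2)
      }
      if (ok) { xy[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("field too crowded: could not place lenticel ", i, " after ",
           max_tries, " tries")
  }

  scale_mm <- spec$scale_um_per_px / 1000
  W_px <- round(W / scale_mm); H_px <- round(H / scale_mm)
  bf <- matrix(.render$bf_background, H_px, W_px)
  fl <- matrix(.render$fl_background, H_px, W_px)

  for (i in seq_len(n)) {
    a <- a_mm[i]; b <- a / aspect[i]
    ext <- if (has_halo[i]) max(a, sqrt(halo[i] / pi) + edge_mm) else a
    cols <- max(1L, ceiling((xy[i, 1] - ext) / scale_mm)) :
            min(W_px, ceiling((xy[i, 1] + ext) / scale_mm))
    rows <- max(1L, ceiling((xy[i, 2] - ext) / scale_mm)) :
            min(H_px, ceiling((xy[i, 2] + ext) / scale_mm))
    xs <- (cols - 0.5) * scale_mm - xy[i, 1]
    ys <- (rows - 0.5) * scale_mm - xy[i, 2]
    gx <- matrix(xs, length(rows), length(cols), byrow = TRUE)
    gy <- matrix(ys, length(rows), length(cols))
    # rotate into the ellipse frame
    u <- gx * cos(theta[i]) + gy * sin(theta[i])
    v <- -gx * sin(theta[i]) + gy * cos(theta[i])
    q <- (u / a)^2 + (v / b)^2
    s <- sqrt(pore[i] / core[i])     # pore ellipse is the core scaled by s
    patch <- bf[rows, cols]
    patch[q <= 1] <- .render$bf_core
    patch[q <= s^2] <- .render$bf_pore
    bf[rows, cols] <- patch
    if (has_halo[i]) {
      d <- sqrt(gx^2 + gy^2)
      r_h <- sqrt(halo[i] / pi)
      sigma <- .render$edge_sd_px * scale_mm
      # Gaussian-decay edge positioned so the half-maximum contour lies at
      # the true halo radius: thresholding anywhere near mid-intensity then
      # recovers the planted area
      r_in <- max(r_h - sqrt(2 * log(2)) * sigma, 0)
      inten <- .render$fl_halo *
        ifelse(d <= r_in, 1, exp(-(d - r_in)^2 / (2 * sigma^2)))
      fl[rows, cols] <- pmax(fl[rows, cols], inten)
    }
  }

  if (spec$background_noise_sd > 0) {
    bf <- bf + stats::rnorm(length(bf), 0, spec$background_noise_sd)
    fl <- fl + stats::rnorm(length(fl), 0, spec$background_noise_sd)
  }
  bf <- pmin(pmax(bf, 0), 1); fl <- pmin(pmax(fl, 0), 1)

  truth <- data.frame(
    id = seq_len(n),
    x_mm = xy[, 1], y_mm = xy[, 2],
    core_area_mm2 = core, pore_area_mm2 = pore, halo_area_mm2 = halo)
  if (n == 0L)
    truth <- data.frame(id = integer(), x_mm = numeric(), y_mm = numeric(),
                        core_area_mm2 = numeric(), pore_area_mm2 = numeric(),
                        halo_area_mm2 = numeric())
  attr(truth, "frequency_per_mm2") <- n / (W * H)

  list(
    brightfield = calibrated_image(bf, spec$scale_um_per_px, "brightfield"),
    fluorescence = calibrated_image(fl, spec$scale_um_per_px, "fluorescence"),
    truth = truth)
}

#' Write a generated scene to disk
#'
#' Both channels go to 16-bit TIFF with YAML calibration sidecars; the
#' ground truth goes to CSV (one row per lenticel).
#'
#' @param scene Result of [generate_surface_scene()].
#' @param dir Output directory (created if needed).
#' @param stem Filename stem.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_calibrated_tiff(scene$brightfield,
                        file.path(dir, paste0(stem, "_brightfield.tif")))
  write_calibrated_tiff(scene$fluorescence,
                        file.path(dir, paste0(stem, "_fluorescence.tif")))
  utils::write.csv(scene$truth, file.path(dir, paste0(stem, "_truth.csv")),
                   row.names = FALSE)
  invisible(dir)
}
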