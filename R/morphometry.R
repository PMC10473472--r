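#' Segment lenticels on a calibrated bright-field image
#'
#' Reproducible automatic chain: global Otsu threshold on the inverted
#' bright-field intensity, hole filling, connected-component labelling,
#' and an area filter `[min_core_area_mm2, max_core_area_mm2]`. Each
#' retained component is a lenticel core; the pore (the darker opening
#' inside the core) is resolved by a second Otsu split restricted to the
#' component's pixels, guarded by a minimum intensity contrast so that
#' pore-free cores report a pore area of 0.
#'
#' Components touching the image border are flagged: they are excluded
#' from per-lenticel area statistics but contribute a weight of 1/2 to the
#' density estimate (unbiased counting on a finite window).
#'
#' @param image A [calibrated_image()] in the `brightfield` channel.
#' @param min_core_area_mm2,max_core_area_mm2 Area filter for candidate
#'   cores, mm^2.
#' @param pore_contrast Minimum intensity range within a core for a pore
#'   to be resolved (full dynamic range = 1).
#' @param min_contrast Minimum separation between foreground and background
#'   mean intensity for the threshold to be considered meaningful; below
#'   it the image is treated as object-free (a blank, noisy field would
#'   otherwise be split at the noise mean).
#'
#' @return Data frame of lenticel regions sorted by centroid (`x_mm`,
#'   then `y_mm`): `id`, `x_mm`, `y_mm`, `core_area_mm2`, `pore_area_mm2`,
#'   `border` (touches the window edge), `weight` (count weight for
#'   density estimation). Zero rows when nothing is segmented.
#' @export
segment_lenticels <- function(image, min_core_area_mm2 = 0.005,
                              max_core_area_mm2 = 5, pore_contrast = 0.15,
                              min_contrast = 0.1) {
  stopifnot(is_calibrated_image(image))
  if (image$channel != "brightfield")
    stop("`segment_lenticels()` expects a brightfield image, got ",
         image$channel)
  if (!(min_core_area_mm2 > 0 && max_core_area_mm2 > min_core_area_mm2))
    stop("area bounds must satisfy 0 < min < max")

  empty <- data.frame(id = integer(), x_mm = numeric(), y_mm = numeric(),
                      core_area_mm2 = numeric(), pore_area_mm2 = numeric(),
                      border = logical(), weight = numeric())
  px <- image$pixels
  if (diff(range(px)) < 1e-6) {
    warning("degenerate (constant) image: nothing to segment")
    return(empty)
  }

  inv <- 1 - px
  thr <- EBImage::otsu(EBImage::Image(inv), range = c(0, 1))
  fg <- inv > thr
  if (!any(fg) || mean(inv[fg]) - mean(inv[!fg]) < min_contrast) {
    warning("no segmentable contrast: image treated as object-free")
    return(empty)
  }
  mask <- EBImage::fillHull(EBImage::Image(fg))
  lab <- EBImage::imageData(EBImage::bwlabel(mask))

  apx <- px_area_mm2(image)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * apx >= min_core_area_mm2 &
                sizes * apx <= max_core_area_mm2)
  if (length(keep) == 0L) return(empty)

  scale_mm <- image$scale_um_per_px / 1000
  H <- nrow(lab); W <- ncol(lab)
  out <- lapply(keep, function(lbl) {
    idx <- which(lab == lbl, arr.ind = TRUE)
    vals <- px[idx]
    contrast <- max(vals) - min(vals)
    pore_px <- 0L
    if (contrast >= pore_contrast) {
      t2 <- EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1)),
                          range = c(0, 1))
      pore_px <- sum(vals <= t2)
    }
    data.frame(
      x_mm = (mean(idx[, "col"]) - 0.5) * scale_mm,
      y_mm = (mean(idx[, "row"]) - 0.5) * scale_mm,
      core_area_mm2 = nrow(idx) * apx,
      pore_area_mm2 = pore_px * apx,
      border = any(idx[, "row"] %in% c(1L, H)) ||
               any(idx[, "col"] %in% c(1L, W)))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$x_mm, out$y_mm), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  out$weight <- ifelse(out$border, 0.5, 1)
  rownames(out) <- NULL
  out[, c("id", "x_mm", "y_mm", "core_area_mm2", "pore_area_mm2",
          "border", "weight")]
}

#' Lenticel frequency per unit area
#'
#' Border-touching regions count 1/2 (their `weight` column); interior
#' regions count 1.
#'
#' @param regions Data frame from [segment_lenticels()] (a `weight` column
#'   is honoured; absent, every region counts 1).
#' @param window_area_mm2 Area of the measurement window, mm^2.
#' @return Density, lenticels per mm^2.
#' @export
lenticel_frequency <- function(regions, window_area_mm2) {
  if (!is.numeric(window_area_mm2) || window_area_mm2 <= 0)
    stop("`window_area_mm2` must be positive")
  w <- if (!is.null(regions$weight)) regions$weight else rep(1, nrow(regions))
  sum(w) / window_area_mm2
}

#' Fluorescent-tracer infiltrated area around lenticels
#'
#' Thresholds the fluorescence channel (Otsu by default, or a fixed
#' intensity quantile), labels connected fluorescent components, and
#' attributes to each lenticel the component that contains or touches its
#' core footprint. A component claimed by several lenticels is split by
#' nearest-centroid assignment of its pixels, so no area is double
#' counted. The measured area includes the lenticel core itself.
#'
#' @param fluor A [calibrated_image()] in the `fluorescence` channel.
#' @param regions One or more lenticel regions (data frame with `x_mm`,
#'   `y_mm`, `core_area_mm2`).
#' @param threshold_method `"otsu"` or `"quantile"`.
#' @param quantile Intensity quantile used when
#'   `threshold_method = "quantile"`.
#' @return Numeric vector, one infiltrated area (mm^2) per region; 0 where
#'   no fluorescent component touches the region.
#' @export
infiltrated_area <- function(fluor, regions,
                             threshold_method = c("otsu", "quantile"),
                             quantile = 0.99) {
  stopifnot(is_calibrated_image(fluor))
  if (fluor$channel != "fluorescence")
    stop("`infiltrated_area()` expects a fluorescence image, got ",
         fluor$channel)
  threshold_method <- match.arg(threshold_method)
  n <- nrow(regions)
  if (n == 0L) return(numeric(0))

  px <- fluor$pixels
  if (diff(range(px)) < 1e-6) return(rep(0, n))
  thr <- switch(threshold_method,
    otsu = EBImage::otsu(EBImage::Image(px), range = c(0, 1)),
    quantile = stats::quantile(px, quantile, names = FALSE))
  fg <- px > thr
  # a signal-free field split at its noise mean carries no fluorescence
  if (!any(fg) || mean(px[fg]) - mean(px[!fg]) < 0.1) return(rep(0, n))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg)))
  if (max(lab) == 0) return(rep(0, n))

  scale_mm <- fluor$scale_um_per_px / 1000
  apx <- px_area_mm2(fluor)
  H <- nrow(lab); W <- ncol(lab)
  col_of <- function(x) pmin(pmax(round(x / scale_mm + 0.5), 1L), W)
  row_of <- function(y) pmin(pmax(round(y / scale_mm + 0.5), 1L), H)

  # component claimed by each region: at the centroid, else the modal
  # nonzero label within the core-equivalent radius
  claimed <- vapply(seq_len(n), function(i) {
    r0 <- row_of(regions$y_mm[i]); c0 <- col_of(regions$x_mm[i])
    if (r0 < 1 || r0 > H || c0 < 1 || c0 > W)
      stop("region ", i, " centroid lies outside the image")
    lbl <- lab[r0, c0]
    if (lbl == 0) {
      r_px <- ceiling(sqrt(regions$core_area_mm2[i] / pi) / scale_mm)
      sub <- lab[max(1L, r0 - r_px):min(H, r0 + r_px),
                 max(1L, c0 - r_px):min(W, c0 + r_px)]
      nz <- sub[sub > 0]
      lbl <- if (length(nz)) as.integer(names(which.max(table(nz)))) else 0L
    }
    as.integer(lbl)
  }, integer(1))

  comp_sizes <- tabulate(lab[lab > 0])
  out <- numeric(n)
  for (lbl in unique(claimed[claimed > 0])) {
    owners <- which(claimed == lbl)
    if (length(owners) == 1L) {
      out[owners] <- comp_sizes[lbl] * apx
    } else {
      idx <- which(lab == lbl, arr.ind = TRUE)
      pxy <- cbind((idx[, "col"] - 0.5) * scale_mm,
                   (idx[, "row"] - 0.5) * scale_mm)
      d2 <- sapply(owners, function(i)
        (pxy[, 1] - regions$x_mm[i])^2 + (pxy[, 2] - regions$y_mm[i])^2)
      nearest <- max.col(-d2)
      for (j in seq_along(owners))
        out[owners[j]] <- sum(nearest == j) * apx
    }
  }
  out
}

#' Summarize a measurement window
#'
#' Frequency plus per-lenticel means and standard errors (SE = sd/sqrt(n)),
#' mirroring a "means +/- SE" morphometry table. Border-touching regions
#' are excluded from the area statistics but enter the density with weight
#' 1/2.
#'
#' @param regions Data frame from [segment_lenticels()].
#' @param window_area_mm2 Window area, mm^2.
#' @return One-row data frame: `window_area_mm2`, `n_lenticels`,
#'   `frequency_per_mm2`, `mean_core_area_mm2`, `se_core_area_mm2`,
#'   `mean_pore_area_mm2`, `se_pore_area_mm2`. Means are `NA` for an empty
#'   window; SEs are `NA` when fewer than two interior regions exist.
#' @export
summarize_window <- function(regions, window_area_mm2) {
  if (!is.numeric(window_area_mm2) || window_area_mm2 <= 0)
    stop("`window_area_mm2` must be positive")
  interior <- if (!is.null(regions$border))
    regions[!regions$border, , drop = FALSE] else regions
  n_int <- nrow(interior)
  se <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
  mn <- function(x) if (length(x) >= 1) mean(x) else NA_real_
  data.frame(
    window_area_mm2 = window_area_mm2,
    n_lenticels = nrow(regions),
    frequency_per_mm2 = lenticel_frequency(regions, window_area_mm2),
    mean_core_area_mm2 = mn(interior$core_area_mm2),
    se_core_area_mm2 = se(interior$core_area_mm2),
    mean_pore_area_mm2 = mn(interior$pore_area_mm2),
    se_pore_area_mm2 = se(interior$pore_area_mm2))
}
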