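#' Calibrated surface image
#'
#' A thin container pairing a 2-D intensity raster with its physical
#' calibration (micrometres per pixel) and the role of the channel it was
#' acquired in. Intensities are stored as doubles in `[0, 1]`; the physical
#' extent of the field follows from `dim(pixels) * scale_um_per_px`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`; rows index the
#'   y axis (top to bottom), columns the x axis.
#' @param scale_um_per_px Physical size of one pixel edge, in micrometres.
#' @param channel Either `"brightfield"` or `"fluorescence"`.
#'
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, scale_um_per_px,
                             channel = c("brightfield", "fluorescence")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric matrix")
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1L ||
      !is.finite(scale_um_per_px) || scale_um_per_px <= 0)
    stop("`scale_um_per_px` must be a single positive number")
  structure(
    list(pixels = pixels, scale_um_per_px = as.numeric(scale_um_per_px),
         channel = channel),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<calibrated_image> %s, %d x %d px at %.3g um/px (%.2f x %.2f mm)\n",
    x$channel, d[2], d[1], x$scale_um_per_px,
    d[2] * x$scale_um_per_px / 1000, d[1] * x$scale_um_per_px / 1000))
  invisible(x)
}

is_calibrated_image <- function(x) inherits(x, "calibrated_image")

#' Area of one pixel in mm^2
#' @noRd
px_area_mm2 <- function(img) (img$scale_um_per_px / 1000)^2

#' Write a calibrated image to TIFF with a YAML calibration sidecar
#'
#' The raster is written as 16-bit grayscale TIFF; the physical scale and
#' channel role go to `<path>.yaml` so a round trip preserves calibration.
#'
#' @param img A [calibrated_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_calibrated_tiff <- function(img, path) {
  stopifnot(is_calibrated_image(img))
  tiff::writeTIFF(img$pixels, path, bits.per.sample = 16L)
  yaml::write_yaml(
    list(scale_um_per_px = img$scale_um_per_px, channel = img$channel),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Read a calibrated image written by [write_calibrated_tiff()]
#'
#' @param path TIFF path. Calibration is taken from the `<path>.yaml`
#'   sidecar unless `scale_um_per_px`/`channel` are supplied explicitly.
#' @param scale_um_per_px,channel Optional overrides for the sidecar.
#' @return A [calibrated_image()].
#' @export
read_calibrated_tiff <- function(path, scale_um_per_px = NULL, channel = NULL) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  scale <- scale_um_per_px %||% meta$scale_um_per_px
  chan <- channel %||% meta$channel
  if (is.null(scale))
    stop("no calibration: supply `scale_um_per_px` or provide a sidecar YAML")
  calibrated_image(px, scale, chan %||% "brightfield")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
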