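# Shared fixtures built in code.

# A small, quick scene with well-separated lenticels.
small_scene_spec <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(field_width_mm = 10, field_height_mm = 10, scale_um_per_px = 20,
         lenticel_frequency_per_mm2 = 0.5, core_area_mean_mm2 = 0.1,
         core_area_cv = 0.3, halo_fraction = 0.5, halo_area_multiple = 3,
         background_noise_sd = 0.01, seed = seed),
    list(...))
  do.call(scene_spec, args)
}

# Match each segmented region to its nearest planted lenticel.
match_truth <- function(regions, truth) {
  vapply(seq_len(nrow(regions)), function(i)
    which.min((truth$x_mm - regions$x_mm[i])^2 +
              (truth$y_mm - regions$y_mm[i])^2), integer(1))
}

# A hand-built bright-field raster: bright background with hard-edged dark
# disks (optionally darker center pore) at given centers/radii, all in mm.
disk_image <- function(width_mm, height_mm, scale_um_per_px,
                       x_mm, y_mm, r_mm, pore_r_mm = 0) {
  scale_mm <- scale_um_per_px / 1000
  W <- round(width_mm / scale_mm); H <- round(height_mm / scale_mm)
  px <- matrix(0.9, H, W)
  xs <- (col(px) - 0.5) * scale_mm
  ys <- (row(px) - 0.5) * scale_mm
  for (i in seq_along(x_mm)) {
    d2 <- (xs - x_mm[i])^2 + (ys - y_mm[i])^2
    px[d2 <= r_mm[i]^2] <- 0.3
    if (pore_r_mm[i] > 0) px[d2 <= pore_r_mm[i]^2] <- 0.05
  }
  calibrated_image(px, scale_um_per_px, "brightfield")
}
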