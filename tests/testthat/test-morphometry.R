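test_that("degenerate and wrong-channel inputs are handled", {
  flat <- calibrated_image(matrix(0.5, 50, 50), 10, "brightfield")
  expect_warning(reg <- segment_lenticels(flat), "constant")
  expect_equal(nrow(reg), 0L)
  fluor <- calibrated_image(matrix(0.5, 50, 50), 10, "fluorescence")
  expect_error(segment_lenticels(fluor), "brightfield")
  expect_error(infiltrated_area(flat, data.frame(x_mm = 1, y_mm = 1,
                                                 core_area_mm2 = 0.1)),
               "fluorescence")
  expect_error(segment_lenticels(flat, min_core_area_mm2 = 1,
                                 max_core_area_mm2 = 0.5), "min < max")
})

test_that("a single planted disk is measured to within 5% of pi r^2", {
  img <- disk_image(4, 4, 10, x_mm = 2, y_mm = 2, r_mm = 0.2,
                    pore_r_mm = 0.08)
  reg <- segment_lenticels(img)
  expect_equal(nrow(reg), 1L)
  expect_lt(abs(reg$core_area_mm2 - pi * 0.2^2) / (pi * 0.2^2), 0.05)
  expect_lt(abs(reg$pore_area_mm2 - pi * 0.08^2) / (pi * 0.08^2), 0.05)
  expect_equal(reg$x_mm, 2, tolerance = 0.02)
  expect_equal(reg$y_mm, 2, tolerance = 0.02)
  # a pore-free disk reports zero pore area
  reg0 <- segment_lenticels(disk_image(4, 4, 10, 2, 2, 0.2, 0))
  expect_equal(reg0$pore_area_mm2, 0)
})

test_that("generator scenes are recovered lenticel by lenticel", {
  scene <- generate_surface_scene(small_scene_spec())
  reg <- segment_lenticels(scene$brightfield)
  expect_equal(nrow(reg), 50L)
  idx <- match_truth(reg, scene$truth)
  expect_equal(sort(idx), 1:50)  # one-to-one
  rel <- abs(reg$core_area_mm2 - scene$truth$core_area_mm2[idx]) /
    scene$truth$core_area_mm2[idx]
  expect_lt(max(rel), 0.05)
  # core >= pore holds for every region
  expect_true(all(reg$pore_area_mm2 <= reg$core_area_mm2))
})

test_that("lenticel frequency is count over window area with border half-counts", {
  reg <- data.frame(weight = rep(1, 50))
  expect_equal(lenticel_frequency(reg, 100), 0.5)
  expect_equal(lenticel_frequency(data.frame(weight = numeric()), 10), 0)
  expect_error(lenticel_frequency(reg, 0), "positive")
  # disk crossing the window edge: flagged, half-weighted, out of area stats
  img <- disk_image(4, 4, 10, x_mm = c(0.02, 2), y_mm = c(2, 2),
                    r_mm = c(0.2, 0.2), pore_r_mm = c(0, 0))
  reg2 <- segment_lenticels(img)
  expect_equal(nrow(reg2), 2L)
  expect_equal(sort(reg2$border), c(FALSE, TRUE))
  expect_equal(lenticel_frequency(reg2, 16), 1.5 / 16)
  sm <- summarize_window(reg2, 16)
  expect_equal(sm$n_lenticels, 2L)
  expect_lt(abs(sm$mean_core_area_mm2 - pi * 0.04) / (pi * 0.04), 0.05)
  expect_true(is.na(sm$se_core_area_mm2))  # single interior region
})

test_that("physical areas are stable across imaging resolution", {
  regs <- lapply(c(5, 10), function(s) {
    spec <- small_scene_spec(seed = 11, field_width_mm = 8,
                             field_height_mm = 8, scale_um_per_px = s,
                             lenticel_frequency_per_mm2 = 0.4,
                             core_area_mean_mm2 = 0.12)
    segment_lenticels(generate_surface_scene(spec)$brightfield)
  })
  expect_equal(nrow(regs[[1]]), nrow(regs[[2]]))
  expect_lt(abs(mean(regs[[1]]$core_area_mm2) - mean(regs[[2]]$core_area_mm2)) /
              mean(regs[[2]]$core_area_mm2), 0.05)
})

test_that("infiltrated area recovers planted halos and scales with the halo multiple", {
  scene <- generate_surface_scene(small_scene_spec())
  reg <- segment_lenticels(scene$brightfield)
  infl <- infiltrated_area(scene$fluorescence, reg)
  idx <- match_truth(reg, scene$truth)
  truth_halo <- scene$truth$halo_area_mm2[idx]
  has <- !is.na(truth_halo)
  expect_lt(max(abs(infl[has] - truth_halo[has]) / truth_halo[has]), 0.05)
  expect_equal(infl[!has], rep(0, sum(!has)))  # no halo -> no signal
  # black fluorescence image -> all zero
  black <- calibrated_image(matrix(0, 100, 100), 20, "fluorescence")
  expect_equal(infiltrated_area(black, reg[1:3, ]), rep(0, 3))
  # doubling the halo multiple increases the mean infiltrated area
  s2 <- generate_surface_scene(small_scene_spec(halo_area_multiple = 2))
  s4 <- generate_surface_scene(small_scene_spec(halo_area_multiple = 4))
  r2 <- segment_lenticels(s2$brightfield); r4 <- segment_lenticels(s4$brightfield)
  expect_gt(mean(infiltrated_area(s4$fluorescence, r4)),
            mean(infiltrated_area(s2$fluorescence, r2)))
})

test_that("window summaries report means with sd/sqrt(n) standard errors", {
  reg <- data.frame(core_area_mm2 = c(0.4, 0.5, 0.6),
                    pore_area_mm2 = c(0.1, 0.1, 0.1),
                    border = c(FALSE, FALSE, FALSE), weight = c(1, 1, 1))
  sm <- summarize_window(reg, 100)
  expect_equal(sm$mean_core_area_mm2, 0.5)
  expect_equal(sm$se_core_area_mm2, sd(c(0.4, 0.5, 0.6)) / sqrt(3))
  expect_equal(sm$se_core_area_mm2, 0.0577, tolerance = 1e-3)
  expect_equal(sm$frequency_per_mm2, 0.03)
  # empty window
  sm0 <- summarize_window(reg[0, ], 100)
  expect_equal(sm0$n_lenticels, 0L)
  expect_equal(sm0$frequency_per_mm2, 0)
  expect_true(is.na(sm0$mean_core_area_mm2))
  expect_error(summarize_window(reg, -1), "positive")
})

test_that("calibrated images round-trip through TIFF with YAML sidecar", {
  img <- calibrated_image(matrix(runif(400), 20, 20), 12.5, "fluorescence")
  path <- file.path(withr::local_tempdir(), "img.tif")
  write_calibrated_tiff(img, path)
  back <- read_calibrated_tiff(path)
  expect_equal(back$scale_um_per_px, 12.5)
  expect_equal(back$channel, "fluorescence")
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 65535)  # 16-bit rounding
  expect_error(calibrated_image(matrix(1, 2, 2), -5), "positive")
})
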