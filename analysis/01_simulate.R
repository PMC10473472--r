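#!/usr/bin/env Rscript
# Generate the synthetic study inputs: three "cultivar" surface scenes
# spanning the observed density/core-area range, a developmental growth
# series, strain samples for skin discs with and without lenticels, and
# per-cultivar russet populations. Everything downstream (02-05) reads
# from results/simulated/.

library(mangolenticel)

seed <- 20260930L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cultivars <- data.frame(
  cultivar = c("sparse_large", "intermediate", "dense_small"),
  frequency_per_mm2 = c(0.05, 0.15, 0.33),   # sparse big-cored to dense small-cored
  core_area_mean_mm2 = c(0.50, 0.16, 0.05),
  russet_mean_pct = c(30, 5, 0.5),
  russet_sd_pct = c(10, 4, 1))
write.csv(cultivars, file.path(out, "cultivar_truth.csv"), row.names = FALSE)

for (i in seq_len(nrow(cultivars))) {
  spec <- scene_spec(field_width_mm = 20, field_height_mm = 20,
                     scale_um_per_px = 20,
                     lenticel_frequency_per_mm2 = cultivars$frequency_per_mm2[i],
                     core_area_mean_mm2 = cultivars$core_area_mean_mm2[i],
                     core_area_cv = 0.4, halo_fraction = 0.5,
                     halo_area_multiple = 3, seed = seed + i)
  scene <- generate_surface_scene(spec)
  write_scene(scene, out, stem = cultivars$cultivar[i])
  message(sprintf("%s: planted %d lenticels on a 20 x 20 mm field",
                  cultivars$cultivar[i], nrow(scene$truth)))
}

growth <- generate_growth_series(a_max = 370, k = 0.04, t_mid = 100,
                                 times = seq(20, 180, by = 10),
                                 noise_sd = 5, seed = seed)
write.csv(growth, file.path(out, "growth_series.csv"), row.names = FALSE)

strain <- rbind(
  generate_strain_samples(12.6, 28.1, cv = 0.05, n = 30, seed = seed,
                          has_lenticels = TRUE),
  generate_strain_samples(8.5, 15.8, cv = 0.05, n = 30, seed = seed + 1L,
                          has_lenticels = FALSE))
write.csv(strain, file.path(out, "strain_samples.csv"), row.names = FALSE)

russet <- do.call(rbind, lapply(seq_len(nrow(cultivars)), function(i) {
  pop <- generate_russet_population(cultivars$russet_mean_pct[i],
                                    cultivars$russet_sd_pct[i],
                                    n = 200, seed = seed + 10L + i)
  cbind(cultivar = cultivars$cultivar[i], pop)
}))
write.csv(russet, file.path(out, "russet_population.csv"), row.names = FALSE)

message("simulated inputs written to ", out)
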