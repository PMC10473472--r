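#!/usr/bin/env Rscript
# Fit the sigmoidal growth model to the simulated developmental series,
# derive the growth-rate curve, and scale the morphometry densities to
# whole-fruit lenticel counts at selected surface areas.

library(mangolenticel)

series <- read.csv("results/simulated/growth_series.csv")
fit <- fit_growth(series, family = "logistic")
print(fit)

rate <- growth_rate_curve(fit, seq(20, 180, by = 2))
write.csv(rate, "results/growth_rate_curve.csv", row.names = FALSE)
write.csv(data.frame(
  family = fit$family, a_max_cm2 = fit$a_max, k_per_d = fit$k,
  t_mid_dafb = fit$t_mid, peak_rate_cm2_per_d = fit$peak_rate_cm2_per_d,
  t_peak_dafb = fit$t_peak_dafb, residual_sd_cm2 = fit$residual_sd),
  "results/growth_fit.csv", row.names = FALSE)

# example caliper measurement and whole-fruit counts through development
a_example <- surface_area(120, 90, 90)
message(sprintf("example fruit (120 x 90 x 90 mm): surface area %.1f cm^2",
                a_example))
morpho <- read.csv("results/morphometry_summary.csv")
areas <- c(50, 150, 300)
counts <- outer(morpho$frequency_per_mm2, areas, lenticels_per_fruit)
dimnames(counts) <- list(morpho$cultivar, paste0("area_", areas, "_cm2"))
write.csv(as.data.frame(counts), "results/lenticels_per_fruit.csv")
message(sprintf("peak growth rate %.2f cm^2 d^-1 at %.0f DAFB",
                fit$peak_rate_cm2_per_d, fit$t_peak_dafb))
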