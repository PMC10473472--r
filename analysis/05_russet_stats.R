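#!/usr/bin/env Rscript
# Score the simulated russet populations, summarise severity per cultivar,
# and run the reporting statistics: ANOVA with Tukey letters on segmented
# core areas, and pore-vs-core correlation.

library(mangolenticel)

russet <- read.csv("results/simulated/russet_population.csv")
severity <- do.call(rbind, lapply(split(russet, russet$cultivar), function(d) {
  sv <- severity_summary(d)
  data.frame(cultivar = d$cultivar[1], n = sv$n, mean_score = sv$mean_score,
             se_score = sv$se_score, t(as.integer(sv$histogram)))
}))
names(severity)[grep("^X", names(severity))] <- paste0("n_score_", 0:4)
write.csv(severity, "results/russet_severity.csv", row.names = FALSE)
for (i in seq_len(nrow(severity)))
  message(sprintf("%s: mean russet score %.2f +/- %.2f (n = %d)",
                  severity$cultivar[i], severity$mean_score[i],
                  severity$se_score[i], severity$n[i]))

per_lent <- read.csv("results/morphometry_per_lenticel.csv")
interior <- per_lent[!per_lent$border, ]

letters_tbl <- anova_tukey_letters(interior$core_area_mm2, interior$cultivar)
write.csv(letters_tbl, "results/core_area_tukey_letters.csv", row.names = FALSE)
message("Tukey letters for core area by cultivar:")
for (i in seq_len(nrow(letters_tbl)))
  message(sprintf("  %s: %.3f +/- %.3f mm^2 %s", letters_tbl$group[i],
                  letters_tbl$mean[i], letters_tbl$se[i],
                  letters_tbl$letters[i]))

r2 <- pearson_r2(interior$core_area_mm2, interior$pore_area_mm2)
message(sprintf("pore vs core area: r^2 = %.2f %s (n = %d)",
                r2$r2, r2$stars, r2$n))
fitln <- linear_fit(interior$core_area_mm2, interior$pore_area_mm2)
write.csv(data.frame(r2 = r2$r2, stars = r2$stars, n = r2$n,
                     slope = fitln$slope, slope_se = fitln$slope_se,
                     intercept = fitln$intercept),
          "results/pore_core_correlation.csv", row.names = FALSE)
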