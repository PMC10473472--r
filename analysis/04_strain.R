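#!/usr/bin/env Rscript
# Apply the strain-relaxation calculus to the simulated skin-disc samples
# and compare discs with and without lenticels.

library(mangolenticel)

samples <- read.csv("results/simulated/strain_samples.csv")
per_sample <- compute_strains(samples)
write.csv(per_sample, "results/strain_per_sample.csv", row.names = FALSE)

cmp <- compare_groups(samples)
write.csv(cmp$by_group, "results/strain_group_summary.csv", row.names = FALSE)
bg <- cmp$by_group
for (g in seq_len(nrow(bg)))
  message(sprintf(
    "%s (n = %d): exc+iso %.1f +/- %.1f %%, extr %.1f +/- %.1f %%, total %.1f +/- %.1f %%",
    bg$group[g], bg$n[g],
    bg$mean_eps_exc_iso_pct[g], bg$se_eps_exc_iso_pct[g],
    bg$mean_eps_extr_pct[g], bg$se_eps_extr_pct[g],
    bg$mean_eps_tot_pct[g], bg$se_eps_tot_pct[g]))
message(sprintf("total-strain ratio with/without lenticels: %.2f",
                cmp$ratio_with_over_without["tot"]))
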