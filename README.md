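# mangolenticel

Quantitative workflow for studying **lenticels and russeting on mango
fruit skin**. Lenticels — unregulated pores that develop from ruptured
stomata and are underlain by a periderm — are focal points of
microcracking and russet formation on susceptible cultivars. Analysing
them quantitatively requires a chain of measurements: lenticel
morphometry on calibrated surface micrographs, fluorescent-tracer
infiltration around lenticels, whole-fruit growth geometry, the
strain-relaxation calculus for excised skin discs, ordinal russet
severity scoring, and the reporting statistics that tie them together.
This package implements that chain for researchers in fruit-surface
physiology, together with a synthetic-data generator that produces every
input with known ground truth, so the entire pipeline is testable end to
end without any field data.

## What it computes

**Lenticel morphometry.** Calibrated bright-field images are segmented by
a reproducible automatic chain (Otsu threshold on inverted intensity,
hole filling, connected-component labelling, area filter). Each lenticel
reports its *core* area (the region of loosely packed cells) and *pore*
area (the opening inside it); window summaries give the lenticel
frequency (count per mm², with border regions half-weighted) and
means ± SE. Tracer-infiltrated area per lenticel is measured on the
registered fluorescence channel.

**Growth geometry.** Fruit surface area from three caliper dimensions,
assuming sphericity via the geometric-mean diameter:

    A = π [(L · d₁ · d₂)^(1/3)]²   (mm → cm²)

A 3-parameter logistic A_max / (1 + e^(−k(t − t_mid))) (or Gompertz) is
fitted to area vs. time (days after full bloom, DAFB); the growth-rate
curve is its analytic first derivative, with peak rate A_max·k/4 at
t_mid for the logistic. Whole-fruit lenticel counts are frequency ×
surface area.

**Strain relaxation.** Excising an epidermal segment (area A, the punch
cross-section), enzymatically isolating the cuticular membrane (A_CM)
and extracting its waxes (dewaxed membrane, A_DCM) successively release
in-plane strain. All apparent strains are referenced to the fully
relaxed area:

    ε′_exc+iso = (A − A_CM) / A_DCM × 100
    ε′_extr    = (A_CM − A_DCM) / A_DCM × 100
    ε′_tot     = ε′_exc+iso + ε′_extr      (exactly additive)

A_DCM can be reconstructed from a square four-hole pattern punched before
extraction (the disc rim curls after dewaxing): A_DCM = A_CM ×
holes_DCM/holes_CM. Per-lenticel core strain uses the same form on core
areas before/after wax extraction.

**Russet scoring.** Russeted surface fraction → ordinal score: 0 ↔ 0%,
1 ↔ (0,10]%, 2 ↔ (10,25]%, 3 ↔ (25,50]%, 4 ↔ (50,100]%; populations are
summarised as mean score ± SE with a score histogram.

**Statistics.** Pearson r² with significance stars, OLS regression,
one-way ANOVA with Tukey studentized-range compact-letter displays
(insert-and-absorb), and paired treatment/control summaries for
moisture-exposure experiments.

## Worked example

```r
library(mangolenticel)

# strain relaxation of skin discs with vs. without lenticels
samples <- rbind(
  generate_strain_samples(12.6, 28.1, cv = 0.05, n = 30, seed = 20260930,
                          has_lenticels = TRUE),
  generate_strain_samples(8.5, 15.8, cv = 0.05, n = 30, seed = 20260931,
                          has_lenticels = FALSE))
cmp <- compare_groups(samples)
```

prints, via `analysis/04_strain.R`:

```
with_lenticels (n = 30): exc+iso 12.6 +/- 0.1 %, extr 28.2 +/- 0.2 %, total 40.8 +/- 0.3 %
without_lenticels (n = 30): exc+iso 8.5 +/- 0.1 %, extr 15.8 +/- 0.1 %, total 24.3 +/- 0.1 %
total-strain ratio with/without lenticels: 1.68
```

i.e. discs containing lenticels release about 1.7× more total strain —
lenticels act as stress concentrators in the skin. A growth fit on a
simulated developmental series:

```r
fit <- fit_growth(generate_growth_series(370, 0.04, 100, seq(20, 180, 10),
                                         noise_sd = 5, seed = 20260930))
print(fit)
#> <growth_fit> logistic: a_max = 377.8 cm^2, k = 0.03889 d^-1, t_mid = 102.1 DAFB
#>   peak growth rate 3.674 cm^2 d^-1 at 102.1 DAFB (residual sd 7.28)
```

The surface expands fastest (≈3.7 cm² d⁻¹) around 100 DAFB — the
developmental window in which lenticels are observed to rupture.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write their tables to `results/`:

1. `01_simulate.R` — scenes for three synthetic "cultivars" (density
   0.05/0.15/0.33 mm⁻², core areas 0.50/0.16/0.05 mm²), growth series,
   strain samples, russet populations
2. `02_morphometry.R` — segmentation, frequency/core/pore/infiltration
   estimates vs. planted truth
3. `03_growth.R` — sigmoid fit, rate curve, lenticels per fruit
4. `04_strain.R` — strain calculus and group comparison
5. `05_russet_stats.R` — severity scoring, Tukey letters, correlations

`run_pipeline(default_config(seed))` chains the same stages
programmatically into a single reproducible run directory.

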