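---
title: "Methods: lenticel morphometry, growth geometry and strain relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lenticel morphometry, growth geometry and strain relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangolenticel)
```

This vignette documents the models, parameter choices and numerical
decisions behind the package, in the spirit of a methods section: what
each stage assumes, where the defaults come from, and what the synthetic
generator does and does not emulate.

## The measurement problem

Lenticels on mango skin are pore-like structures that develop from
stomata: a *core* of loosely packed cells containing an open *pore*.
They matter because skin strain concentrates at them; when the strain
limit is exceeded they crack, a wound periderm forms, and russeting
spreads from there. Quantifying this requires five linked measurements:
per-lenticel morphometry on calibrated micrographs, tracer infiltration
as a microcracking index, whole-fruit growth to know the strain driver,
direct strain-relaxation assays on excised skin, and an ordinal severity
score for russet itself.

## Synthetic scenes as ground truth

No raw micrographs ship with the package, so correctness of the image
chain is defined against a generative model (`scene_spec()`,
`generate_surface_scene()`) rather than against manually annotated
images:

* **Core areas** are lognormal — areas are positive and right-skewed —
  parameterised by mean and CV (default CV 0.4, a typical biological
  spread). Cultivar-scale defaults span the observed range: sparse skins
  with large cores (0.05 mm⁻², 0.50 mm²) to dense skins with small cores
  (0.33 mm⁻², 0.05 mm²).
* **Shapes**: cores are filled ellipses with aspect ratio drawn
  uniformly on [1, 2] and random orientation. Lenticel shape statistics
  are not established for this system; the aspect range is a free
  modelling choice, kept modest so that an equivalent-ellipse area
  description stays meaningful.
* **Pores** are concentric darker ellipses occupying a Beta-distributed
  fraction of the core (mean 0.3, concentration 30), guaranteeing
  pore < core per lenticel.
* **Halos** (tracer infiltration) are soft-edged discs in the registered
  fluorescence channel, area a fixed multiple of the core area, assigned
  to a configurable fraction of lenticels. The Gaussian edge
  (sd 1.5 px) is positioned so the half-maximum contour lies exactly at
  the nominal halo radius; thresholding anywhere near mid-intensity then
  recovers the planted area, which keeps the area semantics of the
  ground truth independent of the exact threshold.
* **Placement** is uniform rejection sampling with a hard non-overlap
  constraint (bounded retries, then a "field too crowded" error); the
  full rendered extent of each lenticel is kept inside the field so that
  planted counts are exact.
* **Noise** is additive Gaussian per pixel (default sd 0.01 of the
  dynamic range), clipped to [0, 1].

What this does *not* emulate: real skin texture, wax glare, uneven
illumination, touching or ruptured lenticels, and partial-volume edges.
Passing the truth-recovery tests therefore demonstrates that the
measurement chain is unbiased under its own generative assumptions — not
that segmentation of difficult field micrographs is solved. The
interactive-measurement step used in practice is replaced here by a
deterministic, reviewable operator chain.

## Segmentation choices

`segment_lenticels()` inverts the bright-field image, applies a global
Otsu threshold, fills holes, labels connected components and filters by
area (defaults 0.005–5 mm², bracketing the smallest pores and largest
cores of interest). Two guards matter in practice:

* **Blank fields.** Otsu always returns a split, so a signal-free noisy
  image would be cut at its noise mean into thousands of speckle
  components. A minimum foreground–background contrast (default 0.1 of
  the dynamic range) declares such images object-free.
* **Pore resolution.** The pore is found by a second Otsu split within
  each core, again guarded by a minimum within-core contrast (0.15); a
  pore-free core reports 0 rather than a noise split.

Regions touching the window border are excluded from per-lenticel area
statistics but counted ½ toward the frequency — an unbiased counting
rule for finite windows, needed because measurement windows in practice
range over an order of magnitude in size. Infiltrated area attributes
each thresholded fluorescent component to the lenticel whose footprint
it contains or touches; a component claimed by several lenticels is
split by nearest-centroid assignment, so no area is counted twice. The
measured infiltration includes the lenticel core itself (the tracer
penetrates the core as well as the surrounding microcracks); this is a
documented, configurable convention rather than a physical claim.

## Growth model

Surface area from length and two orthogonal equatorial diameters uses
the geometric-mean-diameter sphere, `A = π ((L d₁ d₂)^{1/3})²`. This is
the standard operationalisation of "assuming sphericity" for
near-spheroid fruit, and is the kind of calculation that tracks peel
area closely in practice.

The sigmoid family is a 3-parameter logistic by default: it has a
closed-form derivative and peak (`a_max k/4` at `t_mid`), which makes
the growth-rate curve and its maximum exact rather than numerically
differentiated. A Gompertz alternative (peak `a_max k/e`) sits behind
`family = "gompertz"` for asymmetric series. Initialisation is
deterministic and data-driven (`a_max ← 1.05 max(area)`, `t_mid` at the
interpolated half-maximum, `k ← 4 max(slope)/a_max`), so a given series
always produces the same fit; optimisation is Levenberg–Marquardt
(`minpack.lm::nlsLM`, up to 200 iterations), with non-convergence
reported as an error naming the family. Simulated recovery at
measurement noise (sd 5 cm², 17 dates, 200 seeds in the test suite)
shows the estimates unbiased within simulation error.

## Strain calculus

The three apparent strains use the fully relaxed (dewaxed) area as the
common denominator. That choice is deliberate and load-bearing: with a
common denominator the two components are *exactly* additive, which the
package treats as a tested invariant (to 1e-12 relative over 10⁵ random
samples), not documentation. Implementations that "correct" the first
component's denominator to A_CM break this identity. Negative strains
(apparent swelling) are returned and flagged, never clamped — clamping
would bias group means. The excised-segment area A is taken from the
nominal 8 mm biopsy punch unless measured per sample. When
square-hole-pattern areas are present they are preferred over a directly
traced DCM outline, because the disc rim curls after wax extraction;
the reconstruction is a pure ratio, `A_DCM = A_CM · holes_DCM/holes_CM`.

The strain-sample generator works backwards from target component
strains to the area quintet, so at `cv = 0` the calculus recovers the
targets exactly; its noise model jitters the per-sample components
multiplicatively, which keeps sample means centred on the truth.

## Russet scoring

The printed integer bins (0; 1–10; 11–25; 26–50; 51–100 % of surface
russeted) are extended to the continuum as half-open intervals
(0, 10], (10, 25], (25, 50], (50, 100], preserving every printed
boundary while covering all fractions exactly once. Fractions strictly
between 0 and 1 % score 1: any visible russet yields a nonzero score.
Population summaries use the arithmetic mean of the ordinal scores with
SE — a pragmatic field convention that the package follows rather than
endorses; the score histogram is always reported alongside.

## Reporting statistics

Compact letters for Tukey's studentized-range test are produced by the
insert-and-absorb algorithm on the pairwise significance matrix from
`stats::TukeyHSD`, with letters assigned in ascending-mean order from
"a"; the partition is cross-checked against `multcomp::cld` in the test
suite on clearly separated group patterns (borderline pairs can
legitimately differ between p-value adjustments, which is a property of
the adjustments, not of the letter assignment). Degenerate within-group
variance collapses to a shared letter with a warning. Correlation stars
follow the */**/*** convention at 0.05/0.01/0.001. Paired summaries
(moisture-exposed patch vs. the untreated opposite cheek of the same
fruit) report per-time treatment and control means and the within-pair
difference, erroring on any incomplete pair by name; no inferential
claim is attached to the paired difference beyond its SE.

## Problem sizes and reproducibility

The defaults used by the analysis scripts and tests are chosen as a
desk-scale version of a field study: 20 × 20 mm (scripts) or up to
30 × 30 mm (truth-recovery tests) fields at 20 µm px⁻¹, 30 skin discs
per strain group, 200 fruit per russet population, 17 sampling dates for
growth, 200 simulation seeds for recovery checks. Every stochastic
routine takes an explicit integer seed and restores the caller's RNG
state (`withr::with_seed`), and `run_pipeline()` derives per-stage seeds
from one master seed, so identical configuration reproduces every output
byte for byte.

## Known limitations

* Segmentation correctness is defined against the generator, not against
  annotated field micrographs; transfer to real images will require
  illumination correction and possibly local thresholding.
* Core *depth* (a cross-section quantity) is carried as an optional
  recorded field only; it is never computed from surface images.
* The generator plants lenticels that never overlap or touch the field
  border; clumped or truncated lenticels are out of its scope, and the
  border-weighting rule is exercised on constructed rasters instead.
* Mean-of-ordinal-score summaries are reported for comparability with
  field practice; they are not an interval-scale claim.
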