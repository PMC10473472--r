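Package: mangolenticel
Title: Lenticel Morphometry, Growth Geometry and Russet Scoring for Mango Fruit Skin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for studying lenticel development and
    russeting on mango fruit surfaces. Detects lenticels on calibrated
    bright-field micrographs and measures their frequency, core and pore
    areas; quantifies fluorescent-tracer infiltration around lenticels;
    computes fruit surface area from caliper dimensions, fits sigmoidal
    growth models and derives growth-rate curves; implements the
    strain-relaxation calculus for excised skin discs, isolated cuticular
    membranes and dewaxed membranes; maps russeted-area fractions to an
    ordinal 0-4 severity score; and provides the reporting statistics
    (regression, correlation with significance stars, one-way ANOVA with
    Tukey compact-letter displays, paired treatment/control summaries).
    A synthetic-data generator produces calibrated surface scenes, growth
    series, strain samples and russet populations with known ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
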