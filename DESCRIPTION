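Package: germaquant
Title: Quantitative 3D Analysis of Follicle Precursor Cell Fates in the
    Drosophila Germarium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-nucleus quantification of cell-fate markers and signalling
    reporters in 3D confocal stacks of germarium-like tissue. Implements
    two-pass nuclear spot detection (coarse 2.5 um spots refined to 1.75 um
    cores), canonical two-step rotation onto the anterior-posterior axis,
    background subtraction with depth-bias quality control, three
    normalization modes (per-sample maximum, internal-control mean, and
    one-phase-decay gradient prediction), Eya/Cas co-expression state
    classification, and a variance-gated statistical decision tree
    (F-test-gated t vs Mann-Whitney, Brown-Forsythe-gated ANOVA with Tukey
    vs Kruskal-Wallis with Dunn, Fisher's exact test on clone-composition
    tables). A seeded synthetic germarium phantom generator with full
    ground truth makes every pipeline stage testable without external
    image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    minpack.lm,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
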