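Package: casaR
Title: Computer-Assisted Sperm Motility Analysis from High-Speed Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies Drosophila sperm flagellar motility from high-speed
    grayscale video: zero-crossing beat frequency from pixel-intensity time
    series at measurement points, calibrated tail beat speed from kymograph
    peak tracking, and a whole-field intensity index (mean absolute lagged
    pixel brightness difference normalised by bit depth). Includes a
    deterministic synthetic beating-flagellum video generator with analytic
    ground truth for estimator validation, multi-page TIFF / PNG stack I/O
    with plain-text calibration sidecars, and the accompanying nonparametric
    statistical battery: exact Wilcoxon-Mann-Whitney tests from the
    combinatorial null distribution of U, tie-corrected Kruskal-Wallis,
    Dunn's post hoc comparisons with a compact letter display, Bonferroni and
    Holm (sequential Bonferroni) corrections, chi-square contingency tests,
    and sperm-storage retention and fertilisation-proportion arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
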