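Package: pistack
Title: Pi-Stacking Complexation Analysis for Methylxanthine Solubilization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studying how aromatic complexing agents
    (polyphenolate and related salts) solubilize methylxanthines such as
    caffeine via pi-stacking complexation rather than classical hydrotropy.
    Provides quantitative 1H NMR molality calculation against the water
    internal reference, solubility-increase factors, discrimination of
    linear (complexation-like) versus minimum-hydrotropic-concentration
    solubility curves, ROESY cross-peak normalization and homo- versus
    hetero-association classification, and geometric trajectory metrics for
    periodic molecular configurations: neighbor censuses, axial
    stacking-configuration distributions, bias-corrected per-agent
    efficiencies and fibril/aggregate detection. A synthetic-configuration
    generator builds stacked fibrils with known ground truth so every
    analysis stage is testable without external trajectories or spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
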