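Package: digitalSERS
Title: Digital Single-Molecule Nanopillar SERS Assay Simulation and Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for digital single-molecule immunoassays read out by
    surface-enhanced Raman scattering (SERS) mapping of nanopillar arrays.
    Implements the Poisson occupancy mathematics of digital counting
    (molecule-number arithmetic, occupancy probabilities, saturation-corrected
    concentration estimates with exact binomial intervals), a seeded simulator
    of pillar-array loading, nanotag labelling and confocal hyperspectral map
    rendering, the counting pipeline (spectral band filters with polynomial
    baseline subtraction, silicon-channel pillar registration, threshold
    spot-calling, multi-image aggregation), log-log calibration with inverse
    prediction and recovery statistics, and longitudinal biomarker-panel
    analysis (Kruskal-Wallis with Dunn's post-hoc comparisons and Fisher
    linear discriminant projection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
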