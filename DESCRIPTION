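Package: hdlfibril
Title: Quantitative Analysis of HDL Particle Morphology, Amyloid Fibril
    Order, and Blood-Brain-Barrier Transport Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative readouts used when studying how the
    lipidation state of apolipoprotein A-I (HDL subclasses) modulates
    beta-amyloid fibrils and their transport across an in vitro blood-brain
    barrier. Includes AFM height-map analytics (plane leveling, fixed-height
    threshold pixel fractions, fibrillation time courses, sphere/disc particle
    height-distribution models and fits), structural-order metrics on fibril
    coordinate models (inter-chain order parameter, Kabsch superposition and
    RMSD, essential-dynamics PCA, Calpha-based secondary-structure assignment,
    solvent-accessible interface area), transwell apparent-permeability and
    percent-passage estimation, thioflavin-T kinetic summaries, and the
    accompanying inferential statistics (one-way ANOVA with Tukey HSD,
    one-tailed Student's t). Every input can be simulated with known ground
    truth by the built-in generators, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
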