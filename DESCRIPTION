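Package: npamyloid
Title: Nanoparticle Modulation of Amyloid Aggregation: Simulation and
    Kinetic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how surface-functionalised gold
    nanoparticles modulate amyloid-beta fibrillation. Provides a
    coarse-grained Metropolis Monte Carlo simulator of bead-chain peptides
    aggregating through inter-chain hydrogen bonds in a periodic box
    containing fixed spherical nanoparticles, with a surface-area-matched
    nanoparticle size sweep; sigmoidal fitting of thioflavin-T
    fibrillation kinetics with lag time, half-time and apparent rate;
    one-site binding analysis of isothermal titration calorimetry
    thermograms with derived Gibbs energy and entropy; first-order
    plasma-elimination fitting with half-life; and seeded synthetic-data
    generators for every stage so the full pipeline runs without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
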