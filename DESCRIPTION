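Package: nucshuttle
Title: Nucleocytoplasmic Transport Kinetics and Polyprotein Unfolding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery for studying mechanoselective protein
    import across the nuclear pore complex. Fits a two-compartment
    import/export model to single-cell optogenetic (LEXY-style) recovery
    curves, applies a semi-automatic three-step cell filtering protocol
    (iterative extreme studentized deviate outlier removal, activation-phase
    quality control and manual rejection lists), simulates and analyses
    force-clamp polyprotein unfolding trajectories under stochastic and
    sequential kinetic models, converts single-molecule step sizes with
    freely-jointed-chain and worm-like-chain polymer elasticity, and derives
    cross-construct mechanoselectivity statistics (mass law, relative
    acceleration, directionality ratios and a transport free-energy
    surface). A synthetic-data module generates single-cell fluorescence
    time courses and unfolding trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
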