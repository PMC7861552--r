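Package: mitoalternans
Title: Stochastic Spatiotemporal Myocyte Model of Mitochondria-Driven
    Calcium Alternans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic spatiotemporal rabbit ventricular myocyte model
    coupling a three-dimensional lattice of calcium release units (CRUs) to a
    lattice of mitochondria. RyR and L-type channel gating are simulated as
    Markov chains, the mitochondrial permeability transition pore (mPTP) as a
    three-state channel whose opening depolarizes the mitochondrion, halts ATP
    production and elevates ROS emission. ROS, oxidized CaMKII activation and
    the ATP/ADP pool feed back on RyR opening and SERCA uptake. Includes the
    pacing, clamping and parameter-scan protocols used to study how
    mitochondrial depolarization promotes calcium alternans, plus alternans
    quantification and bifurcation analysis utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
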