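Package: braidmet
Title: Stoichiometric Modelling of Braided Microbial Community Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing microbial community metabolism in
    oxygen-pulsed ('tidal') chemostats. Represents compounds and
    element-balanced catabolic/anabolic half-reactions, predicts biomass
    yields from a Gibbs-energy-dissipation correlation combined with
    respiratory-chain proton-translocation efficiencies, and fits
    non-negative reaction rates of a communal metabolic network to observed
    substrate conversions by weighted non-negative least squares. Includes
    calculators for diffusion-limited oxygen uptake by single cells and
    microaggregates, bioenergetic efficiency of respiratory chains at a
    given proton motive force, per-ORF transcriptional activity and
    single-copy-gene (rpoBC) normalization of functional gene counts, and a
    seeded synthetic-data generator (chemostat tidal-cycle ODE simulator,
    conversion vectors from known rates, multinomial read-count tables) so
    that every stage can be tested with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
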