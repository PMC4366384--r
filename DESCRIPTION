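Package: fgf21pkpd
Title: Species-Resolved PK/PD Modeling of a Two-Armed Antibody-FGF21 Conjugate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pharmacokinetic and pharmacodynamic models for a long-acting
    antibody-FGF21 conjugate whose two FGF21 arms are cleaved at different
    rates at the C- and N-terminus.  Provides non-compartmental analysis
    (log-linear trapezoidal AUC, terminal half-life, clearance, distribution
    volumes, bioavailability), a combinatorial 16-species cleavage-network PK
    model for ob/ob mice, a simplified depot/central/adipose PK model for
    diet-induced obese mice, an equilibrium receptor-occupancy solver for two
    ligand pools competing for one receptor complex, a convolution model for
    the oral glucose tolerance test response, an energy-balance body-weight
    model with an overfeeding response and an adipose thermogenesis term, and
    seeded synthetic-data generators so that every stage of the analysis is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
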