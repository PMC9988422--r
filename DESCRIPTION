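Package: bbbench
Title: Benchmarking Transwell Blood-Brain Barrier Models from Bidirectional
    Permeability Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for benchmarking in vitro blood-brain barrier
    (BBB) microphysiological systems built on transwell inserts. Estimates
    permeability coefficients (Pe) from donor/receiver concentration
    timecourses by the cleared-volume slope method with blank-membrane
    correction, computes trans-endothelial electrical resistance (TEER),
    derives efflux ratios from bidirectional transport assays with Student's
    t-test significance marking, tests receptor-mediated transcytosis by
    dose saturation and competition assays, assembles a benchmark scorecard
    over tight-junction and transporter criteria, and compares efflux results
    between facilities. A forward simulator of two-compartment transwell
    kinetics (passive diffusion, polarized efflux, saturable transport,
    measurement noise) supplies ground-truthed synthetic assays so the whole
    pipeline runs and is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
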