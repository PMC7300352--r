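Package: oriseg
Title: Entropy-Driven Bacterial Chromosome Segregation: Bead-Spring
    Simulation and Origin-Tracking Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Langevin-dynamics simulation of a replicating, cylindrically
    confined bacterial chromosome represented as a bead-spring ring polymer,
    with replication implemented either at a fixed midcell factory or by
    forks tracking along the chromosome, together with an analysis pipeline
    for fluorescence time-lapse tracks of replication-origin foci: pairing of
    origin foci, principal-axis separation series, lag-displacement curves,
    step-size distributions, and ensemble segregation statistics. Includes a
    synthetic-track generator emulating microscopy data so the experimental
    pipeline is fully testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
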