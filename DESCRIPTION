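Package: mirloops
Title: Signed TF-miRNA Regulatory Networks, Composite Loop Motifs, and
    Circuit Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assembling signed, mechanism-tagged transcription
    factor and microRNA regulatory networks from edge tables (TSV, SIF,
    GraphML), extracting focal (ego) subnetworks, integrating validated
    miRNA-target interactions, and enumerating and sign-classifying
    miRNA-mediated feedforward and feedback loop motifs.  Includes
    Hill-kinetics ordinary differential equation models of the circuits
    such motifs form around the melanocyte master regulators SOX10 and
    MITF: graded input-function analysis under a phenotype rheostat map,
    AND/OR-gate feedforward loops with sign-sensitive delay and
    transient-pulse rejection, miRNA-accelerated clearance of leaky
    transcripts, and positive-feedback toggle switches with saddle-node
    bifurcation, hysteresis, and reversibility analysis.  Synthetic
    network generators with planted, ground-truth motifs make the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
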