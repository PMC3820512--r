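Package: tempoflow
Title: Temporally Constrained Minimum-Cost Flow Inference of Active Gene
    Sub-Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers active gene sub-networks from three-stage time-course
    expression data laid over a reliability-scored molecular interaction
    network. Stage-labelled genes (initial responders, intermediate
    regulators, late effectors) are wired to auxiliary source and sink
    terminals and connected by a minimum-cost network flow whose capacities
    track fold change and abundance and whose costs track interaction
    reliability, with a constraint forcing every unit of flow through at
    least one intermediate regulator. Includes a non-temporal ResponseNet
    baseline, randomization-based per-gene significance, alternate-optima
    stability bounds, knockout analysis, hop-capped flow-weighted shortest
    paths, and a seeded synthetic fixture generator with planted cascades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
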