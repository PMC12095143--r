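Package: dosenet
Title: Dosage-Weighted Network Pharmacology for Multi-Herb Prescriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds paired non-dosage and dosage-weighted
    drug-metabolite-target networks for multi-herb prescriptions.
    Converts historical Chinese mass units (Fen, Qian, Liang) to grams,
    standardizes dosages to ratio vectors, predicts key and drug targets
    by weighted degree centrality, runs hypergeometric pathway
    over-representation, and quantifies input and output differences
    between the two network variants with the indicators Dedis, DeSD,
    DeDT and DePy. Ships a reproducible synthetic-data generator, batch
    statistics for prescription ensembles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
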