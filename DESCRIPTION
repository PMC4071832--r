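Package: photolim
Title: Drought-Recovery Photosynthesis Limitation Analysis and Causal Path Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing leaf gas-exchange and chlorophyll-fluorescence
    records from drought and rewatering experiments. Estimates mesophyll
    conductance by the variable-J method with Harley reliability filtering,
    partitions photosynthesis limitations into stomatal, mesophyll and
    biochemical components against same-day well-watered references, computes
    soil relative extractable water and leaf relative water content, quantifies
    relative gene expression from qPCR plates by the relative standard curve
    method, and tests user-specified causal models (directed acyclic graphs)
    over physiological and expression variables by d-separation with Fisher's C.
    Includes a forward Farquhar-von Caemmerer-Berry leaf simulator and a
    synthetic drought-recovery study generator with known ground truth for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
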