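Package: emanet
Title: Dynamic Network Analysis of Ecological Momentary Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control dynamic network analysis for intensive longitudinal
    (ecological momentary assessment, EMA) data. Simulates EMA panels from
    structural vector-autoregressive models with planted contemporaneous and
    lagged structure, pools per-subject series, estimates signed
    partial-correlation networks with PC-style condition selection and
    momentary-conditional-independence testing, compares groups with a
    network goodness-of-fit R-squared and density statistics, and enumerates
    and classifies signed feedback loops (positive/negative feedback, likely
    adaptive/maladaptive, context-involving). Includes augmented
    Dickey-Fuller stationarity checks, Table-1-style group descriptives, and
    an end-to-end seeded pipeline.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
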