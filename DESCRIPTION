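Package: mtcea
Title: Markov Cohort Cost-Effectiveness Analysis of Specialised Manual Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-based health-economic evaluation of specialised manual
    therapy versus standard orthopaedic care for non-surgical musculoskeletal
    disorders. Classifies long-term follow-up records into recovered and
    non-recovered states under a health-care perspective, estimates state
    utilities, per-cycle costs and transition probabilities from panel counts,
    runs a two-state three-month-cycle Markov cohort model over 96 months with
    discounting, and derives incremental QALYs, incremental costs, the ICER or
    a dominance verdict, model validation against observed recovery, and a
    two-standard-deviation cost outlier sensitivity analysis. Includes a
    synthetic two-arm trial generator for ground-truth testing and packaged
    transcriptions of the trial's aggregate utility and cost tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
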