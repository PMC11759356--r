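Package: boldnet
Title: Latent-Input Network Modeling of fMRI BOLD Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Effective-connectivity analysis of regional fMRI BOLD time
    series with a directed linear signaling model driven by latent inputs
    (structural and physiological modeling, SAPM). Provides the forward
    model and fitting engine estimating input weightings (D), conversion
    factors (B) and their products (DB, the reported connectivity
    statistic); significance calibration against null simulations with
    family-wise error control; k-means partitioning of regions into
    sub-regions and a greedy search for the sub-region combination that
    best fits the network; extraction of bespoke BOLD features such as
    the pre-stimulus initial rise; group-level ANCOVA and correlation
    statistics; and pupillometry summaries. A fully seeded synthetic-data
    generator emulates the threat/safety noxious-stimulation paradigm so
    every stage is testable without imaging data.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    mclust,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
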