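Package: avoidr
Title: Scoring and Inference for Nematode Chemosensory Avoidance Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Caenorhabditis elegans repellent-avoidance
    experiments. Scores phasmid (tail) dry-drop assays with normalized
    backing-time response indices, amphid (head) assays as response
    proportions, and chemotaxis plates by chemotaxis index; performs the
    accompanying inference (two-proportion z-tests, pooled t-tests, one-way
    ANOVA with Tukey HSD, Hochberg step-up adjustment, Cohen's d, and
    power-based sample-size calculations). Also implements a GCaMP calcium
    imaging pipeline (percent change in fluorescence against a pre-stimulus
    baseline, buffer-control subtraction, stimulus-window area under the
    curve) and extracted-ion-chromatogram quantification of derivatized
    fatty acids from centroided LC-MS runs (monoisotopic mass calculation,
    ppm-window extraction, trapezoidal peak integration). A synthetic-data
    generator emulates every input modality so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
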