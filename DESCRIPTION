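Package: herdsense
Title: Collar-Accelerometer Behavior Classification for Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies dairy-cow behavior (standing, lying, ruminating,
    eating, drinking, walking, other) from 25 Hz triaxial neck-collar
    accelerometer streams. Implements 10-minute windowing, a 23-feature
    sub-window statistics stage with correlation-based feature reduction,
    class-pair and lumped-class labeling of observation windows, five
    decision-tree classifiers over nested class sets, a weighted
    class-containment combined classifier, and time-budget evaluation.
    Includes a synthetic decorated-stream generator with per-behavior
    postural and spectral signatures so the full pipeline can be exercised
    without farm recordings.
License: MIT
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
    rpart,
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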