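Package: aquafis
Title: Hierarchical Mamdani Fuzzy Inference for Drinking-Water Quality
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scores drinking-water samples with a hierarchical Mamdani fuzzy
    inference system: three 3-input, 27-rule sub-models (alkalinity/pH/hardness,
    Ca/Mg/Fe, sulfate/nitrate/fluoride) feed a final water-quality model on a
    seven-class 0-100 scale. Implements triangular membership functions with
    shoulder conventions, min implication, max aggregation, and five
    defuzzifiers (centroid, bisector, mean/smallest/largest of maximum), plus a
    deterministic water-quality index with analytic-hierarchy-process (AHP)
    weighting for cross-validation. Includes a seeded synthetic-sample
    generator, YAML model configuration, CSV batch scoring, sensitivity
    surfaces, ggplot2 visualisations, and a command-line interface.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
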