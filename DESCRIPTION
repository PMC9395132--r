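Package: melaxis
Title: Mapping Melanoma Phenotypic Heterogeneity onto the EMT Axis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-sample transcriptomic scoring engines (ssGSEA, signed
    Kolmogorov-Smirnov EMT score, 76-gene epithelial signature score,
    singscore, fatty-acid-oxidation z-mean) together with the inference
    stages used to map the melanoma proliferative-invasive
    (de-differentiation) axis onto epithelial-mesenchymal and metabolic
    programs: Spearman correlation meta-analysis with volcano summaries,
    moving-window gradient estimation, top-10 percent phenotype assignment,
    one-proportion Z tests for conditional phenotype enrichment, and
    non-monotonicity detection. Includes a synthetic expression-program
    simulator with ground truth so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
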