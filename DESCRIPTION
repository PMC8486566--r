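Package: cfmeth
Title: Co-Methylated Read Analysis of Cell-Free DNA for Colorectal
    Cancer Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a read-level methylation analysis pipeline for
    targeted bisulfite sequencing of tissue and plasma cell-free DNA.
    Computes the percentage of co-methylated reads (PCM) per region and
    sample from epiread-style input, discovers colorectal-cancer-specific
    hypermethylation markers in a tissue cohort (rank-sum tests with
    Benjamini-Hochberg correction, effect-size and trend-concordance
    filters), refines markers in plasma, fits an L1-penalised logistic
    risk model with cross-validated lambda selection and a Youden-index
    operating threshold, and evaluates diagnostic performance (DeLong
    confidence intervals, stage and adenoma subgroup reports, scalar
    tumor-marker comparison). A synthetic cohort generator with planted
    markers and stage-dependent circulating-tumor-DNA fractions provides
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
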