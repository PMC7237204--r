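Package: seqcorrect
Title: Sequential Multiple-Comparison Correction for Dataset Reuse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and applying significance-threshold
    corrections when hypothesis tests accumulate sequentially on a reused
    dataset. Implements the alpha-debt, alpha-spending and alpha-investing
    sequential procedures alongside uncorrected testing and the
    simultaneous Bonferroni and Benjamini-Hochberg baselines; Monte-Carlo
    experiments measuring familywise error under a global null and
    true/false discovery trade-offs when true effects are ordered within
    the test sequence; and a mass-univariate pipeline that fits one linear
    model per outcome and combines sequential threshold derivation with
    within-model false-discovery-rate correction. Includes a synthetic
    study generator emulating large subjects-by-variables tables with
    planted effects and missing values.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    yaml
Config/testthat/edition: 3
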