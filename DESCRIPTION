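Package: fhtriage
Title: Variant Triage, Penetrance and Carrier Association Analysis for
    Familial Hypercholesterolemia Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based final classification of LDLR/APOB/PCSK9 variants from
    pre-computed annotations (ClinVar assertion and review status, an
    InterVar-style interpretation, and an in-silico predictor consensus),
    carrier assignment with cohort exclusion rules, per-gene penetrance with
    pre-treatment LDL-C back-correction, Dutch Lipid Clinic Network scoring,
    and carrier versus non-carrier association statistics (Fisher exact,
    Mann-Whitney, covariate-adjusted logistic odds ratios). Includes a
    synthetic-cohort generator with known ground truth and deterministic
    fixtures constrained to published table marginals, so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
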