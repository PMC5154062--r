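Package: ifnstab
Title: Interferon Score Computation and Split-Half Stability Screening for
    Clinical Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes a composite peripheral-blood interferon (IFN) score from
    a panel of interferon response genes quantified by real-time PCR (standard
    curve method, reference-gene normalized, log2 scale), screens the score
    against continuous and dichotomous clinical variables with Spearman and
    Mann-Whitney tests, applies Benjamini-Hochberg multiple-testing correction
    in two dialects, and internally cross-validates every association by
    repeatedly randomizing the cohort into two equally sized halves and
    counting how often significance replicates in both, one, or neither half.
    Includes a synthetic cohort generator emulating an established rheumatoid
    arthritis population (correlated gene panel via a common-factor model,
    clinical marginals, additive treatment-linked suppression of the score)
    so that every stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
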