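Package: antherm
Title: Thermal Tolerance and Comparative Heat-Stress Transcriptomics in Ants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of heat tolerance and transcriptomic
    heat-shock responses across ant species. Estimates median lethal
    temperatures (LT50) from survival assays by logistic dose-response
    regression with delta-method confidence intervals and a Firth-penalized
    fallback for separated data, compares LT50s between species with a
    ratio test, and determines upper thermal limits (UTL) by one-way ANOVA
    with Tukey HSD. Normalizes RNA-seq count matrices by the trimmed mean
    of M-values (TMM), calls differential expression with a lightweight
    negative-binomial exact-style test, and applies a two-caller consensus
    filter (fold-change and FDR cut-offs). Tests cross-species overlap of
    differentially expressed gene annotations against a Monte-Carlo
    resampling null, classifies orthogroups into taxonomic categories to
    derive conserved versus taxonomically restricted gene status with
    Fisher exact enrichment among differentially expressed transcripts,
    and classifies species stress strategies as constitutive or reactive.
    Includes a synthetic multi-species study generator with known ground
    truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
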