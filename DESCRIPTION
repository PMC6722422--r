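Package: gutreg
Title: Host Gene Regulation Responses to Gut Microbiota Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for in vitro host-microbiome gene regulation
    experiments in which colonocytes are exposed to complex gut microbial
    communities. Provides a self-contained negative-binomial GLM engine
    (median-of-ratios size factors, Cox-Reid adjusted dispersion estimation,
    Wald and likelihood-ratio tests) driving several differential-expression
    designs, including a taxon-baseline-abundance covariate model and a
    single-species spike-in dose model; taxon-table processing (rarefaction,
    Gini-Simpson diversity, coculture-effect likelihood-ratio tests); windowed
    differential chromatin accessibility from ATAC fragments with
    motif-stratified false discovery rate; a fragment-length-stratified,
    two-condition transcription-factor footprint mixture model with a logistic
    prior on motif score; and trait-catalog enrichment and cross-experiment
    effect concordance statistics. A synthetic-data module generates every
    input with planted ground truth so the full pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
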