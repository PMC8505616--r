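Package: imscore
Title: Immune Microenvironment Scoring for Multi-Cohort Tumor Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs an immune microenvironment score (IMS) for tumor
    cohorts from single-sample gene-set enrichment (ssGSEA) of immune and
    stromal cell signatures. Signature activity is screened against overall
    survival by univariate Cox regression within each cohort, pooled across
    cohorts by fixed-effect or DerSimonian-Laird random-effects meta-analysis,
    and significant signatures are combined into a per-sample score (sum of
    normalized enrichment over protective signatures minus sum over risk
    signatures) that is dichotomized at the cohort median. Includes the
    downstream association battery (rank tests, correlation screens with
    frequency filters, ROC analysis of treatment response, fraction of genome
    altered from copy-number segments), readers for GCT/TSV/GMT/SEG/MAF-style
    inputs, and a synthetic multi-cohort generator with planted signature
    effects for calibration and power benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    pROC
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
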