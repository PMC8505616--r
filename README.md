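# imscore

Immune microenvironment scoring for multi-cohort tumor transcriptomics.

Bulk tumor transcriptomes carry the footprint of the immune and stromal
cells infiltrating the tissue. **imscore** turns that footprint into a
single prognostic number per patient — an immune microenvironment score
(IMS) — by:

1. scoring every sample for a collection of cell-type gene signatures with
   single-sample gene-set enrichment (ssGSEA): the accumulated difference
   between the rank-weighted empirical CDF of signature genes and the CDF
   of the remaining genes, normalized to NES per cohort;
2. screening each signature's NES against overall survival by univariate
   Cox regression within each cohort (log hazard ratio β, Efron ties);
3. pooling the per-cohort log hazard ratios across cohorts by
   inverse-variance (or DerSimonian–Laird random-effects) meta-analysis
   and keeping signatures with overall *p* < 0.05;
4. combining the survivors with the sign of their pooled hazard ratio:

   IMS_s = Σ_{i: HR<1} NES(i, s) − Σ_{j: HR>1} NES(j, s)

5. splitting each cohort at its median IMS into high/low groups and
   comparing them by Kaplan–Meier / log-rank / restricted-mean survival.

The package also ships the downstream association battery (Wilcoxon,
Kruskal–Wallis, Spearman screens with the 2.5% mutation-frequency filter
and the |rho| > 0.1 joint rule, responder ROC/AUC, fraction of genome
altered from SEG segments), readers for GCT 1.2 / TSV / GMT / SEG /
MAF-style files with an FPKM→TPM converter, and a synthetic multi-cohort
generator with planted signature effects so the whole pipeline is
testable and its operating characteristics measurable offline.

Intended users: computational oncologists building or auditing
TME-based prognostic scores, and methodologists who want a calibrated,
fully testable reference implementation of this widely used construction.

## Worked example

Three synthetic cohorts of 100 samples with the default planted truth
(6 protective signatures at log-HR −0.5, 4 risk at +0.5, 41 nulls):

```r
library(imscore)

cfg  <- simConfig(nCohorts = 3, samplesPerCohort = 100, seed = 7)
sim  <- simulateCohorts(cfg)
disc <- runDiscovery(sim, simSignatureCollection(cfg))
disc$selection
#> SignatureSelection: 7 protective, 5 risk (p < 0.05)

head(disc$metaTable[order(disc$metaTable$p),
     c("signature_id", "pooled_hr", "ci_lo", "ci_hi", "p", "cohort_hits")], 4)
#>   signature_id pooled_hr      ci_lo      ci_hi            p cohort_hits
#> 9        sig09 8.0093674 3.44542125 18.6189034 1.336549e-06           3
#> 4        sig04 0.2229265 0.11035464  0.4503320 2.867116e-05           2
#> 5        sig05 0.2164773 0.09896603  0.4735203 1.271141e-04           2
#> 1        sig01 0.1772361 0.07069933  0.4443132 2.242047e-04           2
```

`sig09` (a planted risk signature) carries a pooled hazard ratio of 8.0
per unit NES — higher enrichment, higher hazard — and was significant in
all 3 cohorts on its own; `sig04`, `sig05`, `sig01` are planted
protective signatures (HR ≈ 0.2). Scoring with the frozen selection:

```r
sc <- runScoring(sim, disc)
head(sc$ims, 3)
#>      sample_id cohort_id        ims group cohort_median n_ties
#> 1 cohort1_s001   cohort1  0.4657122  high    0.01128751      0
#> 2 cohort1_s002   cohort1 -1.4552950   low    0.01128751      0
#> 3 cohort1_s003   cohort1 -0.7941666   low    0.01128751      0

sc$survival[, c("cohort_id", "statistic", "p", "rmst_high", "rmst_low")]
#>   cohort_id statistic            p rmst_high rmst_low
#> 1   cohort1  40.45047 2.016639e-10  68.17341 20.32119
#> 2   cohort2  19.90554 8.136414e-06  58.72351 26.71708
#> 3   cohort3  29.48333 5.639974e-08  58.48791 23.19709
```

In every cohort the high-IMS half lives substantially longer (restricted
mean survival 58–68 vs 20–27 months; log-rank p < 1e-5). Against the
planted truth:

```r
evaluateRecovery(disc$selection, sim$truth)
#>   sensitivity false_selection_rate sign_accuracy ...
#> 1           1           0.04878049             1
```

all 10 planted signatures are recovered with the correct hazard
direction, and 2 of the 41 null signatures slip in — consistent with the
5% selection threshold.

`runBenchmark()` repeats this loop over replicates and reports
sensitivity, sign accuracy, false-selection rate, stratification power
and responder AUC; the methods vignette
(`vignettes/ims-methods.Rmd`) documents the model, parameters, and the
design decisions behind every default.

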