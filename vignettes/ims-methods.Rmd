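---
title: "Constructing an immune microenvironment score: methods and design notes"
author: "imscore package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing an immune microenvironment score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imscore)
```

## The problem

Tumors with similar histology differ widely in their immune contexture, and
that contexture carries prognostic and therapy-predictive information. A
practical way to summarize it from bulk transcriptomes is to score each
sample for the activity of many immune and stromal cell-type signatures,
ask which signatures are reproducibly associated with overall survival
across independent cohorts, and collapse the survival-informative
signatures into a single per-sample **immune microenvironment score
(IMS)**. Patients are then dichotomized at the cohort median IMS into
high/low groups for survival and treatment-response comparisons.

This package implements that construction end to end, together with the
downstream association battery (rank tests, correlation screens, responder
ROC analysis, copy-number burden fractions) and a synthetic multi-cohort
generator with planted ground truth so every stage can be calibrated and
power-tested without access to any real cohort.

## Single-sample enrichment (ssGSEA)

For one sample, genes are ranked by expression: the most highly expressed
of the $G$ genes receives rank $G$, and ties share the average rank.
Walking the genes in decreasing rank order (residual ties broken
lexicographically by gene id so results are deterministic), the enrichment
score of a signature $S$ is

$$
\mathrm{ES} = \sum_{i=1}^{G} \left[ P_{\mathrm{in}}(i) - P_{\mathrm{out}}(i) \right],
\qquad
P_{\mathrm{in}}(i) = \frac{\sum_{j \le i,\; g_j \in S} r_j^{\alpha}}
                          {\sum_{g \in S} r_g^{\alpha}},
\qquad
P_{\mathrm{out}}(i) = \frac{\#\{j \le i : g_j \notin S\}}{G - |S|},
$$

the accumulated difference between the rank-weighted empirical CDF of the
signature genes and the CDF of the remaining genes. Because only ranks
enter, ES is invariant under any strictly increasing per-sample transform
of expression — log-transformed microarray intensities and linear TPM are
scored identically, and additive cohort-wide shifts have no effect.

`ssgseaScore()` evaluates this sum for all signatures and samples at once
through the identity $\sum_i \mathrm{cumsum}(x)_i = \sum_j x_j (G - p_j + 1)$
(with $p_j$ the position of gene $j$ in the ordering), which reduces the
per-sample walk to three matrix products; `singleSetES()` is the
transparent single-set reference, and the test suite checks both against an
independently coded position-by-position summation to $10^{-9}$.

Parameters (`ssgseaParams()`):

* **alpha = 0.25** — the rank-weighting exponent of the original ssGSEA
  formulation. Common descriptions of the method leave the exponent
  implicit, so it is exposed as a parameter rather than fixed silently.
* **normalization = "matrix_range"** — the normalized enrichment score
  (NES) divides every ES by the range (max − min) of the whole cohort ES
  matrix. This matches the common single-sample normalization and makes
  NES scale-free; a per-signature `"zscore"` alternative is offered. The
  choice matters because the IMS *sums* NES values, so it is recorded in
  the discovery manifest and scoring refuses to run under a different
  setting.
* **minSetOverlap = 0.8** — signatures with fewer than 80% of their genes
  measured on a platform are dropped (with the missing genes logged)
  rather than scored on a fragment.

Normalization is always per cohort; cohorts are never pooled at the sample
level at any stage.

## Survival screen and meta-analysis

Within each cohort, each signature's NES is regressed on overall survival
by univariate Cox proportional hazards (Efron tie correction by default,
Breslow available for cross-checking), giving a log hazard ratio
$\hat\beta_k$ with standard error $s_k$ per cohort $k$ and a two-sided
Wald p-value. Fits with $|\hat\beta| > 15$ are flagged as likely
monotone-likelihood divergence and excluded from pooling rather than
silently reported or dropped.

Per-cohort estimates are pooled by inverse-variance meta-analysis:
$w_k = 1/s_k^2$, pooled $\beta = \sum w_k \hat\beta_k / \sum w_k$,
$\mathrm{SE} = (\sum w_k)^{-1/2}$, with heterogeneity
$Q = \sum w_k (\hat\beta_k - \beta)^2$ and
$I^2 = \max(0, (Q - \mathrm{df})/Q) \cdot 100$. A DerSimonian–Laird
random-effects alternative re-weights with $w_k^* = 1/(s_k^2 + \tau^2)$,
$\tau^2 = \max\!\big(0, (Q - \mathrm{df}) / (\sum w_k - \sum w_k^2 / \sum w_k)\big)$.
The fixed-effect model is the default for selection and the model used is
recorded in every output; the unit tests verify both closed forms against
`metafor`.

Signatures with overall $p < 0.05$ (raw; a Benjamini–Hochberg option
exists but is off by default, matching the usual practice of this screen)
are partitioned by pooled hazard-ratio direction into protective
(HR < 1) and risk (HR > 1) sets. The per-cohort significance tally — the
intermediate "associated in at least one cohort" count — is reported
alongside but does not gate pooling: all signatures that pass the overlap
filter are pooled.

## The score and its stratification

For sample $s$, with $n$ protective and $m$ risk signatures selected,

$$
\mathrm{IMS}_s \;=\; \sum_{i=1}^{n} \mathrm{NES}_{i,s} \;-\; \sum_{j=1}^{m} \mathrm{NES}_{j,s}.
$$

The score is reported unscaled. Each cohort is split at its own median
IMS; samples strictly above the median are "high", ties at the median go
to "low" (high is defined as strictly above the cutoff — the tie rule is
documented because it is otherwise a silent implementation choice).
Adding a constant $c$ to every NES shifts every IMS by $c(n - m)$ and
leaves the split unchanged, which the tests assert exactly. The median
cut is simple and assumption-free but not an optimized cutpoint; that is a
known limitation of the design, not of the implementation.

High/low groups are compared by Kaplan–Meier curves, the two-sided
log-rank test, and restricted mean survival over the common follow-up
horizon (so the direction of the survival difference is checked, not just
its significance).

## Synthetic cohorts and what they do (not) show

`simConfig()` / `simulateCohorts()` generate the study conditions the
pipeline is validated under. Per sample $s$ and signature $k$, a latent
activity $a_{sk} \sim N(0,1)$ drives both expression and survival:

* expression of each gene in signature $k$ is
  `baseline + expressionEffect * a_sk + N(0, noiseSd)` (defaults 1 and 1,
  i.e. half the variance of a signature gene is signal), non-signature
  genes are pure noise around their baseline;
* the hazard is $h_0 \exp(\sum_k \mathrm{effect}_k\, a_{sk})$ with
  exponential event times ($h_0 = 0.02$ per month, median survival near
  35 months) and administrative censoring at the empirical quantile that
  yields 30% censoring;
* cohorts differ by a constant expression offset (`cohortShift = 2`),
  which is monotone and therefore invisible to the rank-based scores —
  deliberately the kind of between-platform shift the method is supposed
  to tolerate.

Defaults plant 6 protective signatures at log-HR −0.5 and 4 risk
signatures at +0.5 among 51 disjoint 15-gene signatures in a 2000-gene
universe, 4 cohorts of 300 samples — a desk-scale stand-in for a
multi-cohort gastric-cancer discovery study. Binary treatment-response
labels come from a logistic model on the z-scored planted score
(`simulateResponse()`, separation 3 by default); copy-number segments are
constructed so the planted gained/lost fractions are recovered exactly
(`simulateSegments()` snaps targets to base-pair resolution and returns
the attained values).

What passing these benchmarks shows: the machinery is correctly
calibrated (null selection at the nominal 5%, uniform null p-values,
nominal log-rank size) and has the expected operating characteristics
under a faithful proportional-hazards world with rank-preserving cohort
differences. What it does not show: robustness to negative-binomial
count noise, batch effects that change ranks, overlapping signatures,
copy-number-driven expression coupling, or non-proportional hazards —
real-data properties deliberately outside the generator (an overlap
fraction for signatures and a Weibull shape are the natural extensions).

## Numerical and design choices

* **Readers** sort by identifier, so results are independent of input row
  order; duplicate gene rows collapse to the highest-mean row (the usual
  microarray convention — the probe-collapse policy of any given public
  cohort is rarely recoverable, so one convention is fixed and logged).
  Missing expression values are rejected, not imputed: ssGSEA ranks are
  ill-defined under missingness.
* **Writers** emit full-precision (`%.17g`) doubles, so write/read
  round-trips are exact.
* **Cox** fitting delegates to the survival package's Newton–Raphson;
  the test oracle is an independent grid search of the Efron partial
  likelihood at $10^{-4}$ resolution.
* **SEG coordinates** are 1-based inclusive (length = end − start + 1);
  the altered-fraction threshold is |log2 ratio| ≥ 0.2 and the
  denominator is the *segmented* length, not the genome length — robust
  to incomplete segmentation; both are configurable.
* **Mutation screen**: genes below 2.5% mutation frequency are excluded
  before testing; the Spearman correlation of a binary indicator against
  the IMS reduces to an affine transform of the indicator, so the whole
  screen is one vectorized correlation; the joint filter is |rho| > 0.1
  and raw p < 0.05.
* **Wilcoxon** p-values are exact by enumeration for combined n ≤ 12
  without ties, otherwise normal approximation with tie and continuity
  correction. AUC uses the Mann–Whitney identity with a DeLong interval.
* **Degenerate inputs** (constant covariates, all-tied samples, empty
  groups, all-censored cohorts, signatures spanning the whole gene
  universe) raise errors naming the offending unit instead of returning
  conventional values.

## Benchmarks computed by the package

`runBenchmark()` loops simulate → discover → score → evaluate and reports
sensitivity (planted signatures selected), sign accuracy (hazard
direction among selected planted signatures), false selection rate among
nulls, replicate-level log-rank power of the median split (pooled across
cohorts, requiring the high group to also have the larger restricted mean
survival), the Spearman correlation between IMS and the planted latent
score, and responder AUC. The shipped test suite runs the null
calibration at 500 replicates (4 cohorts × 150 samples) and the recovery
benchmark at 100 replicates of the default configuration;
`scripts/acceptance.R` recomputes the same quantities at 50/200
replicates. These sizes were chosen so the full suite completes in
minutes on a single core while leaving the binomial noise on each
calibration estimate well inside its acceptance band.

## Limitations

The selection threshold is a raw p-value, so the discovered signature set
inherits the usual instability of marginal screens; the median cutpoint
is not optimized; the meta-analysis pools Wald statistics and will be
optimistic for very small cohorts; and the generator's idealizations
listed above mean real-data performance claims require real cohorts.
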