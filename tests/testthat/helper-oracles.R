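# Independent oracles, coded from the definitions rather than from the
# package internals: a position-by-position ssGSEA summation, a grid-search
# maximizer of the Efron partial likelihood, exact Wilcoxon enumeration and
# concordant-pair AUC counting.

# Direct summation of the weighted-ECDF enrichment score: walk the
# decreasing-rank ordering one position at a time and accumulate
# P_in(i) - P_out(i).
oracleES <- function(sampleRanks, geneSet, alpha = 0.25) {
  genes <- names(sampleRanks)
  eff <- intersect(geneSet, genes)
  G <- length(genes)
  ord <- order(-sampleRanks, genes)
  r <- sampleRanks[ord]
  id <- genes[ord]
  wsum <- sum(r[id %in% eff]^alpha)
  inCount <- 0
  outCount <- 0
  es <- 0
  for (i in seq_len(G)) {
    if (id[i] %in% eff) inCount <- inCount + r[[i]]^alpha
    else outCount <- outCount + 1
    es <- es + inCount / wsum - outCount / (G - length(eff))
  }
  unname(es)
}

# Efron log partial likelihood, vectorized over a beta grid.
efronLogLik <- function(betas, time, status, x) {
  E <- exp(outer(x, betas))            # n x B
  ll <- numeric(length(betas))
  for (t in sort(unique(time[status == 1]))) {
    atRisk <- time >= t
    dead <- time == t & status == 1
    d <- sum(dead)
    sR <- colSums(E[atRisk, , drop = FALSE])
    sD <- colSums(E[dead, , drop = FALSE])
    ll <- ll + sum(x[dead]) * betas
    for (l in seq_len(d) - 1L) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

# Coarse-to-fine grid search (resolution 1e-4) over beta in [-5, 5].
gridCoxBeta <- function(time, status, x) {
  coarse <- seq(-5, 5, by = 0.01)
  b0 <- coarse[which.max(efronLogLik(coarse, time, status, x))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  fine[which.max(efronLogLik(fine, time, status, x))]
}

# Exact two-sided Wilcoxon p by enumerating every assignment of the pooled
# ranks to group 1 (no ties assumed).
enumWilcoxP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- rank(c(x, y))
  uObs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  allRanks <- seq_len(n1 + n2)
  u <- apply(combos, 2L, function(idx) sum(allRanks[idx]) - n1 * (n1 + 1) / 2)
  pLow <- mean(u <= uObs)
  pHigh <- mean(u >= uObs)
  min(1, 2 * min(pLow, pHigh))
}

# AUC by explicit pair counting (concordant + half ties).
enumAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Small helpers used across test files --------------------------------------

randomExpression <- function(G, n, seed, prefix = "g") {
  set.seed(seed)
  m <- matrix(rexp(G * n, rate = 0.2), G, n,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(G)),
                              sprintf("smp%03d", seq_len(n))))
  ExpressionMatrix(m)
}

randomSets <- function(genes, nSets, sizeRange = c(5, 12), seed = 1) {
  set.seed(seed)
  sets <- lapply(seq_len(nSets), function(i)
    sample(genes, sample(sizeRange[1]:sizeRange[2], 1)))
  names(sets) <- sprintf("set%02d", seq_len(nSets))
  GeneSetCollection(sets)
}

toyClinical <- function(times, events, ids = sprintf("p%02d", seq_along(times))) {
  data.frame(sample_id = ids, os_time = times, os_event = events)
}
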