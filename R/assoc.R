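# Downstream association battery: two-group and k-group rank tests,
# Spearman correlation, responder ROC/AUC, copy-number burden fractions and
# the mutation-vs-score correlation screen with its frequency filter.

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p by enumeration when the combined sample size is at most
#' 12 and there are no ties; otherwise the normal approximation with tie and
#' continuity correction. When every value in both groups is identical the
#' comparison carries no information: U = n1*n2/2 and p = 1 with a warning.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return One-row `data.frame`: `statistic` (Mann-Whitney U of `x`), `p`,
#'   `n1`, `n2`, `method`.
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  if (max(c(x, y)) == min(c(x, y))) {
    warning("all values tied across both groups; test uninformative")
    return(data.frame(statistic = n1 * n2 / 2, p = 1, n1 = n1, n2 = n2,
                      method = "Wilcoxon rank sum (degenerate)"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2) <= 12L && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  data.frame(statistic = unname(wt$statistic), p = wt$p.value,
             n1 = n1, n2 = n2,
             method = if (exact) "Wilcoxon rank sum (exact)"
                      else "Wilcoxon rank sum (normal approximation)")
}

#' Kruskal-Wallis test for three or more groups
#'
#' H statistic with tie correction, p from the chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param groups list of at least 3 non-empty numeric vectors.
#' @return One-row `data.frame`: `statistic`, `df`, `p`, `method`.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("need at least 3 groups; for two groups use wilcoxonRankSum()")
  if (any(lengths(groups) == 0L)) stop("empty group")
  all <- unlist(groups)
  if (length(unique(all)) < 2L)
    stop("fewer than 2 distinct values overall; test undefined")
  kt <- kruskal.test(groups)
  data.frame(statistic = unname(kt$statistic), df = unname(kt$parameter),
             p = kt$p.value, method = "Kruskal-Wallis")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average ranks; the two-sided p-value
#' uses t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#' A binary variable is accepted (the statistic then reduces to a
#' rank-biserial-style measure), which is what the mutation screen relies
#' on.
#'
#' @param x,y paired numeric vectors, length >= 3, each with at least 2
#'   distinct values.
#' @return One-row `data.frame`: `rho`, `statistic` (t), `p`, `n`, `method`.
#' @export
spearmanCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (max(x) == min(x) || max(y) == min(y))
    stop("constant vector; correlation undefined")
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  if (abs(rho) >= 1) tstat <- sign(rho) * Inf
  data.frame(rho = rho, statistic = tstat,
             p = 2 * pt(-abs(tstat), df = n - 2), n = n,
             method = "Spearman (t approximation)")
}

#' ROC AUC for a binary responder label
#'
#' AUC through the Mann-Whitney identity (concordant pairs plus half the
#' tied pairs over all positive x negative pairs), with a DeLong asymptotic
#' 95\% confidence interval.
#'
#' @param scores numeric predictor (higher = more responder-like).
#' @param labels binary labels (0/1 or a two-level factor); both classes
#'   must be present.
#' @return One-row `data.frame`: `auc`, `ci_lo`, `ci_hi`, `n_pos`, `n_neg`.
#' @export
rocAuc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  labels <- suppressWarnings(as.integer(labels))
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  data.frame(auc = as.numeric(pROC::auc(r)),
             ci_lo = max(0, ci[1L]), ci_hi = min(1, ci[3L]),
             n_pos = sum(labels == 1L), n_neg = sum(labels == 0L))
}

#' Fraction of genome altered / gained / lost from copy-number segments
#'
#' Per sample, the denominator is the total segmented length (robust to
#' incomplete segmentation); FGG is the fraction with log2 ratio at or above
#' the threshold, FGL at or below minus the threshold, and FGA = FGG + FGL.
#' Segment length is end - start + 1 (1-based inclusive coordinates).
#'
#' @param seg segment `data.frame` from [readSegmentTable()] or
#'   [simulateSegments()].
#' @param threshold absolute log2-ratio cutoff (default 0.2, the cBioPortal
#'   convention).
#' @return `data.frame`: `sample_id`, `fga`, `fgg`, `fgl`, `threshold`.
#' @export
genomeAlteredFractions <- function(seg, threshold = 0.2) {
  req <- c("sample_id", "start_bp", "end_bp", "seg_mean")
  miss <- setdiff(req, colnames(seg))
  if (length(miss)) stop("segment table lacks columns: ",
                         paste(miss, collapse = ", "))
  len <- seg$end_bp - seg$start_bp + 1
  out <- lapply(split(seq_len(nrow(seg)), seg$sample_id), function(idx) {
    tot <- sum(len[idx])
    if (tot <= 0) stop("sample with zero total segmented length")
    gain <- sum(len[idx][seg$seg_mean[idx] >= threshold]) / tot
    loss <- sum(len[idx][seg$seg_mean[idx] <= -threshold]) / tot
    data.frame(sample_id = seg$sample_id[idx[1L]],
               fga = gain + loss, fgg = gain, fgl = loss,
               threshold = threshold)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mutation-vs-IMS correlation screen
#'
#' Genes mutated in fewer than `minFreq` of samples are excluded before
#' testing. Each remaining gene's binary mutation indicator is correlated
#' with the IMS by Spearman correlation; genes passing the joint filter
#' (|rho| above `rhoThreshold` and p below `pThreshold`, both raw) are
#' returned sorted by |rho| descending.
#'
#' @param mut binary mutation matrix (samples x genes), e.g. from
#'   [readMutationTable()].
#' @param ims named numeric vector of IMS values; sample sets must match.
#' @param minFreq minimum mutation frequency (default 0.025).
#' @param rhoThreshold minimum |rho| (default 0.1).
#' @param pThreshold maximum p (default 0.05).
#' @return `data.frame`: `gene`, `frequency`, `rho`, `p`, sorted by |rho|
#'   descending; zero rows (with a warning) when no gene passes the
#'   frequency filter.
#' @export
mutationImsScreen <- function(mut, ims, minFreq = 0.025, rhoThreshold = 0.1,
                              pThreshold = 0.05) {
  if (is.null(rownames(mut)) || is.null(names(ims)))
    stop("mutation matrix rows and ims must be named by sample_id")
  if (!setequal(rownames(mut), names(ims)))
    stop("samples of mutation matrix and ims do not match")
  mut <- mut[names(ims), , drop = FALSE]
  n <- length(ims)
  freq <- colMeans(mut)
  tested <- which(freq >= minFreq & freq < 1)  # all-mutated genes carry no ranks
  if (!length(tested)) {
    warning("no gene passes the mutation-frequency filter")
    return(data.frame(gene = character(), frequency = numeric(),
                      rho = numeric(), p = numeric()))
  }
  # Spearman of a binary indicator: zeros share rank (n0+1)/2, ones share
  # n0 + (n1+1)/2, a gap of n/2 -- so the rank matrix is affine in mut and
  # all correlations reduce to one cor() call against the rank of ims.
  n1 <- colSums(mut[, tested, drop = FALSE])
  rankMat <- sweep(mut[, tested, drop = FALSE] * (n / 2), 2L,
                   (n - n1 + 1) / 2, "+")
  rho <- as.vector(cor(rankMat, rank(ims)))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  keep <- abs(rho) > rhoThreshold & p < pThreshold
  out <- data.frame(gene = colnames(mut)[tested][keep],
                    frequency = unname(freq[tested][keep]),
                    rho = rho[keep], p = p[keep])
  out <- out[order(-abs(out$rho)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
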