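# Single-sample gene-set enrichment (ssGSEA).
#
# For one sample, genes are ranked by expression (average ranks for ties,
# rank G = highest). Walking genes in decreasing rank order, the enrichment
# score of a set S is
#
#   ES = sum_i [ P_in(i) - P_out(i) ]
#   P_in(i)  = sum_{j<=i, g_j in S} r_j^alpha / sum_{g in S} r_g^alpha
#   P_out(i) = #{j<=i : g_j not in S} / (G - |S|)
#
# i.e. the difference between the rank-weighted ECDF of set genes and the
# ECDF of the remaining genes, accumulated over the whole ranking. Residual
# ordering ties are broken lexicographically by gene id so scores are
# deterministic. scoreMatrix() evaluates the same sum through the identity
#   sum_i cumsum(x)_i = sum_j x_j * (G - pos_j + 1)
# which turns the per-sample walk into three matrix products.

#' Rank-transform an expression matrix
#'
#' Per-sample average ranks of expression: the most highly expressed gene of
#' a sample receives rank G, ties share the average rank. Ranks are invariant
#' to any strictly increasing transform of a sample's values, which is what
#' makes the enrichment scores robust to per-cohort monotone shifts.
#'
#' @param m an [ExpressionMatrix-class] with at least 2 genes.
#' @return Numeric matrix of ranks, same dimnames as the input; each column
#'   sums to G(G+1)/2.
#' @export
rankTransform <- function(m) {
  v <- exprValues(m)
  if (nrow(v) < 2L) stop("need at least 2 genes to rank")
  R <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    if (max(x) == min(x))
      stop("sample with all-identical values, ranking degenerate: ",
           colnames(v)[j])
    R[, j] <- rank(x)  # ties.method = "average"
  }
  R
}

#' Raw ssGSEA enrichment score of one gene set in one sample
#'
#' Direct evaluation of the weighted-ECDF running sum (see the package
#' vignette). [ssgseaScore()] computes the same quantity for all signatures
#' and samples at once; this single-set form is the transparent reference.
#'
#' @param sampleRanks named numeric vector of per-gene ranks for one sample
#'   (as one column of [rankTransform()]).
#' @param geneSet character vector of gene symbols.
#' @param alpha rank weighting exponent (default 0.25).
#' @return The raw enrichment score (a single number).
#' @export
singleSetES <- function(sampleRanks, geneSet, alpha = 0.25) {
  genes <- names(sampleRanks)
  if (is.null(genes)) stop("sampleRanks must be named by gene id")
  eff <- intersect(geneSet, genes)
  G <- length(genes)
  if (length(eff) == 0L) stop("gene set has no genes in the matrix")
  if (length(eff) == G)
    stop("gene set covers the whole gene universe; complement ECDF undefined")
  ord <- order(-sampleRanks, genes)        # decreasing rank, ties by gene id
  r <- sampleRanks[ord]
  inS <- genes[ord] %in% eff
  w <- r^alpha * inS
  pin <- cumsum(w) / sum(w)
  pout <- cumsum(!inS) / (G - length(eff))
  sum(pin - pout)
}

#' ssGSEA enrichment scores for all signatures and samples
#'
#' Signatures with fewer than `minSetOverlap` of their genes present in the
#' matrix are dropped with a warning naming the missing genes; at least one
#' signature must survive.
#'
#' @param m an [ExpressionMatrix-class].
#' @param sets a [GeneSetCollection-class].
#' @param params an [SsgseaParams-class].
#' @return An [EnrichmentMatrix-class] holding raw ES (apply
#'   [normalizeNES()] for NES).
#' @examples
#' m <- ExpressionMatrix(matrix(rexp(60), 10, 6,
#'   dimnames = list(paste0("g", 1:10), paste0("s", 1:6))))
#' sets <- GeneSetCollection(list(a = c("g1", "g2", "g3"), b = c("g7", "g9")))
#' e <- ssgseaScore(m, sets)
#' enrichES(e)
#' @export
ssgseaScore <- function(m, sets, params = ssgseaParams()) {
  stopifnot(is(m, "ExpressionMatrix"), is(sets, "GeneSetCollection"),
            is(params, "SsgseaParams"))
  R <- rankTransform(m)
  genes <- rownames(R)
  G <- nrow(R)

  setsL <- geneSets(sets)
  if (!length(setsL)) stop("empty gene set collection")
  eff <- lapply(setsL, function(g) g[g %in% genes])
  frac <- lengths(eff) / lengths(setsL)
  drop <- frac < params@minSetOverlap
  if (any(drop)) {
    missing <- vapply(which(drop), function(i) {
      paste0(names(setsL)[i], " (missing: ",
             paste(setdiff(setsL[[i]], genes), collapse = ","), ")")
    }, character(1))
    warning("signatures below minSetOverlap dropped: ",
            paste(missing, collapse = "; "))
  }
  eff <- eff[!drop]
  if (!length(eff)) stop("all signatures dropped by the minSetOverlap filter")
  full <- lengths(eff) == G
  if (any(full))
    stop("signature(s) covering the whole gene universe: ",
         paste(names(eff)[full], collapse = ", "))

  # membership matrix (genes x signatures)
  K <- length(eff)
  M <- matrix(0, G, K, dimnames = list(genes, names(eff)))
  for (k in seq_len(K)) M[eff[[k]], k] <- 1

  # v_gj = G - position of gene g in sample j's decreasing-rank order + 1.
  # Without ties this is the rank itself; tied columns need the explicit
  # lexicographic tie-break order.
  V <- R
  for (j in seq_len(ncol(R))) {
    if (anyDuplicated(R[, j])) {
      ord <- order(-R[, j], genes)
      V[ord, j] <- G:1
    }
  }
  W <- R^params@alpha
  A <- crossprod(M, W * V)              # sum_{g in S} w v   (K x n)
  B <- crossprod(M, W)                  # sum_{g in S} w
  Cm <- crossprod(M, V)                 # sum_{g in S} v
  sizes <- lengths(eff)
  totv <- G * (G + 1) / 2
  es <- A / B - (totv - Cm) / (G - sizes)
  dimnames(es) <- list(names(eff), colnames(R))
  new("EnrichmentMatrix", es = es, nes = matrix(numeric(0), 0, 0),
      params = params)
}

#' Normalize enrichment scores (NES)
#'
#' `matrix_range` mode divides every ES by the range (max - min) of the whole
#' cohort ES matrix, so NES is scale-free in expression and comparable across
#' signatures within a cohort; `zscore` mode standardizes each signature row
#' across samples. Normalization is always per cohort -- never pool matrices
#' from different cohorts before calling this.
#'
#' @param e an [EnrichmentMatrix-class] with raw ES.
#' @return The same object with the `nes` slot filled.
#' @export
normalizeNES <- function(e) {
  stopifnot(is(e, "EnrichmentMatrix"))
  es <- e@es
  mode <- e@params@normalization
  if (mode == "matrix_range") {
    rng <- max(es) - min(es)
    if (rng == 0) stop("constant ES matrix; range normalization degenerate")
    nes <- es / rng
  } else {
    sds <- apply(es, 1L, sd)
    if (any(sds == 0))
      stop("constant ES row(s), z-score normalization degenerate: ",
           paste(rownames(es)[sds == 0], collapse = ", "))
    nes <- t(scale(t(es)))
    dimnames(nes) <- dimnames(es)
  }
  new("EnrichmentMatrix", es = es, nes = nes, params = e@params)
}
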