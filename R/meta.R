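# Cross-cohort pooling of per-cohort log hazard ratios and the signature
# selection rule. Inverse-variance fixed-effect pooling:
#   w_k = 1/se_k^2,  beta = sum(w b)/sum(w),  se = sum(w)^{-1/2}
# Heterogeneity: Q = sum w (b - beta)^2, I^2 = max(0, (Q - df)/Q) * 100.
# DerSimonian-Laird random effects re-weight with w*_k = 1/(se_k^2 + tau^2),
#   tau^2 = max(0, (Q - df) / (sum w - sum w^2 / sum w)).

.poolCore <- function(betas, ses, tau2) {
  w <- 1 / (ses^2 + tau2)
  pb <- sum(w * betas) / sum(w)
  pse <- sqrt(1 / sum(w))
  list(beta = pb, se = pse)
}

.metaRow <- function(betas, ses, model) {
  k <- length(betas)
  if (k < 1L) stop("need at least one cohort result to pool")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("all standard errors must be > 0")
  w <- 1 / ses^2
  fixed <- .poolCore(betas, ses, 0)
  Q <- sum(w * (betas - fixed$beta)^2)
  df <- k - 1L
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  if (model == "fixed") {
    tau2 <- 0
    pooled <- fixed
  } else {
    denom <- sum(w) - sum(w^2) / sum(w)
    tau2 <- if (df > 0L && denom > 0) max(0, (Q - df) / denom) else 0
    pooled <- .poolCore(betas, ses, tau2)
  }
  z <- pooled$beta / pooled$se
  data.frame(pooled_beta = pooled$beta, pooled_se = pooled$se,
             pooled_hr = exp(pooled$beta),
             ci_lo = exp(pooled$beta - 1.96 * pooled$se),
             ci_hi = exp(pooled$beta + 1.96 * pooled$se),
             p = 2 * pnorm(-abs(z)),
             q_stat = Q, i2 = i2, tau2 = tau2, k = k, model = model)
}

#' Fixed-effect (inverse-variance) meta-analysis of log hazard ratios
#'
#' @param betas per-cohort log hazard ratios.
#' @param ses per-cohort standard errors (all > 0).
#' @return One-row `data.frame`: `pooled_beta`, `pooled_se`, `pooled_hr`,
#'   `ci_lo`, `ci_hi`, `p` (Wald two-sided), `q_stat`, `i2`, `tau2` (0 for
#'   the fixed model), `k`, `model`. With a single study the pooled values
#'   equal that study's.
#' @examples
#' poolFixedEffect(c(0.2, 0.6), c(0.1, 0.2))  # pooled beta 0.28
#' @export
poolFixedEffect <- function(betas, ses) .metaRow(betas, ses, "fixed")

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance with truncation at zero; when
#' `Q <= df` the result reduces to fixed-effect pooling.
#'
#' @inheritParams poolFixedEffect
#' @return As [poolFixedEffect()], with `tau2` the DL estimate and
#'   `model = "random_dl"`.
#' @export
poolRandomEffectsDL <- function(betas, ses) .metaRow(betas, ses, "random_dl")

#' Pool the per-cohort Cox screen across cohorts
#'
#' One meta-analysis per signature over its unflagged per-cohort fits.
#' Flagged (divergent) fits are excluded from pooling and counted in
#' `n_flagged`. `cohort_hits` tallies how many cohorts reached per-cohort
#' significance on their own -- the intermediate "associated in at least one
#' cohort" count.
#'
#' @param coxTable output of [coxScreen()].
#' @param model `"fixed"` (default) or `"random_dl"`.
#' @param alphaThreshold threshold used for the per-cohort hit tally.
#' @return `data.frame`, one row per signature, with the pooled columns of
#'   [poolFixedEffect()] plus `signature_id`, `cohort_hits`, `n_flagged`.
#' @export
metaScreen <- function(coxTable, model = c("fixed", "random_dl"),
                       alphaThreshold = 0.05) {
  model <- match.arg(model)
  rows <- lapply(split(coxTable, coxTable$signature_id), function(d) {
    ok <- !d$flagged
    if (!any(ok)) return(NULL)  # nothing poolable for this signature
    pooled <- .metaRow(d$beta[ok], d$se[ok], model)
    cbind(signature_id = d$signature_id[1L], pooled,
          cohort_hits = sum(d$p[ok] < alphaThreshold),
          n_flagged = sum(!ok))
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped))
    warning("signature(s) with no unflagged cohort fit skipped: ",
            paste(names(rows)[dropped], collapse = ", "))
  out <- do.call(rbind, rows[!dropped])
  rownames(out) <- NULL
  out
}

#' Select protective and risk signatures from the meta-analysis
#'
#' Signatures with overall p below the threshold are kept and partitioned by
#' pooled hazard-ratio direction: HR < 1 protective, HR > 1 risk. An empty
#' selection is a valid outcome (reported, and rejected later by
#' [computeIMS()]).
#'
#' @param metaTable output of [metaScreen()].
#' @param alphaThreshold selection p threshold (default 0.05, no multiplicity
#'   correction -- raw overall p, matching common practice for this screen).
#' @return A [SignatureSelection-class].
#' @export
selectSignatures <- function(metaTable, alphaThreshold = 0.05) {
  if (!nrow(metaTable)) stop("empty meta-analysis table")
  sig <- metaTable$p < alphaThreshold
  SignatureSelection(
    protective = metaTable$signature_id[sig & metaTable$pooled_hr < 1],
    risk = metaTable$signature_id[sig & metaTable$pooled_hr > 1],
    alphaThreshold = alphaThreshold,
    table = metaTable)
}
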