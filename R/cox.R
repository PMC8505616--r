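# Per-cohort survival machinery: univariate Cox screening of signature
# activity, Kaplan-Meier curves, the two-group log-rank test and restricted
# mean survival. Fitting is delegated to the survival package (Efron tie
# handling by default); this module adds the validation, alignment and
# reporting contracts the screen relies on.

.alignCovariate <- function(x, clin) {
  if (is.null(names(x))) stop("covariate must be named by sample_id")
  if (!setequal(names(x), clin$sample_id))
    stop("samples of covariate and clinical table do not match")
  x[clin$sample_id]
}

#' Univariate Cox regression of one covariate against overall survival
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by default)
#' and reports the log hazard ratio per unit covariate with its Wald test.
#' Fits whose coefficient exceeds 15 in absolute value are flagged as likely
#' monotone-likelihood divergence (and excluded from pooling by
#' [metaScreen()]) rather than silently reported.
#'
#' @param x named numeric vector of per-sample covariate values (e.g. one
#'   signature's NES).
#' @param clin clinical `data.frame` with `sample_id`, `os_time`, `os_event`;
#'   sample sets must match.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return One-row `data.frame`: `beta`, `se`, `hr`, `ci_lo`, `ci_hi` (Wald
#'   95\%), `p`, `n`, `events`, `flagged`.
#' @export
fitCoxUnivariate <- function(x, clin, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .validateClinical(clin)
  x <- .alignCovariate(x, clin)
  events <- sum(clin$os_event)
  if (events < 2L) stop("need at least 2 events to fit Cox regression (got ",
                        events, ")")
  if (max(x) == min(x)) stop("constant covariate; hazard ratio not identifiable")
  # coxph.fit warns on its own about non-convergence; the flagged-divergence
  # warning below is the single user-facing diagnostic
  fit <- suppressWarnings(
    survival::coxph.fit(matrix(x, ncol = 1L),
                        survival::Surv(clin$os_time, clin$os_event),
                        strata = NULL, offset = NULL, init = 0,
                        control = survival::coxph.control(),
                        weights = NULL, method = ties, rownames = NULL))
  beta <- unname(fit$coefficients)
  se <- sqrt(as.vector(fit$var))
  flagged <- !is.finite(beta) || abs(beta) > 15
  if (flagged)
    warning("likely monotone-likelihood divergence (|beta| > 15); fit flagged")
  z <- beta / se
  data.frame(beta = beta, se = se, hr = exp(beta),
             ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
             p = 2 * pnorm(-abs(z)), n = nrow(clin), events = events,
             flagged = flagged)
}

.alignGroups <- function(groups, clin) {
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), clin$sample_id))
      stop("samples of group labels and clinical table do not match")
    groups <- groups[clin$sample_id]
  } else if (length(groups) != nrow(clin)) {
    stop("group labels must be named or match the clinical table length")
  }
  factor(as.character(groups))
}

#' Kaplan-Meier product-limit estimate per group
#'
#' @param clin clinical `data.frame` (`sample_id`, `os_time`, `os_event`).
#' @param groups group labels, named by sample_id or in clinical row order;
#'   a single group is allowed.
#' @return Named list (one element per group) of `data.frame`s with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
kmEstimate <- function(clin, groups = rep("all", nrow(clin))) {
  .validateClinical(clin)
  g <- .alignGroups(groups, clin)
  if (any(table(g) == 0L)) stop("empty group")
  out <- lapply(levels(g), function(lv) {
    keep <- g == lv
    sf <- survival::survfit(
      survival::Surv(clin$os_time[keep], clin$os_event[keep]) ~ 1)
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               n_censor = sf$n.censor, surv = sf$surv)
  })
  names(out) <- levels(g)
  out
}

#' Two-group log-rank test
#'
#' Chi-square statistic (1 df) accumulated over distinct event times with
#' the hypergeometric variance; two-sided p-value.
#'
#' @param clin clinical `data.frame`.
#' @param groups two-level group labels, named by sample_id or in row order.
#' @return One-row `data.frame`: `statistic`, `df`, `p`, `method`.
#' @export
logrankTest <- function(clin, groups) {
  .validateClinical(clin)
  g <- .alignGroups(groups, clin)
  if (nlevels(g) != 2L) stop("log-rank test requires exactly two groups")
  if (any(table(g) == 0L)) stop("empty group")
  if (sum(clin$os_event) == 0L) stop("no events; log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(clin$os_time, clin$os_event) ~ g)
  stat <- unname(sd$chisq)
  data.frame(statistic = stat, df = 1L,
             p = pchisq(stat, df = 1L, lower.tail = FALSE),
             method = "two-sided log-rank")
}

#' Restricted mean survival time per group
#'
#' Area under the Kaplan-Meier curve up to `tau` (default: the smallest
#' maximum observed time across groups, so groups are compared over a common
#' horizon).
#'
#' @inheritParams kmEstimate
#' @param tau restriction time; `NULL` for the common-horizon default.
#' @return Named numeric vector of restricted means, one per group.
#' @export
restrictedMeanSurvival <- function(clin, groups = rep("all", nrow(clin)),
                                   tau = NULL) {
  .validateClinical(clin)
  g <- .alignGroups(groups, clin)
  if (is.null(tau))
    tau <- min(tapply(clin$os_time, g, max))
  km <- kmEstimate(clin, g)
  vapply(km, function(k) {
    tt <- c(0, k$time[k$time <= tau], tau)
    ss <- c(1, k$surv[k$time <= tau])
    sum(diff(tt) * ss)
  }, numeric(1))
}

#' Univariate Cox screen of every signature in every cohort
#'
#' Runs [fitCoxUnivariate()] for each signature row of each cohort's NES
#' matrix. Divergent (flagged) fits are kept in the table with
#' `flagged = TRUE` so downstream pooling can exclude them explicitly.
#'
#' @param nesList named list (one element per cohort) of NES matrices
#'   (signatures x samples) or [EnrichmentMatrix-class] objects.
#' @param clinList named list of clinical `data.frame`s, same names.
#' @param ties tie handling passed to [fitCoxUnivariate()].
#' @return Long `data.frame`: `signature_id`, `cohort_id` plus the
#'   [fitCoxUnivariate()] columns.
#' @export
coxScreen <- function(nesList, clinList, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!identical(sort(names(nesList)), sort(names(clinList))))
    stop("cohort names of nesList and clinList differ")
  ctrl <- survival::coxph.control()
  out <- list()
  for (co in names(nesList)) {
    nes <- nesList[[co]]
    if (is(nes, "EnrichmentMatrix")) nes <- enrichNES(nes)
    clin <- clinList[[co]]
    .validateClinical(clin)
    if (!setequal(colnames(nes), clin$sample_id))
      stop("samples of NES matrix and clinical table differ in cohort '",
           co, "'")
    nes <- nes[, clin$sample_id, drop = FALSE]
    events <- sum(clin$os_event)
    if (events < 2L)
      stop("cohort '", co, "' has fewer than 2 events")
    y <- survival::Surv(clin$os_time, clin$os_event)
    K <- nrow(nes)
    beta <- se <- numeric(K)
    for (k in seq_len(K)) {
      x <- nes[k, ]
      if (max(x) == min(x))
        stop("constant NES for signature '", rownames(nes)[k],
             "' in cohort '", co, "'")
      fit <- survival::coxph.fit(matrix(x, ncol = 1L), y, strata = NULL,
                                 offset = NULL, init = 0, control = ctrl,
                                 weights = NULL, method = ties,
                                 rownames = NULL)
      beta[k] <- fit$coefficients
      se[k] <- sqrt(as.vector(fit$var))
    }
    flagged <- !is.finite(beta) | abs(beta) > 15
    z <- beta / se
    out[[co]] <- data.frame(
      signature_id = rownames(nes), cohort_id = co, beta = beta, se = se,
      hr = exp(beta), ci_lo = exp(beta - 1.96 * se),
      ci_hi = exp(beta + 1.96 * se), p = 2 * pnorm(-abs(z)),
      n = nrow(clin), events = events, flagged = flagged)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
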