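# Orchestration: discovery (score -> per-cohort Cox -> meta-analysis ->
# selection), scoring (IMS -> median split -> survival comparison) and the
# simulation benchmark. Discovery and scoring are separate so a frozen
# selection can score new cohorts; the discovery manifest records every
# result-affecting parameter and scoring refuses to run under different
# enrichment parameters.

.asCohortList <- function(cohorts) {
  if (inherits(cohorts, "SyntheticCohorts")) cohorts <- cohorts$cohorts
  if (!length(cohorts) || is.null(names(cohorts)))
    stop("cohorts must be a named list of list(expression, clinical)")
  for (co in names(cohorts)) {
    if (!is(cohorts[[co]]$expression, "ExpressionMatrix"))
      stop("cohort '", co, "' lacks an ExpressionMatrix")
    .validateClinical(cohorts[[co]]$clinical)
  }
  cohorts
}

.stage <- function(what, cohort, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("%s failed for cohort '%s': %s", what, cohort,
                 conditionMessage(e)), call. = FALSE))
}

.manifest <- function(params, ties, metaModel, alphaThreshold, cohorts) {
  list(alpha = params@alpha, normalization = params@normalization,
       minSetOverlap = params@minSetOverlap, ties = ties,
       metaModel = metaModel, alphaThreshold = alphaThreshold,
       cohorts = paste(names(cohorts), collapse = ","),
       samples = paste(vapply(cohorts,
                              function(co) ncol(exprValues(co$expression)),
                              numeric(1)), collapse = ","))
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmtNum)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.scoreCohorts <- function(cohorts, sets, params) {
  out <- list()
  for (co in names(cohorts)) {
    out[[co]] <- .stage("ssGSEA scoring", co,
      normalizeNES(ssgseaScore(cohorts[[co]]$expression, sets, params)))
  }
  out
}

#' Discovery: cross-cohort survival screen of signature activity
#'
#' Runs, per cohort, ssGSEA scoring and NES normalization, then the
#' univariate Cox screen, pools log hazard ratios across cohorts by
#' meta-analysis and selects protective/risk signatures at the overall-p
#' threshold.
#'
#' @param cohorts named list of `list(expression = ExpressionMatrix,
#'   clinical = data.frame)` (a `SyntheticCohorts` object is accepted).
#' @param sets a [GeneSetCollection-class] of signatures.
#' @param params [SsgseaParams-class] for scoring.
#' @param ties Cox tie handling.
#' @param metaModel `"fixed"` (default) or `"random_dl"`.
#' @param alphaThreshold selection p threshold.
#' @param outDir optional directory; when given, writes
#'   `cox_per_cohort.tsv`, `meta.tsv`, `selection.tsv` and `manifest.tsv`.
#' @return List of class `imsDiscovery`: `nes` (per-cohort
#'   [EnrichmentMatrix-class]), `coxTable`, `metaTable`, `selection`,
#'   `manifest`.
#' @export
runDiscovery <- function(cohorts, sets, params = ssgseaParams(),
                         ties = c("efron", "breslow"),
                         metaModel = c("fixed", "random_dl"),
                         alphaThreshold = 0.05, outDir = NULL) {
  ties <- match.arg(ties)
  metaModel <- match.arg(metaModel)
  cohorts <- .asCohortList(cohorts)
  nes <- .scoreCohorts(cohorts, sets, params)
  coxTable <- coxScreen(nes, lapply(cohorts, `[[`, "clinical"), ties = ties)
  metaTable <- metaScreen(coxTable, model = metaModel,
                          alphaThreshold = alphaThreshold)
  selection <- selectSignatures(metaTable, alphaThreshold = alphaThreshold)
  manifest <- .manifest(params, ties, metaModel, alphaThreshold, cohorts)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTsv(coxTable, file.path(outDir, "cox_per_cohort.tsv"))
    .writeTsv(metaTable, file.path(outDir, "meta.tsv"))
    selTab <- data.frame(
      signature_id = c(protectiveSignatures(selection),
                       riskSignatures(selection)),
      direction = c(rep("protective", length(protectiveSignatures(selection))),
                    rep("risk", length(riskSignatures(selection)))))
    .writeTsv(selTab, file.path(outDir, "selection.tsv"))
    .writeTsv(data.frame(parameter = names(manifest),
                         value = unlist(manifest)),
              file.path(outDir, "manifest.tsv"))
  }
  structure(list(nes = nes, coxTable = coxTable, metaTable = metaTable,
                 selection = selection, manifest = manifest),
            class = "imsDiscovery")
}

#' Scoring: IMS computation, median split and survival comparison
#'
#' Scores cohorts with a frozen [SignatureSelection-class], splits each
#' cohort at its median IMS and compares the high/low groups by log-rank
#' test and restricted mean survival. When a discovery manifest is supplied,
#' scoring refuses to run under enrichment parameters that differ from the
#' discovery run.
#'
#' @param cohorts as in [runDiscovery()].
#' @param selection a [SignatureSelection-class] (or an `imsDiscovery`
#'   object, whose selection, parameters and NES are reused).
#' @param params [SsgseaParams-class]; must match the manifest when one is
#'   given.
#' @param manifest optional manifest from discovery for the parameter check.
#' @param nes optional precomputed per-cohort NES (skips rescoring).
#' @param outDir optional output directory (`ims.tsv`, `survival.tsv`).
#' @return List of class `imsScoring`: `ims` (per-sample table with group
#'   labels), `survival` (per-cohort log-rank + restricted-mean columns).
#' @export
runScoring <- function(cohorts, selection, params = ssgseaParams(),
                       manifest = NULL, nes = NULL, outDir = NULL) {
  if (inherits(selection, "imsDiscovery")) {
    disc <- selection
    selection <- disc$selection
    manifest <- disc$manifest
    if (is.null(nes)) nes <- disc$nes
    params <- ssgseaParams(alpha = manifest$alpha,
                           normalization = manifest$normalization,
                           minSetOverlap = manifest$minSetOverlap)
  }
  stopifnot(is(selection, "SignatureSelection"))
  if (!is.null(manifest)) {
    same <- identical(manifest$alpha, params@alpha) &&
      identical(manifest$normalization, params@normalization) &&
      identical(manifest$minSetOverlap, params@minSetOverlap)
    if (!same)
      stop("ssGSEA parameters differ from the discovery manifest; ",
           "refusing to score")
  }
  cohorts <- .asCohortList(cohorts)
  if (is.null(nes))
    stop("runScoring needs either precomputed nes or an imsDiscovery ",
         "object; to score from expression use scoreCohortsWithSelection()")
  if (!identical(sort(names(nes)), sort(names(cohorts))))
    stop("cohort names of nes and cohorts differ")

  imsRows <- list()
  survRows <- list()
  for (co in names(cohorts)) {
    imsVec <- .stage("IMS computation", co,
                     computeIMS(nes[[co]], selection))
    strat <- .stage("median stratification", co,
                    stratifyByMedian(imsVec, co))
    clin <- cohorts[[co]]$clinical
    groups <- setNames(strat$group, strat$sample_id)
    lr <- .stage("log-rank comparison", co, logrankTest(clin, groups))
    rm <- restrictedMeanSurvival(clin, groups)
    imsRows[[co]] <- strat
    survRows[[co]] <- cbind(cohort_id = co, lr,
                            rmst_high = rm[["high"]], rmst_low = rm[["low"]])
  }
  ims <- do.call(rbind, imsRows)
  surv <- do.call(rbind, survRows)
  rownames(ims) <- rownames(surv) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTsv(ims, file.path(outDir, "ims.tsv"))
    .writeTsv(surv, file.path(outDir, "survival.tsv"))
  }
  structure(list(ims = ims, survival = surv), class = "imsScoring")
}

#' Scoring directly from expression (standalone use of a frozen selection)
#'
#' Convenience wrapper that scores cohorts from scratch with a given
#' selection and parameters (e.g. applying a gastric-derived selection to a
#' new cohort).
#'
#' @inheritParams runScoring
#' @param sets the [GeneSetCollection-class] to score with.
#' @export
scoreCohortsWithSelection <- function(cohorts, sets, selection,
                                      params = ssgseaParams(),
                                      manifest = NULL, outDir = NULL) {
  cohorts <- .asCohortList(cohorts)
  nes <- .scoreCohorts(cohorts, sets, params)
  runScoring(cohorts, selection, params = params, manifest = manifest,
             nes = nes, outDir = outDir)
}

#' Simulation benchmark: recovery and operating characteristics
#'
#' Loops simulate -> discover -> score -> evaluate over `nReps` replicates
#' of a [simConfig()]. Per replicate it records signature recovery against
#' the planted truth, the pooled (cohort-stratified samples pooled per
#' replicate) high-vs-low log-rank comparison with restricted-mean ordering,
#' the Spearman correlation between IMS and the planted latent score, and
#' the responder AUC at the given separation.
#'
#' @param config a [simConfig()].
#' @param nReps number of replicates.
#' @param separation logistic separation for response simulation (`NA`
#'   skips the response arm).
#' @param scoring when `FALSE`, only discovery/selection metrics are
#'   computed (used for null calibration, where selections are empty by
#'   design).
#' @param seed base seed; replicate r uses `seed + r` (response draws use an
#'   offset stream).
#' @return List: `replicates` (per-replicate metric `data.frame`) and
#'   `metrics` (aggregate named list: `sensitivity`, `sign_accuracy`,
#'   `false_selection_rate`, `selection_rate`, `logrank_power`,
#'   `spearman_rho`, `auc`).
#' @export
runBenchmark <- function(config = simConfig(), nReps = 100L, separation = 3,
                         scoring = TRUE, seed = config$seed) {
  sets <- simSignatureCollection(config)
  rows <- list()
  for (r in seq_len(nReps)) {
    sim <- simulateCohorts(config, seed = seed + r)
    disc <- suppressWarnings(runDiscovery(sim, sets))
    rec <- evaluateRecovery(disc$selection, sim$truth)
    rec$selection_rate <- rec$n_selected / length(config$effects)
    rec$logrank_p <- NA_real_
    rec$rmst_ordered <- NA
    rec$spearman_rho <- NA_real_
    rec$auc <- NA_real_
    if (scoring && rec$n_selected > 0) {
      sc <- runScoring(sim, disc)
      # replicate-level survival contrast: pool samples across cohorts
      # (survival model is cohort-invariant by construction)
      clin <- do.call(rbind, lapply(sim$cohorts, `[[`, "clinical"))
      groups <- setNames(sc$ims$group, sc$ims$sample_id)
      lr <- logrankTest(clin, groups)
      rm <- restrictedMeanSurvival(clin, groups)
      rec$logrank_p <- lr$p
      rec$rmst_ordered <- rm[["high"]] > rm[["low"]]
      truthScore <- unlist(lapply(names(sim$truth$activity), function(co) {
        A <- sim$truth$activity[[co]]
        setNames(rowSums(A[, sim$truth$protective, drop = FALSE]) -
                   rowSums(A[, sim$truth$risk, drop = FALSE]), rownames(A))
      }))
      imsVec <- setNames(sc$ims$ims, sc$ims$sample_id)
      rec$spearman_rho <-
        spearmanCorrelation(imsVec, truthScore[names(imsVec)])$rho
      if (!is.na(separation)) {
        resp <- simulateResponse(sim$truth, separation,
                                 seed = seed + 100000L + r)
        rec$auc <- rocAuc(imsVec[resp$sample_id], resp$response)$auc
      }
    }
    rows[[r]] <- cbind(replicate = r, rec)
  }
  reps <- do.call(rbind, rows)
  metrics <- list(
    sensitivity = mean(reps$sensitivity, na.rm = TRUE),
    sign_accuracy = if (sum(reps$n_hit) > 0)
      sum(reps$n_correct_sign) / sum(reps$n_hit) else NA_real_,
    false_selection_rate = mean(reps$false_selection_rate, na.rm = TRUE),
    selection_rate = mean(reps$selection_rate),
    logrank_power = mean(reps$logrank_p < 0.01 & reps$rmst_ordered,
                         na.rm = TRUE),
    spearman_rho = mean(reps$spearman_rho, na.rm = TRUE),
    auc = mean(reps$auc, na.rm = TRUE))
  list(replicates = reps, metrics = metrics)
}
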