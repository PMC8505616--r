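# Synthetic multi-cohort generator with known ground truth.
#
# Each sample s carries one latent activity a(s, k) ~ N(0, 1) per signature
# k. Signature genes load on their latent (expression = baseline +
# loading * a + noise); all other genes are pure noise. Survival follows a
# proportional-hazards model on the latents,
#   hazard(s) = h0 * exp(sum_k effect_k * a(s, k)),
# with exponential event times and administrative censoring at a configured
# quantile of the event-time distribution. Cohorts differ by a constant
# (monotone) baseline shift, so within-sample expression ranks -- and hence
# ssGSEA scores -- are identical across the shift.

#' Simulation configuration
#'
#' Default scale mirrors a multi-cohort discovery study: 51 disjoint
#' signatures of 15 genes in a 2000-gene universe, 4 cohorts of 300 samples,
#' 6 protective signatures at log-HR -0.5 and 4 risk signatures at +0.5 per
#' unit latent activity, with roughly 30% administrative censoring.
#'
#' @param nCohorts number of cohorts.
#' @param samplesPerCohort samples per cohort (>= 20).
#' @param nGenes gene universe size.
#' @param nSignatures number of disjoint signatures.
#' @param genesPerSignature genes per signature.
#' @param nProtective signatures planted with log-HR `-effectSize`.
#' @param nRisk signatures planted with log-HR `+effectSize`.
#' @param effectSize absolute planted log hazard ratio per unit latent.
#' @param expressionEffect loading of latent activity on signature genes.
#' @param noiseSd residual expression noise SD.
#' @param baselineHazard exponential baseline hazard (per month).
#' @param censoringFraction target administrative censoring fraction.
#' @param cohortShift additive expression offset between consecutive cohorts
#'   (monotone, rank-preserving).
#' @param seed default RNG seed recorded in the config.
#' @return A list of class `SimulationConfig` with the resolved signature
#'   gene lists (`signatures`) and named effect vector (`effects`).
#' @export
simConfig <- function(nCohorts = 4L, samplesPerCohort = 300L, nGenes = 2000L,
                      nSignatures = 51L, genesPerSignature = 15L,
                      nProtective = 6L, nRisk = 4L, effectSize = 0.5,
                      expressionEffect = 1, noiseSd = 1,
                      baselineHazard = 0.02, censoringFraction = 0.3,
                      cohortShift = 2, seed = 1L) {
  if (samplesPerCohort < 20L) stop("samplesPerCohort must be >= 20")
  if (nSignatures * genesPerSignature > nGenes)
    stop("gene universe too small for the requested signatures")
  if (nProtective + nRisk > nSignatures)
    stop("more planted effects than signatures")
  if (censoringFraction < 0 || censoringFraction >= 1)
    stop("censoringFraction must be in [0, 1)")
  genes <- sprintf("gene%04d", seq_len(nGenes))
  sigNames <- sprintf("sig%02d", seq_len(nSignatures))
  signatures <- split(genes[seq_len(nSignatures * genesPerSignature)],
                      rep(seq_len(nSignatures), each = genesPerSignature))
  names(signatures) <- sigNames
  effects <- setNames(rep(0, nSignatures), sigNames)
  if (nProtective > 0) effects[seq_len(nProtective)] <- -effectSize
  if (nRisk > 0) effects[nProtective + seq_len(nRisk)] <- effectSize
  structure(list(nCohorts = nCohorts, samplesPerCohort = samplesPerCohort,
                 nGenes = nGenes, genes = genes, signatures = signatures,
                 effects = effects, expressionEffect = expressionEffect,
                 noiseSd = noiseSd, baselineHazard = baselineHazard,
                 censoringFraction = censoringFraction,
                 cohortShift = cohortShift, seed = seed),
            class = "SimulationConfig")
}

#' Signature collection of a simulation config
#'
#' @param config a [simConfig()] object.
#' @return The planted signatures as a [GeneSetCollection-class].
#' @export
simSignatureCollection <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  GeneSetCollection(config$signatures)
}

#' Simulate multi-cohort expression and survival data
#'
#' Fully reproducible from `(config, seed)`; see the package vignette for
#' the generating model.
#'
#' @param config a [simConfig()] object.
#' @param seed RNG seed (defaults to the config's).
#' @return List of class `SyntheticCohorts` with elements `cohorts` (named
#'   list of `list(expression = ExpressionMatrix, clinical = data.frame)`)
#'   and `truth` (per-cohort latent activity matrices, the planted
#'   protective/risk signature ids, the effect vector and the seed).
#' @export
simulateCohorts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(seed)
  G <- config$nGenes
  n <- config$samplesPerCohort
  K <- length(config$signatures)
  sigNames <- names(config$signatures)
  baseline <- rnorm(G, mean = 7, sd = 1)

  cohorts <- list()
  activity <- list()
  for (co in seq_len(config$nCohorts)) {
    coId <- sprintf("cohort%d", co)
    ids <- sprintf("%s_s%03d", coId, seq_len(n))
    A <- matrix(rnorm(n * K), n, K, dimnames = list(ids, sigNames))
    X <- matrix(rnorm(G * n, sd = config$noiseSd), G, n,
                dimnames = list(config$genes, ids)) + baseline
    for (k in seq_len(K)) {
      gk <- config$signatures[[k]]
      X[gk, ] <- X[gk, ] +
        config$expressionEffect * matrix(A[, k], length(gk), n, byrow = TRUE)
    }
    X <- X + config$cohortShift * (co - 1)
    lp <- as.vector(A %*% config$effects)
    evt <- rexp(n, rate = config$baselineHazard * exp(lp))
    cens <- if (config$censoringFraction > 0)
      quantile(evt, 1 - config$censoringFraction) else Inf
    clin <- data.frame(sample_id = ids,
                       os_time = pmin(evt, cens),
                       os_event = as.integer(evt <= cens))
    cohorts[[coId]] <- list(
      expression = ExpressionMatrix(X, scale = "log2", unit = "intensity"),
      clinical = clin)
    activity[[coId]] <- A
  }
  structure(list(
    cohorts = cohorts,
    truth = list(activity = activity,
                 protective = names(config$effects)[config$effects < 0],
                 risk = names(config$effects)[config$effects > 0],
                 effects = config$effects, config = config, seed = seed)),
    class = "SyntheticCohorts")
}

#' Simulate binary treatment-response labels
#'
#' The true score of each sample is the planted-direction combination of
#' latent activities (sum over protective minus sum over risk signatures);
#' response probability is `plogis(separation * z)` of its z-score. At
#' separation 0 labels are coin flips; large separation approaches
#' deterministic responder labels.
#'
#' @param truth the `truth` element of [simulateCohorts()] output (or the
#'   whole `SyntheticCohorts` object).
#' @param separation non-negative logistic slope.
#' @param seed RNG seed.
#' @return `data.frame`: `sample_id`, `cohort_id`, `true_score`,
#'   `probability`, `response` (0/1).
#' @export
simulateResponse <- function(truth, separation = 3, seed = 1L) {
  if (inherits(truth, "SyntheticCohorts")) truth <- truth$truth
  if (separation < 0) stop("separation must be >= 0")
  set.seed(seed)
  rows <- lapply(names(truth$activity), function(co) {
    A <- truth$activity[[co]]
    score <- rowSums(A[, truth$protective, drop = FALSE]) -
      rowSums(A[, truth$risk, drop = FALSE])
    data.frame(sample_id = rownames(A), cohort_id = co, true_score = score)
  })
  out <- do.call(rbind, rows)
  z <- if (sd(out$true_score) > 0) as.vector(scale(out$true_score)) else
    rep(0, nrow(out))
  out$probability <- plogis(separation * z)
  out$response <- rbinom(nrow(out), 1L, out$probability)
  rownames(out) <- NULL
  out
}

#' Simulate copy-number segments with planted altered fractions
#'
#' Builds, for each sample, gain (log2 ratio +1), loss (-1) and neutral (0)
#' segments over a 22-chromosome genome such that the realized
#' gained/lost fractions equal the targets exactly (targets are snapped to
#' base-pair resolution and the attained values are returned).
#'
#' @param targets optional `data.frame` with `sample_id`, `fgg`, `fgl`
#'   (each in \[0, 1\], `fgg + fgl <= 1`). When `NULL`, `nSamples` random
#'   targets are drawn.
#' @param nSamples number of samples when `targets` is `NULL`.
#' @param seed RNG seed for random targets.
#' @param chromLength length of each of the 22 autosomes (bp).
#' @return List: `segments` (SEG-style `data.frame`), `targets` (attained
#'   per-sample `fgg`/`fgl` after snapping).
#' @export
simulateSegments <- function(targets = NULL, nSamples = 50L, seed = 1L,
                             chromLength = 1e8) {
  nChrom <- 22L
  L <- nChrom * chromLength
  if (is.null(targets)) {
    set.seed(seed)
    targets <- data.frame(sample_id = sprintf("s%03d", seq_len(nSamples)),
                          fgg = runif(nSamples, 0, 0.4),
                          fgl = runif(nSamples, 0, 0.3))
  }
  if (any(targets$fgg < 0) || any(targets$fgl < 0) ||
      any(targets$fgg + targets$fgl > 1))
    stop("targets must be non-negative with fgg + fgl <= 1 per sample")
  gainBp <- round(targets$fgg * L)
  lossBp <- round(targets$fgl * L)
  targets$fgg <- gainBp / L
  targets$fgl <- lossBp / L

  rows <- list()
  for (i in seq_len(nrow(targets))) {
    lens <- c(gain = gainBp[i], loss = lossBp[i],
              neutral = L - gainBp[i] - lossBp[i])
    means <- c(gain = 1, loss = -1, neutral = 0)
    lens <- lens[lens > 0]
    pos <- 0
    for (blk in names(lens)) {
      remaining <- lens[[blk]]
      while (remaining > 0) {
        chrom <- floor(pos / chromLength) + 1
        room <- chrom * chromLength - pos
        take <- min(room, remaining)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = targets$sample_id[i],
          chromosome = as.character(chrom),
          start_bp = pos - (chrom - 1) * chromLength + 1,
          end_bp = pos - (chrom - 1) * chromLength + take,
          seg_mean = means[[blk]])
        pos <- pos + take
        remaining <- remaining - take
      }
    }
  }
  seg <- do.call(rbind, rows)
  rownames(seg) <- NULL
  list(segments = .validateSegments(seg), targets = targets)
}

#' Compare a signature selection against the simulation truth
#'
#' @param selection a [SignatureSelection-class].
#' @param truth the `truth` element of [simulateCohorts()] output.
#' @return One-row `data.frame`: `sensitivity` (planted signatures
#'   selected), `false_selection_rate` (null signatures selected),
#'   `sign_accuracy` (direction agreement among selected planted
#'   signatures; `NA` when none selected), plus the raw counts.
#' @export
evaluateRecovery <- function(selection, truth) {
  stopifnot(is(selection, "SignatureSelection"))
  if (inherits(truth, "SyntheticCohorts")) truth <- truth$truth
  planted <- c(truth$protective, truth$risk)
  nulls <- setdiff(names(truth$effects), planted)
  selected <- c(protectiveSignatures(selection), riskSignatures(selection))
  hit <- intersect(selected, planted)
  correct <- sum(hit %in% truth$protective &
                   hit %in% protectiveSignatures(selection)) +
             sum(hit %in% truth$risk & hit %in% riskSignatures(selection))
  data.frame(
    sensitivity = if (length(planted)) length(hit) / length(planted) else NA_real_,
    false_selection_rate = if (length(nulls))
      length(intersect(selected, nulls)) / length(nulls) else NA_real_,
    sign_accuracy = if (length(hit)) correct / length(hit) else NA_real_,
    n_planted = length(planted), n_selected = length(selected),
    n_hit = length(hit), n_correct_sign = correct)
}
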