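# The immune microenvironment score itself:
#   IMS_s = sum_{i in protective} NES(i, s) - sum_{j in risk} NES(j, s)
# followed by the median split within each cohort.

#' Compute the immune microenvironment score (IMS) per sample
#'
#' Sum of NES over the protective signatures minus the sum over the risk
#' signatures of a [SignatureSelection-class]. The score is reported
#' unscaled; the median cut of [stratifyByMedian()] is applied to it
#' directly.
#'
#' @param nes an [EnrichmentMatrix-class] with NES computed, or an NES
#'   matrix (signatures x samples).
#' @param selection a [SignatureSelection-class]; every selected signature
#'   must be present among the NES rows.
#' @return Named numeric vector of IMS values, one per sample.
#' @examples
#' nes <- matrix(c(0.3, 0.2, 0.1), 3, 1,
#'               dimnames = list(c("a", "b", "c"), "s1"))
#' computeIMS(nes, SignatureSelection(protective = c("a", "b"), risk = "c"))
#' @export
computeIMS <- function(nes, selection) {
  stopifnot(is(selection, "SignatureSelection"))
  if (is(nes, "EnrichmentMatrix")) nes <- enrichNES(nes)
  prot <- protectiveSignatures(selection)
  risk <- riskSignatures(selection)
  if (!length(prot) && !length(risk))
    stop("empty signature selection; IMS undefined")
  missing <- setdiff(c(prot, risk), rownames(nes))
  if (length(missing))
    stop("selected signature(s) missing from the NES matrix: ",
         paste(missing, collapse = ", "))
  colSums(nes[prot, , drop = FALSE]) - colSums(nes[risk, , drop = FALSE])
}

#' Stratify samples at the cohort median IMS
#'
#' The median is computed within each cohort on that cohort's scores only.
#' Samples strictly above the median are `"high"`, all others (including
#' ties at the median) are `"low"` -- "high" is defined strictly above the
#' cutoff.
#'
#' @param ims named numeric vector of IMS values.
#' @param cohorts cohort label per sample (recycled single label allowed);
#'   each cohort needs at least 2 samples and a non-degenerate IMS
#'   distribution.
#' @return `data.frame` with `sample_id`, `cohort_id`, `ims`, `group`
#'   (`"high"`/`"low"`), `cohort_median`, `n_ties` (samples exactly at the
#'   median).
#' @export
stratifyByMedian <- function(ims, cohorts = "cohort1") {
  if (is.null(names(ims))) stop("ims must be named by sample_id")
  if (length(cohorts) == 1L) cohorts <- rep(cohorts, length(ims))
  if (length(cohorts) != length(ims))
    stop("cohorts must have one label per sample")
  out <- lapply(split(seq_along(ims), cohorts), function(idx) {
    x <- ims[idx]
    if (length(x) < 2L) stop("cohort with fewer than 2 samples")
    if (max(x) == min(x))
      stop("all IMS values equal within a cohort; median split degenerate")
    med <- median(x)
    data.frame(sample_id = names(x), cohort_id = cohorts[idx][1L],
               ims = unname(x),
               group = ifelse(x > med, "high", "low"),
               cohort_median = med, n_ties = sum(x == med))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
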