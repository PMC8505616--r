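#' @import methods
#' @importFrom stats median pchisq pnorm pt quantile rbinom rexp rnorm runif
#'   cor plogis var sd setNames wilcox.test kruskal.test
#' @importFrom utils read.delim write.table
NULL

.EXPR_SCALES <- c("linear", "log2")
.EXPR_UNITS  <- c("TPM", "FPKM", "intensity", "arbitrary")

#' ExpressionMatrix: genes x samples abundance values with scale metadata
#'
#' Container for a bulk expression matrix. Row names are gene symbols, column
#' names are sample identifiers; both must be unique and the matrix must be
#' complete (no missing values). Linear-scale values must be non-negative;
#' log2-scale values (microarray intensities, log-transformed TPM) may be
#' negative.
#'
#' @slot values numeric matrix, genes in rows, samples in columns.
#' @slot scale `"linear"` or `"log2"`.
#' @slot unit one of `"TPM"`, `"FPKM"`, `"intensity"`, `"arbitrary"`.
#'
#' @seealso [readExpressionTable()], [fpkmToTpm()], [ssgseaScore()]
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", scale = "character", unit = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L) msg <- c(msg, "expression matrix is empty")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry gene row names and sample column names")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate sample identifiers")
  }
  if (anyNA(v)) msg <- c(msg, "missing values are not allowed")
  if (length(object@scale) != 1L || !object@scale %in% .EXPR_SCALES)
    msg <- c(msg, "scale must be 'linear' or 'log2'")
  if (length(object@unit) != 1L || !object@unit %in% .EXPR_UNITS)
    msg <- c(msg, "unit must be one of TPM, FPKM, intensity, arbitrary")
  if (length(msg) == 0L && object@scale == "linear" && any(v < 0))
    msg <- c(msg, "linear-scale values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with gene row names and sample column names.
#' @param scale measurement scale, `"linear"` (default) or `"log2"`.
#' @param unit measurement unit; defaults to `"arbitrary"`.
#' @return A validated [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, scale = c("linear", "log2"),
                             unit = c("arbitrary", "TPM", "FPKM", "intensity")) {
  scale <- match.arg(scale)
  unit <- match.arg(unit)
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, scale = scale, unit = unit)
}

#' @describeIn ExpressionMatrix-class matrix of expression values
#' @param object an `ExpressionMatrix`
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @describeIn ExpressionMatrix-class gene identifiers (row names)
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("geneIds", "ExpressionMatrix", function(object) rownames(object@values))

#' @describeIn ExpressionMatrix-class sample identifiers (column names)
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(object) colnames(object@values))

#' @describeIn ExpressionMatrix-class measurement scale
#' @export
setGeneric("exprScale", function(object) standardGeneric("exprScale"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprScale", "ExpressionMatrix", function(object) object@scale)

#' @describeIn ExpressionMatrix-class measurement unit
#' @export
setGeneric("exprUnit", function(object) standardGeneric("exprUnit"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprUnit", "ExpressionMatrix", function(object) object@unit)

#' @rdname ExpressionMatrix-class
#' @param x an `ExpressionMatrix`
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s %s)\n",
              nrow(object@values), ncol(object@values),
              object@scale, object@unit))
})

#' GeneSetCollection: named gene signatures
#'
#' A collection of named gene sets (signatures), e.g. tumor-microenvironment
#' cell-type marker lists. Set names are unique, every set is a non-empty
#' character vector of gene symbols without internal duplicates.
#'
#' @slot sets named list of character vectors.
#' @slot descriptions named character vector of free-text descriptions
#'   (possibly empty).
#' @seealso [readGmt()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  s <- object@sets
  msg <- character()
  if (length(s)) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      msg <- c(msg, "every set must be named")
    else if (anyDuplicated(names(s)))
      msg <- c(msg, "duplicate set names")
    bad <- !vapply(s, function(g) is.character(g) && length(g) > 0L &&
                     !anyNA(g) && !anyDuplicated(g), logical(1))
    if (any(bad))
      msg <- c(msg, paste("invalid gene sets (empty, non-character or",
                          "duplicated genes):",
                          paste(names(s)[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions optional named character vector of descriptions.
#' @return A validated [GeneSetCollection-class].
#' @examples
#' GeneSetCollection(list(Tcell = c("CD3D", "CD3E"), Bcell = c("CD19", "MS4A1")))
#' @export
GeneSetCollection <- function(sets = list(), descriptions = character()) {
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @describeIn GeneSetCollection-class the named list of gene sets
#' @param object a `GeneSetCollection`
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)

#' @rdname GeneSetCollection-class
#' @param x a `GeneSetCollection`
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection-class
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection of %d sets", length(object@sets)))
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat(sprintf(" (set sizes %d-%d)", min(sz), max(sz)))
  }
  cat("\n")
})

#' ssGSEA parameters
#'
#' Tunables of the single-sample enrichment engine: the rank weighting
#' exponent of the weighted empirical CDF, the normalization mode that turns
#' raw enrichment scores (ES) into normalized scores (NES), and the minimum
#' fraction of a signature's genes that must be present in the expression
#' matrix for the signature to be scored.
#'
#' @slot alpha non-negative rank weighting exponent (default 0.25, the
#'   original ssGSEA weighting).
#' @slot normalization `"matrix_range"` (ES divided by the range of the whole
#'   cohort ES matrix; default) or `"zscore"` (per-signature standardization
#'   across samples).
#' @slot minSetOverlap minimum fraction (0, 1] of signature genes that must be
#'   measured (default 0.8).
#' @export
setClass("SsgseaParams",
  representation(alpha = "numeric", normalization = "character",
                 minSetOverlap = "numeric"))

setValidity("SsgseaParams", function(object) {
  msg <- character()
  if (length(object@alpha) != 1L || is.na(object@alpha) || object@alpha < 0)
    msg <- c(msg, "alpha must be a single non-negative number")
  if (!object@normalization %in% c("matrix_range", "zscore"))
    msg <- c(msg, "normalization must be 'matrix_range' or 'zscore'")
  if (length(object@minSetOverlap) != 1L || is.na(object@minSetOverlap) ||
      object@minSetOverlap <= 0 || object@minSetOverlap > 1)
    msg <- c(msg, "minSetOverlap must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname SsgseaParams-class
#' @param alpha rank weighting exponent.
#' @param normalization NES normalization mode.
#' @param minSetOverlap minimum fraction of signature genes present.
#' @export
ssgseaParams <- function(alpha = 0.25,
                         normalization = c("matrix_range", "zscore"),
                         minSetOverlap = 0.8) {
  new("SsgseaParams", alpha = alpha, normalization = match.arg(normalization),
      minSetOverlap = minSetOverlap)
}

setMethod("show", "SsgseaParams", function(object) {
  cat(sprintf("SsgseaParams: alpha = %g, normalization = %s, minSetOverlap = %g\n",
              object@alpha, object@normalization, object@minSetOverlap))
})

#' EnrichmentMatrix: signatures x samples enrichment scores
#'
#' Raw ssGSEA enrichment scores (`es`) and, after [normalizeNES()], the
#' normalized scores (`nes`) for every retained signature and sample, together
#' with the [SsgseaParams-class] they were computed under.
#'
#' @slot es numeric matrix of raw enrichment scores (signatures x samples).
#' @slot nes numeric matrix of normalized scores; empty until
#'   [normalizeNES()] is applied.
#' @slot params the `SsgseaParams` used.
#' @seealso [ssgseaScore()], [normalizeNES()], [computeIMS()]
#' @export
setClass("EnrichmentMatrix",
  representation(es = "matrix", nes = "matrix", params = "SsgseaParams"))

setValidity("EnrichmentMatrix", function(object) {
  msg <- character()
  if (is.null(rownames(object@es)) || is.null(colnames(object@es)))
    msg <- c(msg, "es must carry signature and sample names")
  if (length(object@nes) &&
      !identical(dim(object@nes), dim(object@es)))
    msg <- c(msg, "nes and es dimensions differ")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnrichmentMatrix-class raw enrichment scores
#' @param object an `EnrichmentMatrix`
#' @export
setGeneric("enrichES", function(object) standardGeneric("enrichES"))

#' @rdname EnrichmentMatrix-class
#' @export
setMethod("enrichES", "EnrichmentMatrix", function(object) object@es)

#' @describeIn EnrichmentMatrix-class normalized enrichment scores (errors if
#'   [normalizeNES()] has not been applied)
#' @export
setGeneric("enrichNES", function(object) standardGeneric("enrichNES"))

#' @rdname EnrichmentMatrix-class
#' @export
setMethod("enrichNES", "EnrichmentMatrix", function(object) {
  if (!length(object@nes))
    stop("NES not computed yet; apply normalizeNES() first")
  object@nes
})

#' @describeIn EnrichmentMatrix-class the ssGSEA parameters used
#' @export
setGeneric("scoreParams", function(object) standardGeneric("scoreParams"))

#' @rdname EnrichmentMatrix-class
#' @export
setMethod("scoreParams", "EnrichmentMatrix", function(object) object@params)

setMethod("show", "EnrichmentMatrix", function(object) {
  cat(sprintf("EnrichmentMatrix: %d signatures x %d samples (%s)\n",
              nrow(object@es), ncol(object@es),
              if (length(object@nes)) "ES + NES" else "raw ES only"))
})

#' SignatureSelection: survival-informed partition of signatures
#'
#' The outcome of the cross-cohort screen: signatures whose pooled hazard
#' ratio is below 1 at the selection threshold are protective (their NES is
#' added into the IMS), those above 1 are risk signatures (subtracted).
#'
#' @slot protective character vector of protective signature ids (pooled
#'   HR < 1, overall p below threshold).
#' @slot risk character vector of risk signature ids (pooled HR > 1).
#' @slot alphaThreshold the selection p-value threshold.
#' @slot table the meta-analysis table the selection was derived from (may be
#'   empty for hand-built selections).
#' @seealso [selectSignatures()], [computeIMS()]
#' @export
setClass("SignatureSelection",
  representation(protective = "character", risk = "character",
                 alphaThreshold = "numeric", table = "data.frame"))

setValidity("SignatureSelection", function(object) {
  msg <- character()
  if (length(intersect(object@protective, object@risk)))
    msg <- c(msg, "protective and risk sets must be disjoint")
  if (anyDuplicated(object@protective) || anyDuplicated(object@risk))
    msg <- c(msg, "duplicate signature ids in selection")
  if (length(object@alphaThreshold) != 1L || object@alphaThreshold <= 0 ||
      object@alphaThreshold > 1)
    msg <- c(msg, "alphaThreshold must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SignatureSelection
#'
#' Usually produced by [selectSignatures()]; the constructor is exported so a
#' frozen selection can be rebuilt from a saved table.
#'
#' @param protective protective signature ids (pooled HR < 1).
#' @param risk risk signature ids (pooled HR > 1).
#' @param alphaThreshold selection p threshold (default 0.05).
#' @param table optional meta-analysis table backing the selection.
#' @export
SignatureSelection <- function(protective = character(), risk = character(),
                               alphaThreshold = 0.05,
                               table = data.frame()) {
  new("SignatureSelection", protective = as.character(protective),
      risk = as.character(risk), alphaThreshold = alphaThreshold,
      table = table)
}

setMethod("show", "SignatureSelection", function(object) {
  cat(sprintf("SignatureSelection: %d protective, %d risk (p < %g)\n",
              length(object@protective), length(object@risk),
              object@alphaThreshold))
})

#' @describeIn SignatureSelection-class protective signature ids
#' @param object a `SignatureSelection`
#' @export
setGeneric("protectiveSignatures",
           function(object) standardGeneric("protectiveSignatures"))

#' @rdname SignatureSelection-class
#' @export
setMethod("protectiveSignatures", "SignatureSelection",
          function(object) object@protective)

#' @describeIn SignatureSelection-class risk signature ids
#' @export
setGeneric("riskSignatures", function(object) standardGeneric("riskSignatures"))

#' @rdname SignatureSelection-class
#' @export
setMethod("riskSignatures", "SignatureSelection", function(object) object@risk)
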