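# Readers/writers for the plain-text formats the pipeline touches:
# GCT 1.2 and TSV expression tables, GMT signature files, clinical TSV,
# SEG copy-number segments and MAF-derived mutation calls. All readers
# sort by identifier so the result is independent of input row order.

.CHROMS <- c(as.character(1:22), "X", "Y")

.fmtNum <- function(x) sprintf("%.17g", x)  # lossless double round-trip

#' Read an expression table (GCT 1.2 or TSV)
#'
#' TSV files have one header row of sample identifiers and a leading gene-id
#' column; GCT files carry the `#1.2` version line, a dimensions line, and
#' `Name`/`Description` columns. Duplicate gene rows are collapsed by keeping
#' the row with the highest mean expression (the usual microarray
#' probe-collapse convention). Rows are returned sorted by gene id.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gct"`, or `"tsv"`.
#' @param scale,unit metadata recorded on the result; values are not
#'   transformed.
#' @return An [ExpressionMatrix-class].
#' @seealso [writeExpressionTable()], [fpkmToTpm()]
#' @export
readExpressionTable <- function(path, format = c("auto", "gct", "tsv"),
                                scale = c("linear", "log2"),
                                unit = c("arbitrary", "TPM", "FPKM", "intensity")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"

  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || trimws(lines[1L]) != "#1.2")
      stop("not a GCT 1.2 file (missing '#1.2' version line): ", path)
    dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("malformed GCT dimensions line: ", path)
    tab <- read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                      header = TRUE, check.names = FALSE,
                      colClasses = "character", sep = "\t")
    if (ncol(tab) < 3L) stop("GCT file has no sample columns: ", path)
    genes <- tab[[1L]]
    vals <- tab[, -(1:2), drop = FALSE]
    if (nrow(vals) != dims[1L] || ncol(vals) != dims[2L])
      stop(sprintf(
        "GCT dimension mismatch: header declares %d x %d but file contains %d x %d",
        dims[1L], dims[2L], nrow(vals), ncol(vals)))
  } else {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      colClasses = "character", sep = "\t")
    if (ncol(tab) < 2L) stop("TSV expression file has no sample columns: ", path)
    genes <- tab[[1L]]
    vals <- tab[, -1L, drop = FALSE]
  }
  if (nrow(vals) == 0L) stop("empty expression matrix: ", path)

  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(NULL, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    num <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(num) & !is.na(vals[[j]]) & nzchar(trimws(vals[[j]])))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   vals[[j]][bad[1L]], genes[bad[1L]], colnames(vals)[j]))
    if (anyNA(num))
      stop(sprintf("missing value at gene '%s', sample '%s'",
                   genes[which(is.na(num))[1L]], colnames(vals)[j]))
    m[, j] <- num
  }
  rownames(m) <- genes

  if (anyDuplicated(genes)) {
    means <- rowMeans(m)
    ord <- order(-means)      # highest-mean row first within each gene
    keep <- ord[!duplicated(genes[ord])]
    message(sprintf("collapsed %d duplicate gene rows (kept highest mean)",
                    nrow(m) - length(keep)))
    m <- m[sort(keep), , drop = FALSE]
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  ExpressionMatrix(m, scale = scale, unit = unit)
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' Values are written with full double precision so a write/read cycle
#' reproduces the matrix exactly.
#'
#' @param m an [ExpressionMatrix-class].
#' @param path output path.
#' @param format `"tsv"` (gene-id column + sample header) or `"gct"`.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(m, path, format = c("tsv", "gct")) {
  stopifnot(is(m, "ExpressionMatrix"))
  format <- match.arg(format)
  v <- exprValues(m)
  body <- vapply(seq_len(nrow(v)),
                 function(i) paste(.fmtNum(v[i, ]), collapse = "\t"),
                 character(1))
  if (format == "tsv") {
    lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
               paste(rownames(v), body, sep = "\t"))
  } else {
    lines <- c("#1.2",
               paste(nrow(v), ncol(v), sep = "\t"),
               paste(c("Name", "Description", colnames(v)), collapse = "\t"),
               paste(rownames(v), "na", body, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Each line holds a set name, a description, and one or more gene symbols,
#' tab-separated. Duplicate genes within a set are removed with a warning;
#' duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return A [GeneSetCollection-class]; an empty file yields an empty
#'   collection.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(GeneSetCollection())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("GMT line %d has %d fields (need >= 3: name, description, genes)",
                 which(nf < 3L)[1L], nf[nf < 3L][1L]))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  dup <- vapply(sets, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    warning("duplicate genes within sets removed: ",
            paste(nm[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  names(sets) <- nm
  GeneSetCollection(sets, descriptions = setNames(desc, nm))
}

.validateClinical <- function(clin) {
  req <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(req, colnames(clin))
  if (length(miss))
    stop("clinical table lacks required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(clin$sample_id))
    stop("duplicate sample_id in clinical table: ",
         paste(unique(clin$sample_id[duplicated(clin$sample_id)]), collapse = ", "))
  if (!is.numeric(clin$os_time) || anyNA(clin$os_time) || any(clin$os_time <= 0))
    stop("os_time must be numeric and strictly positive")
  if (anyNA(clin$os_event) || !all(clin$os_event %in% c(0, 1)))
    stop("os_event must be 0 (censored) or 1 (death)")
  if ("response" %in% colnames(clin)) {
    resp <- clin$response[!is.na(clin$response)]
    if (length(resp) && !all(resp %in% c(0, 1, "responder", "non_responder")))
      stop("response must be binary (0/1 or responder/non_responder)")
  }
  invisible(clin)
}

#' Read a clinical/survival table
#'
#' TSV with required columns `sample_id`, `os_time` (months, strictly
#' positive) and `os_event` (0 censored / 1 death). Any further columns (age,
#' sex, stage, treatment flags, a binary `response` label, ...) are preserved
#' as covariates. Rows are returned sorted by `sample_id`.
#'
#' @param path TSV file path.
#' @return A validated `data.frame`.
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  clin <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
  .validateClinical(clin)
  clin <- clin[order(clin$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  clin
}

.normChrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x[x == "23"] <- "X"
  x
}

.validateSegments <- function(seg) {
  if (any(seg$end_bp < seg$start_bp))
    stop("segment with end < start")
  bad <- !seg$chromosome %in% .CHROMS
  if (any(bad))
    stop("unknown chromosome label(s): ",
         paste(unique(seg$chromosome[bad]), collapse = ", "))
  seg <- seg[order(seg$sample_id, seg$chromosome, seg$start_bp), , drop = FALSE]
  key <- paste(seg$sample_id, seg$chromosome)
  same <- key[-1L] == key[-length(key)]
  if (any(same & seg$start_bp[-1L] <= seg$end_bp[-length(key)]))
    stop("overlapping segments within one sample/chromosome")
  rownames(seg) <- NULL
  seg
}

#' Read a SEG copy-number segment table
#'
#' Standard SEG columns: sample, chromosome, start, end, optional marker
#' count, and the log2 copy ratio (`seg.mean`). Coordinates are 1-based
#' inclusive (segment length = end - start + 1). Chromosome labels `chr1` and
#' `1` are unified; overlapping segments within one sample/chromosome are
#' rejected.
#'
#' @param path SEG-format TSV path.
#' @return A `data.frame` with columns `sample_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `seg_mean`, sorted by sample, chromosome and start.
#' @seealso [genomeAlteredFractions()]
#' @export
readSegmentTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  cn <- tolower(colnames(tab))
  pick <- function(cands, what) {
    i <- which(cn %in% cands)[1L]
    if (is.na(i)) stop("SEG file lacks a ", what, " column")
    tab[[i]]
  }
  seg <- data.frame(
    sample_id  = as.character(pick(c("id", "sample", "sample_id"), "sample")),
    chromosome = .normChrom(pick(c("chrom", "chromosome", "chr"), "chromosome")),
    start_bp   = as.numeric(pick(c("loc.start", "start", "start_bp"), "start")),
    end_bp     = as.numeric(pick(c("loc.end", "end", "end_bp"), "end")),
    seg_mean   = as.numeric(pick(c("seg.mean", "seg_mean", "segmean"), "seg.mean")),
    stringsAsFactors = FALSE)
  if (anyNA(seg$start_bp) || anyNA(seg$end_bp) || anyNA(seg$seg_mean))
    stop("non-numeric coordinates or seg.mean in SEG file")
  .validateSegments(seg)
}

#' Write a segment table as SEG-format TSV
#'
#' @param seg a segment `data.frame` as returned by [readSegmentTable()] or
#'   [simulateSegments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSegmentTable <- function(seg, path) {
  out <- data.frame(ID = seg$sample_id, chrom = seg$chromosome,
                    loc.start = .fmtNum(seg$start_bp),
                    loc.end = .fmtNum(seg$end_bp),
                    seg.mean = .fmtNum(seg$seg_mean))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Variant classes that do not count as non-silent (TMB-style filtering).
.SILENT_CLASSES <- c("Silent", "Intron", "3'UTR", "5'UTR", "3'Flank",
                     "5'Flank", "IGR", "RNA")

#' Read a MAF-derived mutation table into a binary matrix
#'
#' Minimal MAF-style TSV with columns `Hugo_Symbol`, `Tumor_Sample_Barcode`
#' and `Variant_Classification`. Non-silent variants (anything except
#' Silent/Intron/UTR/Flank/IGR/RNA classes) set the sample x gene indicator
#' to 1.
#'
#' @param path TSV file path.
#' @param samples optional character vector of sample ids to force into the
#'   matrix (so mutation-free samples appear as all-zero rows).
#' @return Binary integer matrix, samples in rows, genes in columns.
#' @seealso [mutationImsScreen()]
#' @export
readMutationTable <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  maf <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(req, colnames(maf))
  if (length(miss))
    stop("mutation file lacks required columns: ", paste(miss, collapse = ", "))
  maf <- maf[!maf$Variant_Classification %in% .SILENT_CLASSES, , drop = FALSE]
  ids <- sort(unique(c(maf$Tumor_Sample_Barcode, samples)))
  genes <- sort(unique(maf$Hugo_Symbol))
  m <- matrix(0L, length(ids), length(genes), dimnames = list(ids, genes))
  if (nrow(maf))
    m[cbind(match(maf$Tumor_Sample_Barcode, ids),
            match(maf$Hugo_Symbol, genes))] <- 1L
  m
}

#' Convert FPKM to TPM
#'
#' Per sample, `TPM(g) = FPKM(g) / sum_g FPKM(g) * 1e6`, so each sample
#' (column) sums to one million after conversion.
#'
#' @param m an [ExpressionMatrix-class] with `unit = "FPKM"` on the linear
#'   scale.
#' @return An `ExpressionMatrix` with `unit = "TPM"`.
#' @export
fpkmToTpm <- function(m) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (exprUnit(m) != "FPKM" || exprScale(m) != "linear")
    stop("fpkmToTpm requires linear-scale FPKM input (got ",
         exprScale(m), " ", exprUnit(m), ")")
  v <- exprValues(m)
  tot <- colSums(v)
  if (any(tot == 0))
    stop("sample(s) with all-zero FPKM, normalization undefined: ",
         paste(colnames(v)[tot == 0], collapse = ", "))
  ExpressionMatrix(sweep(v, 2L, tot, "/") * 1e6, scale = "linear", unit = "TPM")
}
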