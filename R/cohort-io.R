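#' @include AllClasses.R
NULL

#' log2(x + 1) transform of a raw abundance matrix
#'
#' Applies the standard pseudo-count log transform used throughout the
#' pipeline: `out[i, j] = log2(raw[i, j] + 1)`, so a raw value of zero
#' stays zero.  The transform is strictly monotone and invertible on the
#' non-negative reals ([invLog2p1()] is the inverse).
#'
#' @param raw non-negative, finite numeric matrix (features x samples)
#'   with dimnames, e.g. FPKM (mRNA) or RPM (miRNA) values.
#' @param unitTag normalization of `raw`, recorded on the result.
#' @return An [ExpressionMatrix-class] of log2(x+1) values.
#' @examples
#' m <- matrix(c(0, 1, 7, 3), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("P1", "P2")))
#' exprValues(log2p1Transform(m, "FPKM"))  # 0, 1, 3, 2
#' @export
log2p1Transform <- function(raw, unitTag = c("FPKM", "RPM", "synthetic")) {
  unitTag <- match.arg(unitTag)
  raw <- as.matrix(raw)
  bad <- which(!is.finite(raw) | raw < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(raw))
    stop(sprintf(
      "negative or non-finite raw value at feature '%s', sample '%s' (%g)",
      rownames(raw)[ij[1]], colnames(raw)[ij[2]], raw[bad[1L]]))
  }
  ExpressionMatrix(log2(raw + 1), unitTag)
}

#' Inverse of the log2(x + 1) transform
#'
#' @param x numeric vector or matrix of log2(x+1) values.
#' @return `2^x - 1` on the raw abundance scale.
#' @export
invLog2p1 <- function(x) 2^x - 1

#' Read a features x samples expression table
#'
#' Parses a tab-delimited text file whose header row holds the sample
#' identifiers and whose first column holds the feature identifiers.
#' Values are returned untransformed (apply [log2p1Transform()] next);
#' duplicated identifiers, ragged rows and non-numeric cells are rejected
#' with the offending line number.
#'
#' @param path file path.
#' @param unitTag normalization of the stored values (`"FPKM"` or
#'   `"RPM"`), recorded downstream.
#' @return numeric matrix with `unitTag` attached as attribute
#'   `"unitTag"`; pass through [log2p1Transform()] to obtain an
#'   [ExpressionMatrix-class].
#' @seealso [writeExpressionTable()]
#' @export
readExpressionTable <- function(path, unitTag = c("FPKM", "RPM", "synthetic")) {
  unitTag <- match.arg(unitTag)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(sprintf("no features in expression table '%s'", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1L]])
  nsamp <- length(header) - 1L
  if (nsamp < 1L) stop(sprintf("no samples in expression table '%s'", path))
  sampleIds <- header[-1L]
  if (anyDuplicated(sampleIds))
    stop(sprintf("duplicated sample id '%s' in '%s'",
                 sampleIds[duplicated(sampleIds)][1L], path))
  body <- fields[-1L]
  lens <- lengths(body)
  if (any(lens != nsamp + 1L))
    stop(sprintf("ragged row at line %d of '%s' (%d fields, expected %d)",
                 which(lens != nsamp + 1L)[1L] + 1L, path,
                 lens[lens != nsamp + 1L][1L], nsamp + 1L))
  featureIds <- trimws(vapply(body, `[[`, "", 1L))
  if (anyDuplicated(featureIds))
    stop(sprintf("duplicated feature id '%s' at line %d of '%s'",
                 featureIds[duplicated(featureIds)][1L],
                 which(duplicated(featureIds))[1L] + 1L, path))
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(nsamp)))
  vals <- matrix(vals, ncol = nsamp, byrow = TRUE,
                 dimnames = list(featureIds, sampleIds))
  if (anyNA(vals)) {
    ij <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at line %d, sample '%s' of '%s'",
                 ij[1L] + 1L, sampleIds[ij[2L]], path))
  }
  structure(vals, unitTag = unitTag)
}

#' Write a features x samples expression table
#'
#' @param x an [ExpressionMatrix-class] or a numeric matrix with dimnames.
#' @param path output file path (tab-delimited; header = sample ids,
#'   first column = feature id).
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(x, path) {
  m <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  df <- data.frame(feature = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MAF file into a binary mutation event table
#'
#' Reads a standard tab-delimited Mutation Annotation Format file
#' (comment lines starting with `#` are skipped).  Only the
#' `Hugo_Symbol` and `Tumor_Sample_Barcode` columns are used: mutation
#' type and position are deliberately ignored, and however many MAF rows
#' share a (patient, gene) pair they collapse to a single binary event.
#'
#' @param path MAF file path.
#' @return A [MutationEventTable-class] (genes x samples).
#' @export
readMafEvents <- function(path) {
  maf <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(maf))
  if (length(miss))
    stop(sprintf("MAF '%s' is missing mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")))
  if (nrow(maf) == 0L)
    stop(sprintf("no records in MAF '%s'", path))
  gene <- trimws(as.character(maf$Hugo_Symbol))
  samp <- trimws(as.character(maf$Tumor_Sample_Barcode))
  events <- table(factor(gene), factor(samp))
  events <- matrix(as.integer(events > 0L), nrow(events),
                   dimnames = list(rownames(events), colnames(events)))
  MutationEventTable(events)
}

#' Write a MutationEventTable as a minimal MAF file
#'
#' Emits one row per (gene, patient) event with the two mandatory
#' columns; the inverse of [readMafEvents()] up to row order.
#'
#' @param x a [MutationEventTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMafEvents <- function(x, path) {
  ev <- which(eventMatrix(x) == 1L, arr.ind = TRUE)
  df <- data.frame(Hugo_Symbol = rownames(eventMatrix(x))[ev[, 1L]],
                   Tumor_Sample_Barcode = colnames(eventMatrix(x))[ev[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regulon table
#'
#' Tab-delimited file with columns `tf`, `target` and `confidence`
#' (grades A to E).
#'
#' @param path file path.
#' @return A [RegulonTable-class].
#' @export
readRegulonTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "target", "confidence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("regulon table '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  df$tf <- trimws(df$tf); df$target <- trimws(df$target)
  RegulonTable(df[need])
}

#' Write a regulon table
#'
#' @param x a [RegulonTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRegulonTable <- function(x, path) {
  utils::write.table(regulonRecords(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align cohort components to their common patients
#'
#' Restricts the mRNA matrix and, when supplied, the miRNA matrix and the
#' mutation event table to the intersection of their sample identifiers
#' (exact string match after whitespace trimming), in a single shared
#' order, and records the dependent gene.  Patients lacking any supplied
#' component are dropped; the drop count is reported as a message and
#' attached as attribute `"droppedSamples"`.
#'
#' @param mrna [ExpressionMatrix-class] of mRNA expression (required).
#' @param mirna optional [ExpressionMatrix-class] of miRNA expression.
#' @param mutations optional [MutationEventTable-class].
#' @param targetGeneId identifier of the dependent gene; must be a
#'   feature of `mrna`.
#' @return A [CohortBundle-class] over the common samples.
#' @export
alignCohort <- function(mrna, mirna = NULL, mutations = NULL,
                        targetGeneId = "CD274") {
  stopifnot(is(mrna, "ExpressionMatrix"))
  if (!targetGeneId %in% featureIDs(mrna))
    stop(sprintf("target gene '%s' is not in the mRNA matrix", targetGeneId))
  idSets <- list(trimws(sampleIDs(mrna)))
  if (!is.null(mirna)) idSets <- c(idSets, list(trimws(sampleIDs(mirna))))
  if (!is.null(mutations)) idSets <- c(idSets, list(trimws(sampleIDs(mutations))))
  common <- Reduce(intersect, idSets)
  if (length(common) == 0L)
    stop("no samples are shared by all supplied cohort components")
  nDropped <- length(unique(unlist(idSets))) - length(common)
  if (nDropped > 0L)
    message(sprintf("alignCohort: dropped %d sample(s) absent from >=1 component",
                    nDropped))
  subsetExpr <- function(em) {
    m <- exprValues(em)
    colnames(m) <- trimws(colnames(m))
    ExpressionMatrix(m[, common, drop = FALSE], unitTag(em))
  }
  mrna2 <- subsetExpr(mrna)
  mirna2 <- if (is.null(mirna)) NULL else subsetExpr(mirna)
  mut2 <- if (is.null(mutations)) NULL else {
    m <- eventMatrix(mutations)
    colnames(m) <- trimws(colnames(m))
    MutationEventTable(m[, common, drop = FALSE])
  }
  out <- new("CohortBundle", mrna = mrna2, mirna = mirna2,
             mutations = mut2, targetGene = targetGeneId)
  attr(out, "droppedSamples") <- nDropped
  out
}
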