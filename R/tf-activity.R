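#' @include AllClasses.R
NULL

#' Select unique, high-confidence target genes per transcription factor
#'
#' Builds the target-gene sets that proxy TF activity: per TF, keep the
#' regulon targets whose confidence grade is at least `confidence`
#' (A is best, so "at least B" keeps grades A and B), then remove every
#' target that appears in more than one of the *considered* TFs'
#' regulons (uniqueness is evaluated over `tfs` only), then remove the
#' genes in `exclude` (the dependent gene itself, so the response never
#' feeds its own predictor), and finally intersect with the genes
#' actually present in the expression matrix (the number dropped at this
#' step is messaged).
#'
#' @param regulons a [RegulonTable-class].
#' @param tfs TFs to consider; must all appear in the regulon table.
#' @param confidence worst acceptable grade (`"A"` keeps only grade A).
#' @param exclude gene ids removed from every set (default `"CD274"`).
#' @param expressed gene ids available in the expression matrix.
#' @return Named list of character vectors (one per TF); an error names
#'   any TF whose set ends up empty, since its activity would be
#'   undefined.
#' @examples
#' reg <- RegulonTable(data.frame(
#'   tf = c("TF1", "TF1", "TF1", "TF2", "TF2"),
#'   target = c("g1", "g2", "g3", "g3", "g4"),
#'   confidence = "A"))
#' selectUniqueTargets(reg, c("TF1", "TF2"),
#'                     expressed = c("g1", "g2", "g3", "g4"))
#' @export
selectUniqueTargets <- function(regulons, tfs, confidence = "A",
                                exclude = "CD274", expressed) {
  stopifnot(is(regulons, "RegulonTable"))
  confidence <- match.arg(toupper(confidence), .VALID_GRADES)
  rec <- regulonRecords(regulons)
  missingTf <- setdiff(tfs, unique(rec$tf))
  if (length(missingTf))
    stop(sprintf("TF(s) absent from the regulon table: %s",
                 paste(missingTf, collapse = ", ")))
  keepGrades <- .VALID_GRADES[seq_len(match(confidence, .VALID_GRADES))]
  rec <- rec[rec$tf %in% tfs & rec$confidence %in% keepGrades, ]
  sets <- split(rec$target, factor(rec$tf, levels = tfs))
  shared <- unique(unlist(lapply(sets, unique)))
  shared <- shared[vapply(shared, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))) > 1L, logical(1))]
  nDropped <- 0L
  sets <- lapply(sets, function(s) {
    s <- setdiff(s, c(shared, exclude))
    nDropped <<- nDropped + sum(!s %in% expressed)
    intersect(s, expressed)
  })
  if (nDropped > 0L)
    message(sprintf(
      "selectUniqueTargets: dropped %d target(s) absent from the expression matrix",
      nDropped))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop(sprintf("no usable target genes remain for TF(s): %s",
                 paste(empty, collapse = ", ")))
  sets
}

#' Per-patient TF activity as mean target-gene expression
#'
#' The activity proxy of a TF in a patient is the mean of the patient's
#' normalized log2(x+1) expression over the TF's unique target genes.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param sets named list of target-gene sets from
#'   [selectUniqueTargets()]; every gene must be present in `expr`.
#' @return Numeric matrix, TFs x samples (log2 units), sample order
#'   matching `expr`.
#' @export
computeActivity <- function(expr, sets) {
  stopifnot(is(expr, "ExpressionMatrix"))
  m <- exprValues(expr)
  miss <- setdiff(unique(unlist(sets)), rownames(m))
  if (length(miss))
    stop(sprintf("target gene(s) absent from the expression matrix: %s",
                 paste(utils::head(miss, 5L), collapse = ", ")))
  act <- t(vapply(sets, function(s)
    colMeans(m[s, , drop = FALSE]), numeric(ncol(m))))
  dimnames(act) <- list(names(sets), colnames(m))
  act
}

#' Correlation between TF activity and the TF's own mRNA
#'
#' Sanity check of the activity proxies: per TF, the Pearson correlation
#' between its activity row (mean unique-target expression) and its own
#' mRNA abundance row.  A zero-variance vector leaves `r` undefined
#' (reported as NA).
#'
#' @param expr an [ExpressionMatrix-class] containing the TF mRNAs.
#' @param activity TFs x samples activity matrix from
#'   [computeActivity()].
#' @param tfGeneMap optional named character mapping TF name to its mRNA
#'   feature id (defaults to the TF names themselves).
#' @return data.frame with columns `tf`, `r`, `p` (two-sided).
#' @export
activityMrnaCorrelation <- function(expr, activity, tfGeneMap = NULL) {
  m <- exprValues(expr)
  tfs <- rownames(activity)
  if (is.null(tfGeneMap)) tfGeneMap <- setNames(tfs, tfs)
  miss <- setdiff(unname(tfGeneMap[tfs]), rownames(m))
  if (length(miss))
    stop(sprintf("TF mRNA(s) absent from the expression matrix: %s",
                 paste(miss, collapse = ", ")))
  out <- lapply(tfs, function(tf) {
    a <- activity[tf, ]
    g <- m[tfGeneMap[[tf]], colnames(activity)]
    if (sd(a) == 0 || sd(g) == 0)
      return(data.frame(tf = tf, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(a, g, method = "pearson")
    data.frame(tf = tf, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}
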