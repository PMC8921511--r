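#' @include AllClasses.R regression.R
NULL

.QUANTILE_LABELS <- c("low", "lower-midrange", "upper-midrange", "high")

#' Discover miRNAs negatively associated with target expression
#'
#' Per miRNA, the Pearson product-moment correlation between its log2
#' expression and the target gene's log2 expression over `subset`, with
#' a two-sided p-value from the exact t reference
#' `t = r sqrt((n-2)/(1-r^2))` (the same statistic
#' [stats::cor.test()] uses; computed vectorised so screens of
#' thousands of miRNAs stay fast).  miRNAs with `r < 0` and `p < pMax`
#' are accepted as down-regulators; zero-variance miRNAs are skipped and
#' listed in attribute `"skipped"`.
#'
#' @param targetExpr named numeric target log2 expression.
#' @param mirnaExpr an [ExpressionMatrix-class] of miRNA expression.
#' @param subset sample ids to analyse (>= 3 required).
#' @param pMax significance threshold.
#' @param basis label recorded on the result.
#' @return data.frame with columns `mirna`, `r`, `p`, `basis`, sorted by
#'   `p`.
#' @export
discoverCriticalMirnas <- function(targetExpr, mirnaExpr, subset = NULL,
                                   pMax = 0.01,
                                   basis = c("all_patients", "accurate_only")) {
  stopifnot(is(mirnaExpr, "ExpressionMatrix"))
  basis <- match.arg(basis)
  m <- exprValues(mirnaExpr)
  if (is.null(subset)) subset <- colnames(m)
  bad <- setdiff(subset, colnames(m))
  if (length(bad))
    stop(sprintf("subset sample(s) absent from the miRNA matrix: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  if (length(subset) < 3L) stop("at least 3 patients are required")
  if (!all(subset %in% names(targetExpr)))
    stop("targetExpr must cover all subset samples")
  m <- m[, subset, drop = FALSE]
  yy <- targetExpr[subset]
  sds <- apply(m, 1L, sd)
  skipped <- rownames(m)[sds == 0]
  ok <- sds > 0 & sd(yy) > 0
  r <- as.numeric(stats::cor(t(m[ok, , drop = FALSE]), yy))
  n <- length(subset)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  out <- data.frame(mirna = rownames(m)[ok], r = r, p = p, basis = basis)
  out <- out[out$r < 0 & out$p < pMax, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  if (length(skipped))
    message(sprintf("discoverCriticalMirnas: skipped %d zero-variance miRNA(s)",
                    length(skipped)))
  attr(out, "skipped") <- skipped
  attr(out, "nTested") <- sum(ok)
  out
}

#' Per-patient average expression of the critical miRNAs
#'
#' Unweighted mean of the critical miRNA rows, per patient.
#'
#' @param mirnaExpr an [ExpressionMatrix-class].
#' @param critical character vector of critical miRNA ids (or the
#'   data.frame from [discoverCriticalMirnas()]).
#' @return Named numeric vector over all samples of `mirnaExpr`.
#' @export
averageCriticalExpression <- function(mirnaExpr, critical) {
  stopifnot(is(mirnaExpr, "ExpressionMatrix"))
  if (is.data.frame(critical)) critical <- critical$mirna
  if (length(critical) == 0L) stop("no critical miRNAs")
  m <- exprValues(mirnaExpr)
  miss <- setdiff(critical, rownames(m))
  if (length(miss))
    stop(sprintf("critical miRNA(s) absent from the matrix: %s",
                 paste(miss, collapse = ", ")))
  colMeans(m[critical, , drop = FALSE])
}

#' Assign patients to quantile bins of critical-miRNA abundance
#'
#' Cut points are the empirical `(1/k, ..., (k-1)/k)` quantiles of the
#' per-patient averages over the whole cohort.  A value equal to a cut
#' point falls in the upper bin, matching the
#' `low: < q1 ... high: >= q3` convention, so bins are
#' `[q_{j-1}, q_j)` with the top bin closed below.  With the default
#' `k = 4` the bins are named low, lower-midrange, upper-midrange and
#' high.  Massive ties that leave a bin empty are flagged (attribute
#' `"degenerate"`) and the bins are reported as-is.
#'
#' @param averages named numeric vector from
#'   [averageCriticalExpression()].
#' @param k number of quantile bins (>= 2); at least `k` patients are
#'   required.
#' @return data.frame with columns `sample`, `average`, `quantile`
#'   (ordered factor); attributes `"cutPoints"` and `"degenerate"`.
#' @examples
#' q <- assignQuantiles(setNames(1:8, paste0("P", 1:8)))
#' table(q$quantile)  # two patients per bin
#' @export
assignQuantiles <- function(averages, k = 4) {
  if (length(averages) < k) stop("need at least k patients")
  cuts <- unname(quantile(averages, probs = seq_len(k - 1) / k))
  labels <- if (k == 4) .QUANTILE_LABELS else sprintf("Q%d", seq_len(k))
  bin <- findInterval(averages, cuts) + 1L
  degenerate <- !all(seq_len(k) %in% bin)
  if (degenerate)
    warning("degenerate quantile assignment: ties leave >=1 empty bin")
  ids <- names(averages)
  if (is.null(ids)) ids <- as.character(seq_along(averages))
  out <- data.frame(sample = ids, average = unname(averages),
                    quantile = factor(labels[bin], levels = labels,
                                      ordered = TRUE),
                    row.names = NULL)
  attr(out, "cutPoints") <- cuts
  attr(out, "degenerate") <- degenerate
  out
}

#' Single-predictor regression of the target on the miRNA average
#'
#' Ordinary least-squares fit (slope unbounded) of the target gene's
#' log2 expression on the average critical-miRNA expression; used to ask
#' how much predictive value the critical miRNAs carry on their own
#' (typically much less than the TF-activity model).
#'
#' @param targetExpr named numeric target log2 expression.
#' @param averages named numeric from [averageCriticalExpression()],
#'   same samples.
#' @return A [FitResult-class] with the single variable
#'   `"mirna_average"`.
#' @export
fitMirnaModel <- function(targetExpr, averages) {
  if (!identical(names(targetExpr), names(averages)))
    averages <- averages[names(targetExpr)]
  X <- cbind(mirna_average = unname(averages))
  rownames(X) <- names(targetExpr)
  inferOls(targetExpr, X)
}
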