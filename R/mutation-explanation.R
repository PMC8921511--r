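#' @include AllClasses.R prediction-classes.R
NULL

#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper over [stats::wilcox.test()] fixing the conventions used
#' throughout the discovery stages: the exact distribution is used when
#' both arms have at most 8 observations and there are no ties (so small
#' worked examples reproduce exhaustive-enumeration p-values exactly);
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric samples.
#' @return list with elements `U` (statistic for `x` vs `y`) and `p`
#'   (two-sided).
#' @examples
#' mannWhitney(c(10, 11, 12), c(1, 2, 3))$p  # exact two-sided 0.1
#' @export
mannWhitney <- function(x, y) {
  useExact <- length(x) <= 8L && length(y) <= 8L &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = useExact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Discover genes whose mutations associate with elevated target expression
#'
#' For every gene whose carrier fraction within `subset` exceeds
#' `prevalenceMin`, compares the target-gene expression of mutated
#' versus wild-type patients with a two-sided Mann-Whitney U test and
#' computes the fold change `FC = 2^(mean log2 mutated - mean log2
#' wild-type)` (a geometric-mean ratio; set `fcScale = "linear"` for a
#' ratio of back-transformed means).  Genes passing all three filters
#' (`prevalence > prevalenceMin`, `FC > fcMin`, `p < pMax`) are the
#' *critical genes*, sorted by p-value.  No multiple-testing correction
#' is applied (the discovery deliberately filters at raw p with an FC
#' floor); genes with fewer than 2 patients in either arm are skipped
#' and listed in attribute `"skipped"`.
#'
#' @param targetExpr named numeric vector of target log2 expression over
#'   (at least) `subset`.
#' @param events a [MutationEventTable-class].
#' @param subset sample ids to analyse (e.g. the accurately predicted
#'   patients, then the whole cohort); prevalence is computed within
#'   this subset.
#' @param pMax,fcMin,prevalenceMin the three filters.
#' @param basis label recorded on the result (`"accurate_only"` or
#'   `"all_patients"`).
#' @param fcScale `"geometric"` (difference of log2 means, default) or
#'   `"linear"` (ratio of mean back-transformed abundances).
#' @return data.frame with columns `gene`, `p`, `foldChange`,
#'   `prevalence`, `basis`, sorted by `p`.
#' @export
discoverCriticalGenes <- function(targetExpr, events, subset = NULL,
                                  pMax = 0.01, fcMin = 1.5,
                                  prevalenceMin = 0.01,
                                  basis = c("all_patients", "accurate_only"),
                                  fcScale = c("geometric", "linear")) {
  stopifnot(is(events, "MutationEventTable"))
  basis <- match.arg(basis)
  fcScale <- match.arg(fcScale)
  ev <- eventMatrix(events)
  if (is.null(subset)) subset <- colnames(ev)
  bad <- setdiff(subset, colnames(ev))
  if (length(bad))
    stop(sprintf("subset sample(s) absent from the event table: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  if (!all(subset %in% names(targetExpr)))
    stop("targetExpr must cover all subset samples")
  ev <- ev[, subset, drop = FALSE]
  yy <- targetExpr[subset]
  prev <- rowMeans(ev)
  candidates <- rownames(ev)[prev > prevalenceMin]
  skipped <- character(0)
  rows <- lapply(candidates, function(g) {
    mut <- ev[g, ] == 1L
    if (sum(mut) < 2L || sum(!mut) < 2L) {
      skipped <<- c(skipped, g)
      return(NULL)
    }
    fc <- if (fcScale == "geometric") {
      2^(mean(yy[mut]) - mean(yy[!mut]))
    } else {
      mean(invLog2p1(yy[mut])) / mean(invLog2p1(yy[!mut]))
    }
    p <- mannWhitney(yy[mut], yy[!mut])$p
    data.frame(gene = g, p = p, foldChange = fc,
               prevalence = unname(prev[g]), basis = basis)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(gene = character(0), p = numeric(0),
                       foldChange = numeric(0), prevalence = numeric(0),
                       basis = character(0))
  keep <- rows[rows$p < pMax & rows$foldChange > fcMin, , drop = FALSE]
  keep <- keep[order(keep$p), , drop = FALSE]
  rownames(keep) <- NULL
  if (length(skipped))
    message(sprintf("discoverCriticalGenes: skipped %d gene(s) with <2 patients per arm",
                    length(skipped)))
  attr(keep, "skipped") <- skipped
  attr(keep, "nTested") <- length(candidates) - length(skipped)
  keep
}

#' Per-patient count of critical-gene mutations
#'
#' @param events a [MutationEventTable-class].
#' @param critical character vector of critical gene ids (or the
#'   data.frame from [discoverCriticalGenes()]).
#' @return Named integer vector per patient; `0 <= count <= |critical|`.
#' @export
countCritical <- function(events, critical) {
  stopifnot(is(events, "MutationEventTable"))
  if (is.data.frame(critical)) critical <- critical$gene
  ev <- eventMatrix(events)
  miss <- setdiff(critical, rownames(ev))
  if (length(miss))
    stop(sprintf("critical gene(s) absent from the event table: %s",
                 paste(miss, collapse = ", ")))
  if (length(critical) == 0L)
    return(setNames(integer(ncol(ev)), colnames(ev)))
  counts <- colSums(ev[critical, , drop = FALSE])
  setNames(as.integer(counts), colnames(ev))
}

#' Compare critical-mutation burden between patient groups
#'
#' Mann-Whitney comparison of the per-patient critical-gene mutation
#' counts between the underpredicted and the accurately predicted
#' groups.
#'
#' @param counts named integer vector from [countCritical()].
#' @param classification data.frame from [classifyPatients()].
#' @return list with `meanUnderpredicted`, `meanAccurate`, `p`
#'   (two-sided Mann-Whitney) and the group sizes.
#' @export
compareGroupBurden <- function(counts, classification) {
  under <- samplesWithLabel(classification, "underpredicted")
  acc <- samplesWithLabel(classification, "accurate")
  if (length(under) == 0L || length(acc) == 0L)
    stop("group comparison undefined: a group is empty")
  miss <- setdiff(c(under, acc), names(counts))
  if (length(miss)) stop("counts must cover both groups")
  mw <- mannWhitney(counts[under], counts[acc])
  list(meanUnderpredicted = mean(counts[under]),
       meanAccurate = mean(counts[acc]),
       p = mw$p, nUnderpredicted = length(under), nAccurate = length(acc))
}
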