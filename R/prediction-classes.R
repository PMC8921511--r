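#' @include AllClasses.R
NULL

.PRED_LABELS <- c("accurate", "underpredicted", "overpredicted")

#' Classify patients by observed-vs-predicted expression
#'
#' Partitions the cohort by the gap `delta = observed - predicted` on
#' the stored log2(x+1) scale: a patient is *underpredicted* when the
#' observation exceeds the prediction by more than `log2(fold)` (a
#' more-than-`fold`-fold difference on the expression scale),
#' *overpredicted* when the prediction exceeds the observation by more
#' than `log2(fold)`, and *accurate* otherwise.  With the default
#' `fold = 2` the band is one log2 unit on either side.
#'
#' @param observed,predicted aligned named numeric vectors (log2 units).
#' @param fold fold threshold, > 1.
#' @return data.frame with columns `sample`, `observed`, `predicted`,
#'   `delta` and `label` (factor with levels accurate / underpredicted /
#'   overpredicted).
#' @examples
#' cl <- classifyPatients(c(A = 5.0, B = 3.0, C = 4.0),
#'                        c(A = 3.9, B = 4.2, C = 4.0))
#' cl$label  # underpredicted, overpredicted, accurate
#' @export
classifyPatients <- function(observed, predicted, fold = 2) {
  if (fold <= 1) stop("fold must be > 1")
  if (length(observed) != length(predicted))
    stop("observed and predicted must be aligned")
  if (!is.null(names(observed)) && !is.null(names(predicted)) &&
      !identical(names(observed), names(predicted)))
    stop("observed and predicted sample ids differ")
  if (!all(is.finite(observed)) || !all(is.finite(predicted)))
    stop("observed and predicted must be finite")
  thr <- log2(fold)
  delta <- observed - predicted
  label <- ifelse(delta > thr, "underpredicted",
                  ifelse(-delta > thr, "overpredicted", "accurate"))
  ids <- names(observed)
  if (is.null(ids)) ids <- as.character(seq_along(observed))
  data.frame(sample = ids, observed = unname(observed),
             predicted = unname(predicted), delta = unname(delta),
             label = factor(label, levels = .PRED_LABELS),
             row.names = NULL)
}

#' Fraction of patients per prediction class
#'
#' @param classification data.frame from [classifyPatients()].
#' @return Named numeric of fractions over
#'   accurate / underpredicted / overpredicted; sums to 1.
#' @export
groupFractions <- function(classification) {
  if (nrow(classification) == 0L) stop("empty classification")
  tab <- table(classification$label)
  setNames(as.numeric(tab) / nrow(classification), names(tab))
}

#' Sample ids carrying a given prediction label
#'
#' @param classification data.frame from [classifyPatients()].
#' @param label one of `"accurate"`, `"underpredicted"`,
#'   `"overpredicted"`.
#' @return Character vector of sample ids.
#' @export
samplesWithLabel <- function(classification,
                             label = c("accurate", "underpredicted",
                                       "overpredicted")) {
  label <- match.arg(label)
  classification$sample[classification$label == label]
}
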