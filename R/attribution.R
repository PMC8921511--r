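#' @include AllClasses.R regression.R prediction-classes.R
NULL

.EXPLANATIONS <- c("TF", "mutation", "miRNA", "mutation+miRNA", "unexplained")

#' Combined TF + mutation + miRNA regression
#'
#' Extends the TF-activity design with the per-patient critical-mutation
#' count (coefficient constrained non-negative) and the average
#' critical-miRNA expression (coefficient constrained non-positive,
#' mirroring the strictly-negative-regulator modeling; set
#' `constrainMirna = FALSE` to leave it unbounded), then runs the same
#' bounded-fit / OLS-refit selection as [selectModel()] at
#' `alpha = 0.01`.  Zero-variance extra terms (e.g. no mutations at all)
#' are dropped with a warning before fitting.
#'
#' @param targetExpr named numeric target log2 expression.
#' @param activity TFs x samples activity matrix.
#' @param mutationCounts named integer vector from [countCritical()],
#'   or NULL to omit the term.
#' @param mirnaAverage named numeric vector from
#'   [averageCriticalExpression()], or NULL to omit the term.
#' @param alpha per-coefficient significance threshold.
#' @param allowNegative TFs whose coefficient may be negative (BRD4).
#' @param constrainMirna constrain the miRNA-average coefficient <= 0.
#' @return A [FitResult-class].
#' @export
fitCombined <- function(targetExpr, activity, mutationCounts = NULL,
                        mirnaAverage = NULL, alpha = 0.01,
                        allowNegative = "BRD4", constrainMirna = TRUE) {
  ids <- names(targetExpr)
  X <- t(activity[, ids, drop = FALSE])
  extraNeg <- character(0)
  if (!is.null(mutationCounts)) {
    if (stats::var(mutationCounts[ids]) == 0) {
      warning("mutation_count has zero variance; term dropped")
    } else {
      X <- cbind(X, mutation_count = as.numeric(mutationCounts[ids]))
    }
  }
  if (!is.null(mirnaAverage)) {
    if (stats::var(mirnaAverage[ids]) == 0) {
      warning("mirna_average has zero variance; term dropped")
    } else {
      X <- cbind(X, mirna_average = unname(mirnaAverage[ids]))
    }
  }
  spec <- designSpec(colnames(X), allowNegative = allowNegative,
                     nonPositive = if (constrainMirna &&
                                       "mirna_average" %in% colnames(X))
                       "mirna_average" else character(0))
  if (!constrainMirna && "mirna_average" %in% colnames(X))
    spec$lower["mirna_average"] <- -Inf
  selectModel(targetExpr, X, spec, alpha = alpha)
}

#' Attribute each patient's expression to an explanation category
#'
#' Accurately predicted (and overpredicted) patients are explained by TF
#' activity.  Each underpredicted patient is attributed by the decision
#' rule: *mutation* when the critical-mutation count is at least
#' `minMutations`, *miRNA* when the critical-miRNA quantile is the
#' lowest bin, *mutation+miRNA* when both hold, *unexplained* when
#' neither does.
#'
#' @param classification data.frame from [classifyPatients()].
#' @param mutationCounts named integer vector from [countCritical()],
#'   or NULL (no mutation explanations).
#' @param quantiles data.frame from [assignQuantiles()], or NULL (no
#'   miRNA explanations).
#' @param minMutations critical-mutation count threshold (default 1).
#' @param lowQuantile label of the explaining bin (default `"low"`).
#' @return list with `records` (per-patient data.frame: sample, label,
#'   mutation count, quantile, explanation) and `summary` (list of
#'   explanation fractions over the underpredicted group and over the
#'   whole cohort; each sums to 1).
#' @export
attributePatients <- function(classification, mutationCounts = NULL,
                              quantiles = NULL, minMutations = 1L,
                              lowQuantile = "low") {
  ids <- classification$sample
  if (!is.null(mutationCounts)) {
    if (!all(ids %in% names(mutationCounts)))
      stop("mutationCounts missing for some patients")
    cnt <- as.integer(mutationCounts[ids])
  } else cnt <- rep(NA_integer_, length(ids))
  if (!is.null(quantiles)) {
    if (!all(ids %in% quantiles$sample))
      stop("quantiles missing for some patients")
    qt <- as.character(quantiles$quantile[match(ids, quantiles$sample)])
  } else qt <- rep(NA_character_, length(ids))
  mutExplained <- !is.na(cnt) & cnt >= minMutations
  mirExplained <- !is.na(qt) & qt == lowQuantile
  expl <- ifelse(classification$label != "underpredicted", "TF",
           ifelse(mutExplained & mirExplained, "mutation+miRNA",
            ifelse(mutExplained, "mutation",
             ifelse(mirExplained, "miRNA", "unexplained"))))
  records <- data.frame(sample = ids, label = classification$label,
                        mutationCount = cnt, quantile = qt,
                        explanation = factor(expl, levels = .EXPLANATIONS),
                        row.names = NULL)
  under <- records[records$label == "underpredicted", ]
  fracOver <- function(df) {
    tab <- table(df$explanation)
    setNames(as.numeric(tab) / nrow(df), names(tab))
  }
  summary <- list(
    underpredicted = if (nrow(under)) fracOver(under)
                     else setNames(rep(NA_real_, length(.EXPLANATIONS)),
                                   .EXPLANATIONS),
    cohort = fracOver(records))
  list(records = records, summary = summary)
}

#' Random train/test split of sample ids
#'
#' @param sampleIds character vector.
#' @param trainFrac training fraction in (0, 1); the training size is
#'   `round(n * trainFrac)`.
#' @param seed integer; the same seed gives the identical split.
#' @return list with character vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
splitTrainTest <- function(sampleIds, trainFrac = 0.8, seed = 1L) {
  if (trainFrac <= 0 || trainFrac >= 1) stop("trainFrac must be in (0, 1)")
  n <- length(sampleIds)
  if (n < 2L) stop("need at least 2 samples to split")
  set.seed(seed)
  nTrain <- max(1L, min(n - 1L, round(n * trainFrac)))
  train <- sample(sampleIds, nTrain)
  list(train = train, test = setdiff(sampleIds, train))
}

#' Generalized model across pooled cohorts
#'
#' Pools the cohorts' activity matrices and target vectors, splits the
#' pooled patients into a training and a test set, runs [selectModel()]
#' on the training pool, and reports the fraction of test patients (and
#' of any supplied external cohorts) whose prediction falls within the
#' `fold`-fold band.  With `nRepeats > 1` the split-fit-evaluate cycle
#' is repeated with consecutive derived seeds and the per-repeat
#' coefficient tables are reported, so coefficient dispersion across
#' training sets can be inspected (no averaged model is formed).
#'
#' @param cohorts named list; each element a list with `activity`
#'   (TFs x samples matrix) and `target` (named numeric).  All cohorts
#'   must share the same TF set.
#' @param seed base integer seed; repeat r uses `seed + r - 1`.
#' @param nRepeats number of independent splits.
#' @param trainFrac training fraction.
#' @param external optional named list of cohorts (same structure) held
#'   out entirely; evaluated with the model of each repeat.
#' @param spec,alpha selection settings, as [selectModel()].
#' @param fold band threshold for the within-band fraction.
#' @return list with `fits` (per-repeat [FitResult-class]),
#'   `coefTable` (repeat x coefficient data.frame), `bandFractions`
#'   (per-repeat named vector: test + external cohorts), `splits`.
#' @export
fitGeneralized <- function(cohorts, seed = 1L, nRepeats = 1L,
                           trainFrac = 0.8, external = list(),
                           spec = NULL, alpha = 0.001, fold = 2) {
  stopifnot(length(cohorts) >= 1L)
  tfSets <- lapply(cohorts, function(co) rownames(co$activity))
  if (!all(vapply(tfSets, identical, logical(1), y = tfSets[[1L]])))
    stop("TF sets are inconsistent across cohorts")
  tfs <- tfSets[[1L]]
  pool <- function(cos, tag = TRUE) {
    acts <- lapply(names(cos), function(nm) {
      a <- cos[[nm]]$activity
      if (tag) colnames(a) <- paste(nm, colnames(a), sep = ".")
      a
    })
    tgts <- lapply(names(cos), function(nm) {
      y <- cos[[nm]]$target
      if (tag) names(y) <- paste(nm, names(y), sep = ".")
      y
    })
    list(activity = do.call(cbind, acts), target = do.call(c, tgts))
  }
  if (is.null(names(cohorts)))
    names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
  pooled <- pool(cohorts)
  if (is.null(spec)) spec <- designSpec(tfs, allowNegative = "BRD4")
  bandFrac <- function(fit, activity, target) {
    pred <- predict(fit, t(activity))
    mean(abs(target[colnames(activity)] - pred) <= log2(fold))
  }
  fits <- vector("list", nRepeats)
  splits <- vector("list", nRepeats)
  bands <- vector("list", nRepeats)
  coefs <- vector("list", nRepeats)
  ids <- colnames(pooled$activity)
  for (r in seq_len(nRepeats)) {
    sp <- splitTrainTest(ids, trainFrac, seed = seed + r - 1L)
    fit <- selectModel(pooled$target[sp$train],
                       t(pooled$activity[, sp$train, drop = FALSE]),
                       spec, alpha = alpha)
    bf <- c(test = bandFrac(fit, pooled$activity[, sp$test, drop = FALSE],
                            pooled$target))
    for (nm in names(external))
      bf[nm] <- bandFrac(fit, external[[nm]]$activity,
                         external[[nm]]$target)
    fits[[r]] <- fit
    splits[[r]] <- sp
    bands[[r]] <- bf
    coefs[[r]] <- data.frame(repeatIdx = r,
                             variable = c("(Intercept)", selectedVariables(fit)),
                             coefficient = unname(coef(fit)))
  }
  list(fits = fits, coefTable = do.call(rbind, coefs),
       bandFractions = do.call(rbind, bands), splits = splits)
}
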