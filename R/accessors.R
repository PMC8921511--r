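#' @include AllClasses.R
NULL

#' Accessors for the core containers
#'
#' `exprValues()` returns the numeric log2 expression matrix,
#' `unitTag()` the pre-transform normalization tag, `featureIDs()` and
#' `sampleIDs()` the identifier vectors, and `eventMatrix()` the binary
#' gene x sample mutation matrix.  `regulonRecords()` returns the
#' (tf, target, confidence) data.frame of a [RegulonTable-class].
#'
#' @param x an [ExpressionMatrix-class], [MutationEventTable-class],
#'   [RegulonTable-class] or [CohortBundle-class] object, as appropriate.
#' @return See details; matrices carry dimnames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(x) assay(x, "log2expr"))

#' @rdname accessors
#' @export
setGeneric("unitTag", function(x) standardGeneric("unitTag"))

#' @rdname accessors
#' @export
setMethod("unitTag", "ExpressionMatrix", function(x) x@unitTag)

#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' @rdname accessors
#' @export
setMethod("featureIDs", "ExpressionMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("featureIDs", "MutationEventTable", function(x) rownames(x@events))

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "ExpressionMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "MutationEventTable", function(x) colnames(x@events))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "CohortBundle", function(x) sampleIDs(x@mrna))

#' @rdname accessors
#' @export
setGeneric("eventMatrix", function(x) standardGeneric("eventMatrix"))

#' @rdname accessors
#' @export
setMethod("eventMatrix", "MutationEventTable", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("regulonRecords", function(x) standardGeneric("regulonRecords"))

#' @rdname accessors
#' @export
setMethod("regulonRecords", "RegulonTable", function(x) x@records)

#' Cohort component accessors
#'
#' Extract the mRNA / miRNA expression matrices, mutation event table and
#' dependent-gene identifier from a [CohortBundle-class], and the
#' dependent gene's per-patient log2 expression vector.
#'
#' @param x a [CohortBundle-class].
#' @return `mrna()`/`mirna()` return [ExpressionMatrix-class] (miRNA may be
#'   NULL), `mutations()` a [MutationEventTable-class] or NULL,
#'   `targetGene()` character(1), and `targetExpression()` a named numeric
#'   vector over the cohort samples.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("mrna", function(x) standardGeneric("mrna"))

#' @rdname cohort-accessors
#' @export
setMethod("mrna", "CohortBundle", function(x) x@mrna)

#' @rdname cohort-accessors
#' @export
setGeneric("mirna", function(x) standardGeneric("mirna"))

#' @rdname cohort-accessors
#' @export
setMethod("mirna", "CohortBundle", function(x) x@mirna)

#' @rdname cohort-accessors
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' @rdname cohort-accessors
#' @export
setMethod("mutations", "CohortBundle", function(x) x@mutations)

#' @rdname cohort-accessors
#' @export
setGeneric("targetGene", function(x) standardGeneric("targetGene"))

#' @rdname cohort-accessors
#' @export
setMethod("targetGene", "CohortBundle", function(x) x@targetGene)

#' @rdname cohort-accessors
#' @export
setGeneric("targetExpression", function(x) standardGeneric("targetExpression"))

#' @rdname cohort-accessors
#' @export
setMethod("targetExpression", "CohortBundle", function(x)
  exprValues(x@mrna)[x@targetGene, ])

#' FitResult accessors
#'
#' Standard extractors for a fitted model: `coef()` returns the intercept
#' followed by the selected coefficients, `residuals()` the per-patient
#' residuals, `pvalues()` the coefficient p-values, `r2()` the coefficient
#' of determination, `fitPvalue()` the overall F-test p-value and
#' `selectedVariables()` the surviving variable names.
#'
#' @param object,x a [FitResult-class].
#' @param ... ignored.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setMethod("coef", "FitResult", function(object, ...)
  c("(Intercept)" = object@beta0, object@betas))

#' @rdname fit-accessors
#' @export
setMethod("residuals", "FitResult", function(object, ...) object@residuals)

#' @rdname fit-accessors
#' @export
setGeneric("pvalues", function(x) standardGeneric("pvalues"))

#' @rdname fit-accessors
#' @export
setMethod("pvalues", "FitResult", function(x) x@pvalues)

#' @rdname fit-accessors
#' @export
setGeneric("r2", function(x) standardGeneric("r2"))

#' @rdname fit-accessors
#' @export
setMethod("r2", "FitResult", function(x) x@r2)

#' @rdname fit-accessors
#' @export
setGeneric("fitPvalue", function(x) standardGeneric("fitPvalue"))

#' @rdname fit-accessors
#' @export
setMethod("fitPvalue", "FitResult", function(x) x@fitPvalue)

#' @rdname fit-accessors
#' @export
setGeneric("selectedVariables", function(x) standardGeneric("selectedVariables"))

#' @rdname fit-accessors
#' @export
setMethod("selectedVariables", "FitResult", function(x) x@selected)

#' @importFrom stats coef residuals
NULL

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples (%s, log2(x+1))\n",
              nrow(object), ncol(object), object@unitTag))
})

setMethod("show", "MutationEventTable", function(object) {
  m <- object@events
  cat(sprintf("MutationEventTable: %d genes x %d samples, %d events\n",
              nrow(m), ncol(m), sum(m)))
})

setMethod("show", "RegulonTable", function(object) {
  r <- object@records
  cat(sprintf("RegulonTable: %d records, %d TFs, grades %s\n",
              nrow(r), length(unique(r$tf)),
              paste(sort(unique(r$confidence)), collapse = "")))
})

setMethod("show", "CohortBundle", function(object) {
  cat(sprintf("CohortBundle: %d patients, target gene %s\n",
              length(sampleIDs(object)), object@targetGene))
  cat(sprintf("  mRNA: %d features; miRNA: %s; mutations: %s\n",
              nrow(object@mrna),
              if (is.null(object@mirna)) "absent"
              else sprintf("%d features", nrow(object@mirna)),
              if (is.null(object@mutations)) "absent"
              else sprintf("%d genes", nrow(object@mutations@events))))
})

setMethod("show", "FitResult", function(object) {
  if (object@interceptOnly) {
    cat(sprintf("FitResult: intercept-only (no variable survived), beta0 = %.4g\n",
                object@beta0))
    return(invisible(NULL))
  }
  cat(sprintf("FitResult: %d selected variables, R^2 = %.4f, F-test p = %.3g\n",
              length(object@selected), object@r2, object@fitPvalue))
  tab <- data.frame(coefficient = c(object@beta0, object@betas[object@selected]),
                    p.value = c(NA, object@pvalues[object@selected]),
                    row.names = c("(Intercept)", object@selected))
  print(format(tab, digits = 4))
})

setMethod("show", "SyntheticGroundTruth", function(object) {
  cat(sprintf(paste0("SyntheticGroundTruth: %d patients, %d TFs, ",
                     "%d effect genes, %d effect miRNAs\n"),
              object@config$nPatients, nrow(object@activities),
              length(object@effectGenes), length(object@effectMirnas)))
})
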