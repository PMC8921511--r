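#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors metadata
NULL

.VALID_UNITS <- c("FPKM", "RPM", "synthetic")
.VALID_GRADES <- c("A", "B", "C", "D", "E")

#' Container for a log2-transformed expression matrix
#'
#' An `ExpressionMatrix` holds a features x samples matrix of
#' `log2(x + 1)`-transformed abundance values (mRNA or miRNA), together with
#' a tag recording the pre-transform normalization (`"FPKM"` for mRNA,
#' `"RPM"` for miRNA, `"synthetic"` for simulated cohorts).  It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single assay named
#' `"log2expr"`; feature and sample identifiers are the dimnames.
#'
#' Validity requires unique feature and sample identifiers and finite,
#' non-negative values (raw abundance is non-negative, so the log2(x+1)
#' values are too).
#'
#' @slot unitTag character(1), one of `"FPKM"`, `"RPM"`, `"synthetic"`.
#' @seealso [ExpressionMatrix()], [log2p1Transform()], [readExpressionTable()]
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(unitTag = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character(0)
  if (length(object@unitTag) != 1L || !object@unitTag %in% .VALID_UNITS)
    msg <- c(msg, sprintf("unitTag must be one of %s",
                          paste(.VALID_UNITS, collapse = ", ")))
  if (!"log2expr" %in% names(assays(object)))
    return(c(msg, "assay 'log2expr' is missing"))
  m <- assay(object, "log2expr")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "feature and sample identifiers are required")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, "duplicate feature identifiers")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "duplicate sample identifiers")
  if (!all(is.finite(m)))
    msg <- c(msg, "all expression values must be finite")
  else if (any(m < 0))
    msg <- c(msg, "all log2(x+1) expression values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, features x samples, of log2(x+1) values
#'   with rownames (feature ids) and colnames (sample ids).
#' @param unitTag `"FPKM"`, `"RPM"` or `"synthetic"`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(c(0, 1, 2, 3), 2, 2,
#'             dimnames = list(c("CD274", "IRF1"), c("P1", "P2")))
#' ExpressionMatrix(m, "FPKM")
#' @export
ExpressionMatrix <- function(values, unitTag = c("FPKM", "RPM", "synthetic")) {
  unitTag <- match.arg(unitTag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = list(log2expr = values))
  new("ExpressionMatrix", se, unitTag = unitTag)
}

#' Binary somatic-mutation event table
#'
#' One row per gene, one column per patient; entry 1 means the patient
#' carries at least one somatic mutation in that gene.  Multiple mutations
#' in the same gene of the same patient are collapsed to one event;
#' mutation type and position are ignored.
#'
#' @slot events integer matrix (genes x samples) with entries in \{0, 1\},
#'   rownames = gene ids, colnames = sample ids.
#' @seealso [MutationEventTable()], [readMafEvents()]
#' @export
setClass("MutationEventTable", representation(events = "matrix"))

setValidity("MutationEventTable", function(object) {
  m <- object@events
  msg <- character(0)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "gene and sample identifiers are required")
  if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate sample identifiers")
  if (length(m) && !all(m %in% c(0L, 1L)))
    msg <- c(msg, "event entries must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct a MutationEventTable
#'
#' @param events genes x samples matrix of 0/1 event indicators with
#'   dimnames.
#' @return A [MutationEventTable-class] object.
#' @export
MutationEventTable <- function(events) {
  events <- as.matrix(events)
  storage.mode(events) <- "integer"
  new("MutationEventTable", events = events)
}

#' Regulon table: transcription factor to target-gene mapping
#'
#' Records of (tf, target, confidence) where confidence is an empirical
#' grade from A (most confident) to E (least confident).  (tf, target)
#' pairs are unique.
#'
#' @slot records data.frame with character columns `tf`, `target` and
#'   `confidence`.
#' @seealso [RegulonTable()], [readRegulonTable()], [selectUniqueTargets()]
#' @export
setClass("RegulonTable", representation(records = "data.frame"))

setValidity("RegulonTable", function(object) {
  r <- object@records
  msg <- character(0)
  if (!all(c("tf", "target", "confidence") %in% names(r)))
    return("records must have columns tf, target, confidence")
  if (!all(r$confidence %in% .VALID_GRADES))
    msg <- c(msg, "confidence grades must be in A..E")
  if (anyDuplicated(r[c("tf", "target")]))
    msg <- c(msg, "(tf, target) pairs must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a RegulonTable
#'
#' @param records data.frame with columns `tf`, `target`, `confidence`.
#' @return A [RegulonTable-class] object.
#' @export
RegulonTable <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$tf <- as.character(records$tf)
  records$target <- as.character(records$target)
  records$confidence <- toupper(as.character(records$confidence))
  rownames(records) <- NULL
  new("RegulonTable", records = records)
}

#' Aligned multi-omic cohort bundle
#'
#' Holds the mRNA expression matrix, and optionally the miRNA expression
#' matrix and the mutation event table, all restricted to the same
#' patients in the same order, plus the identifier of the dependent gene
#' whose expression the pipeline models (CD274 in the motivating
#' application).
#'
#' @slot mrna [ExpressionMatrix-class] of mRNA log2 expression.
#' @slot mirna [ExpressionMatrix-class] of miRNA log2 expression, or NULL.
#' @slot mutations [MutationEventTable-class], or NULL.
#' @slot targetGene character(1), must be a feature of `mrna`.
#' @seealso [alignCohort()], [simulateCohort()]
#' @export
setClass("CohortBundle",
  representation(mrna = "ExpressionMatrix", mirna = "ANY",
                 mutations = "ANY", targetGene = "character"))

setValidity("CohortBundle", function(object) {
  msg <- character(0)
  ids <- colnames(assay(object@mrna, "log2expr"))
  if (length(object@targetGene) != 1L ||
      !object@targetGene %in% rownames(assay(object@mrna, "log2expr")))
    msg <- c(msg, "targetGene must be a single feature of the mRNA matrix")
  if (!is.null(object@mirna)) {
    if (!is(object@mirna, "ExpressionMatrix"))
      msg <- c(msg, "mirna must be an ExpressionMatrix or NULL")
    else if (!identical(colnames(assay(object@mirna, "log2expr")), ids))
      msg <- c(msg, "miRNA sample ids differ from mRNA sample ids")
  }
  if (!is.null(object@mutations)) {
    if (!is(object@mutations, "MutationEventTable"))
      msg <- c(msg, "mutations must be a MutationEventTable or NULL")
    else if (!identical(colnames(object@mutations@events), ids))
      msg <- c(msg, "mutation sample ids differ from mRNA sample ids")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted sign-constrained linear model
#'
#' Result of the bounded-fit / OLS-refit selection procedure: the
#' intercept, the coefficients and two-sided t-test p-values of the
#' selected variables, the coefficient of determination, the overall
#' F-test p-value and the per-patient residuals.  The reported
#' coefficients and p-values come from an ordinary least-squares refit on
#' the surviving variable set; the bounded solver is used to zero out
#' sign-violating variables during selection.
#'
#' @slot beta0 numeric(1) intercept.
#' @slot betas named numeric, coefficients of the selected variables.
#' @slot pvalues named numeric, two-sided coefficient p-values.
#' @slot r2 numeric(1) coefficient of determination.
#' @slot fitPvalue numeric(1) overall F-test p-value (NA for an
#'   intercept-only fit).
#' @slot residuals named numeric, per-patient residuals of the refit.
#' @slot selected character, the surviving variable names.
#' @slot ySd numeric(1) standard deviation of the training response
#'   (used for the near-zero-denominator tolerance of [contributions()]).
#' @slot interceptOnly logical(1), TRUE when no variable survived.
#' @seealso [selectModel()], [inferOls()], [contributions()], [vifReport()]
#' @export
setClass("FitResult",
  representation(beta0 = "numeric", betas = "numeric", pvalues = "numeric",
                 r2 = "numeric", fitPvalue = "numeric",
                 residuals = "numeric", selected = "character",
                 ySd = "numeric", interceptOnly = "logical"))

setValidity("FitResult", function(object) {
  msg <- character(0)
  if (!identical(sort(names(object@betas)), sort(object@selected)))
    msg <- c(msg, "betas must be named by the selected variables")
  if (!identical(sort(names(object@pvalues)), sort(object@selected)))
    msg <- c(msg, "pvalues must be named by the selected variables")
  if (length(object@residuals) && object@ySd > 0 &&
      abs(mean(object@residuals)) >= 1e-8 * object@ySd)
    msg <- c(msg, "residual mean must be ~0 for an OLS refit")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' The generating parameters and realized latent quantities of a
#' synthetic cohort: the configuration, the latent per-patient activity of
#' every transcription factor, the identities and effect sizes of the
#' mutated genes and miRNAs that causally shift the target gene, and the
#' regulon table linking each simulated TF to its target-gene block.
#'
#' @slot config the [simulationConfig()] list used for generation.
#' @slot activities numeric matrix, TFs x patients, latent activities.
#' @slot effectGenes character, mutated genes with a causal effect.
#' @slot effectMirnas character, miRNAs with a causal (negative) effect.
#' @slot regulons [RegulonTable-class] of the simulated regulons.
#' @export
setClass("SyntheticGroundTruth",
  representation(config = "list", activities = "matrix",
                 effectGenes = "character", effectMirnas = "character",
                 regulons = "RegulonTable"))

setValidity("SyntheticGroundTruth", function(object) {
  msg <- character(0)
  if (!all(object@effectGenes %in% object@config$geneNames))
    msg <- c(msg, "effectGenes must be among the generated genes")
  if (!all(object@effectMirnas %in% object@config$mirnaNames))
    msg <- c(msg, "effectMirnas must be among the generated miRNAs")
  if (length(msg)) msg else TRUE
})
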