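#' @include AllClasses.R tf-activity.R regression.R prediction-classes.R
#' @include mutation-explanation.R mirna-explanation.R attribution.R
NULL

#' Run the full attribution pipeline on one cohort
#'
#' Executes every stage in order: unique-target selection and TF-activity
#' computation, the sign-constrained TF regression with p < `alpha`
#' selection, contribution and collinearity reports, two-fold
#' classification, the two-pass (accurate-only, then all-patients)
#' critical-gene and critical-miRNA discoveries, the quantile assignment,
#' the combined TF + mutation + miRNA model, and the per-patient
#' attribution.  The attribution uses the all-patients critical sets
#' (where the mutation-burden difference is strongest).  The run is
#' deterministic given the bundle: rerunning yields identical output.
#'
#' @param bundle an aligned [CohortBundle-class]; mutation and miRNA
#'   stages are skipped (with NULL results) when the component is
#'   absent.
#' @param regulons a [RegulonTable-class] for the activity proxies.
#' @param tfs TFs to consider (default: all TFs in `regulons`).
#' @param confidence regulon confidence threshold (`"A"` = highest only).
#' @param alpha TF-model selection threshold.
#' @param combinedAlpha combined-model selection threshold.
#' @param fold classification fold threshold.
#' @param pMaxMut,fcMin,prevalenceMin critical-gene filters.
#' @param pMaxMirna critical-miRNA significance threshold.
#' @param k number of miRNA quantile bins.
#' @param allowNegative TFs allowed a negative coefficient.
#' @return Named list of stage artifacts: `targetSets`, `activity`,
#'   `tfFit`, `contributions`, `vif`, `classification`,
#'   `groupFractions`, `criticalGenesAccurate`, `criticalGenesAll`,
#'   `mutationCounts`, `burdenComparison`, `criticalMirnasAccurate`,
#'   `criticalMirnasAll`, `mirnaAverages`, `quantiles`, `mirnaFit`,
#'   `combinedFit`, `attribution`, `runLog` (seed-free settings record).
#' @examples
#' sim <- simulateCohort(simulationConfig(nPatients = 120, seed = 3))
#' res <- runPipeline(sim$bundle, sim$truth@regulons)
#' res$groupFractions
#' @export
runPipeline <- function(bundle, regulons,
                        tfs = NULL, confidence = "A",
                        alpha = 0.001, combinedAlpha = 0.01, fold = 2,
                        pMaxMut = 0.01, fcMin = 1.5, prevalenceMin = 0.01,
                        pMaxMirna = 0.01, k = 4,
                        allowNegative = "BRD4") {
  stopifnot(is(bundle, "CohortBundle"), is(regulons, "RegulonTable"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(tfs)) tfs <- unique(regulonRecords(regulons)$tf)
  y <- targetExpression(bundle)

  sets <- stage("activity", selectUniqueTargets(
    regulons, tfs, confidence, exclude = targetGene(bundle),
    expressed = featureIDs(mrna(bundle))))
  activity <- stage("activity", computeActivity(mrna(bundle), sets))

  spec <- designSpec(tfs, allowNegative = allowNegative)
  tfFit <- stage("fit", selectModel(y, t(activity), spec, alpha = alpha))
  contrib <- if (length(selectedVariables(tfFit)))
    stage("fit", contributions(tfFit, t(activity))) else NULL
  vif <- if (length(selectedVariables(tfFit)) >= 2L)
    stage("fit", vifReport(t(activity)[, selectedVariables(tfFit),
                                       drop = FALSE])) else NULL

  pred <- predict(tfFit, t(activity))
  cls <- stage("classify", classifyPatients(y, pred, fold = fold))
  accIds <- samplesWithLabel(cls, "accurate")

  critAcc <- critAll <- counts <- burden <- NULL
  if (!is.null(mutations(bundle))) {
    critAcc <- stage("mutations", discoverCriticalGenes(
      y, mutations(bundle), subset = accIds, pMax = pMaxMut,
      fcMin = fcMin, prevalenceMin = prevalenceMin,
      basis = "accurate_only"))
    critAll <- stage("mutations", discoverCriticalGenes(
      y, mutations(bundle), subset = cls$sample, pMax = pMaxMut,
      fcMin = fcMin, prevalenceMin = prevalenceMin,
      basis = "all_patients"))
    counts <- countCritical(mutations(bundle), critAll)
    if (length(samplesWithLabel(cls, "underpredicted")) && length(accIds))
      burden <- stage("mutations", compareGroupBurden(counts, cls))
  }

  mirAcc <- mirAll <- averages <- quant <- mirnaFit <- NULL
  if (!is.null(mirna(bundle))) {
    mirAcc <- stage("mirnas", discoverCriticalMirnas(
      y, mirna(bundle), subset = accIds, pMax = pMaxMirna,
      basis = "accurate_only"))
    mirAll <- stage("mirnas", discoverCriticalMirnas(
      y, mirna(bundle), subset = cls$sample, pMax = pMaxMirna,
      basis = "all_patients"))
    if (nrow(mirAll)) {
      averages <- averageCriticalExpression(mirna(bundle), mirAll)
      quant <- stage("mirnas", assignQuantiles(averages, k = k))
      mirnaFit <- stage("mirnas", fitMirnaModel(y, averages))
    }
  }

  combined <- stage("combined", fitCombined(
    y, activity,
    mutationCounts = counts, mirnaAverage = averages,
    alpha = combinedAlpha, allowNegative = allowNegative))

  attribution <- stage("attribute", attributePatients(
    cls, mutationCounts = counts, quantiles = quant))

  runLog <- list(
    package = "exprAttributor",
    version = as.character(utils::packageVersion("exprAttributor")),
    nPatients = length(y), targetGene = targetGene(bundle),
    tfs = tfs, confidence = confidence,
    thresholds = list(alpha = alpha, combinedAlpha = combinedAlpha,
                      fold = fold, pMaxMut = pMaxMut, fcMin = fcMin,
                      prevalenceMin = prevalenceMin,
                      pMaxMirna = pMaxMirna, k = k))

  list(targetSets = sets, activity = activity, tfFit = tfFit,
       contributions = contrib, vif = vif, classification = cls,
       groupFractions = groupFractions(cls),
       criticalGenesAccurate = critAcc, criticalGenesAll = critAll,
       mutationCounts = counts, burdenComparison = burden,
       criticalMirnasAccurate = mirAcc, criticalMirnasAll = mirAll,
       mirnaAverages = averages, quantiles = quant, mirnaFit = mirnaFit,
       combinedFit = combined, attribution = attribution,
       runLog = runLog)
}
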