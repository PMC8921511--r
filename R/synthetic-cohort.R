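#' @include AllClasses.R cohort-io.R
NULL

.DEFAULT_TFS <- c("MYC", "HIF1A", "HIF2A", "JUN", "IRF1",
                  "STAT1", "STAT3", "NFKB", "NRF2", "BRD4")

#' Configuration of the synthetic-cohort generator
#'
#' Bundles and validates every generating parameter of
#' [simulateCohort()].  The generator emulates the statistical structure
#' the downstream analysis assumes: latent per-patient TF activities
#' drive disjoint blocks of target genes; the dependent gene is a linear
#' combination of a subset of the activities, plus additive shifts from
#' sparse mutation events and from a few negatively acting miRNAs, plus
#' Gaussian noise on the log2 scale.  All expression is generated
#' directly on the log2 scale (unit tag `"synthetic"`).
#'
#' Defaults (see the methods vignette for the rationale): 1000 patients,
#' the ten canonical PD-L1-regulating TFs with true coefficients
#' IRF1 = 0.6, STAT1 = 0.5, NFKB = 0.8 and 0 elsewhere, intercept -4,
#' activities Normal(4, 1), 20 target genes per TF with target noise SD
#' 0.5, residual noise SD 0.5 log2 units, 5 effect genes mutated at
#' prevalence 0.03 shifting the target by +1.5 log2 units, 50 background
#' genes, 3 effect miRNAs with coefficient -0.3 on Normal(1, 1) levels
#' (floored at 0 before entering the linear predictor), 50 background
#' miRNAs.
#'
#' @param nPatients number of patients.
#' @param tfNames TF names; negative `trueBeta` is allowed only for BRD4.
#' @param targetsPerTF target-gene block size per TF.
#' @param trueBeta named numeric of true TF coefficients; omitted TFs get 0.
#' @param intercept intercept of the generating model (log2 units).
#' @param noiseSigma residual noise SD (log2 units), > 0.
#' @param activityMean,activitySd moments of the latent activities.
#' @param targetNoiseSd SD of the target-gene noise around the activity.
#' @param nEffectGenes,nBackgroundGenes mutated genes with / without a
#'   causal target-gene effect.
#' @param mutationPrevalence per-gene carrier fraction, in (0, 1).
#' @param mutationEffect additive log2 shift of the target per carried
#'   effect-gene event.
#' @param nEffectMirnas,nBackgroundMirnas miRNAs with / without effect.
#' @param mirnaEffect coefficient (<= 0) linking each effect miRNA's
#'   level to the target.
#' @param mirnaMean,mirnaSd moments of the miRNA levels (floored at 0).
#' @param seed integer seed; the same seed gives bit-identical cohorts.
#' @return A validated configuration list of class `"simulationConfig"`.
#' @seealso [simulateCohort()], [nullCohort()]
#' @export
simulationConfig <- function(nPatients = 1000,
                             tfNames = .DEFAULT_TFS,
                             targetsPerTF = 20,
                             trueBeta = c(IRF1 = 0.6, STAT1 = 0.5, NFKB = 0.8),
                             intercept = -4,
                             noiseSigma = 0.5,
                             activityMean = 4, activitySd = 1,
                             targetNoiseSd = 0.5,
                             nEffectGenes = 5, nBackgroundGenes = 50,
                             mutationPrevalence = 0.03, mutationEffect = 1.5,
                             nEffectMirnas = 3, nBackgroundMirnas = 50,
                             mirnaEffect = -0.3,
                             mirnaMean = 1, mirnaSd = 1,
                             seed = 1L) {
  beta <- setNames(numeric(length(tfNames)), tfNames)
  if (length(trueBeta)) {
    unknown <- setdiff(names(trueBeta), tfNames)
    if (length(unknown))
      stop(sprintf("trueBeta names not in tfNames: %s",
                   paste(unknown, collapse = ", ")))
    beta[names(trueBeta)] <- trueBeta
  }
  counts <- c(nPatients = nPatients, targetsPerTF = targetsPerTF,
              nEffectGenes = nEffectGenes, nBackgroundGenes = nBackgroundGenes,
              nEffectMirnas = nEffectMirnas,
              nBackgroundMirnas = nBackgroundMirnas)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("all counts must be non-negative integers")
  if (nPatients < 1 || targetsPerTF < 1)
    stop("nPatients and targetsPerTF must be >= 1")
  if (!is.finite(noiseSigma) || noiseSigma <= 0)
    stop("noiseSigma must be > 0")
  if (mutationPrevalence <= 0 || mutationPrevalence >= 1)
    stop("mutationPrevalence must be in (0, 1)")
  neg <- names(beta)[beta < 0]
  if (length(setdiff(neg, "BRD4")))
    stop("negative trueBeta is allowed only for BRD4")
  if (mirnaEffect > 0)
    stop("mirnaEffect must be <= 0 (miRNAs are modeled as negative regulators)")
  if (anyDuplicated(tfNames)) stop("duplicated TF names")
  structure(list(
    nPatients = as.integer(nPatients), tfNames = tfNames,
    targetsPerTF = as.integer(targetsPerTF), trueBeta = beta,
    intercept = intercept, noiseSigma = noiseSigma,
    activityMean = activityMean, activitySd = activitySd,
    targetNoiseSd = targetNoiseSd,
    nEffectGenes = as.integer(nEffectGenes),
    nBackgroundGenes = as.integer(nBackgroundGenes),
    mutationPrevalence = mutationPrevalence, mutationEffect = mutationEffect,
    nEffectMirnas = as.integer(nEffectMirnas),
    nBackgroundMirnas = as.integer(nBackgroundMirnas),
    mirnaEffect = mirnaEffect, mirnaMean = mirnaMean, mirnaSd = mirnaSd,
    seed = as.integer(seed)), class = "simulationConfig")
}

#' Simulate a cohort with known ground truth
#'
#' Draws latent TF activities `a_t ~ Normal(activityMean, activitySd)`
#' per patient and TF; each TF's block of `targetsPerTF` target genes is
#' that activity plus independent Normal(0, targetNoiseSd) noise, and the
#' blocks of different TFs are disjoint.  Mutation events are Bernoulli
#' with the configured prevalence.  miRNA levels are Normal, floored at 0
#' (log2(x+1) values cannot be negative); the floored level is what
#' enters the linear predictor, so the generating model remains exactly
#' linear in the observed covariates.  The dependent gene is
#'
#' `intercept + sum_t beta_t a_t + sum(effect genes) mutationEffect * event
#'  + sum(effect miRNAs) mirnaEffect * level + Normal(0, noiseSigma)`,
#'
#' floored at 0 and stored as an already-log2 value.  The same seed gives
#' bit-identical output; all draws flow through one generator stream.
#'
#' @param config a [simulationConfig()] list.
#' @return list with elements `bundle` (a [CohortBundle-class] carrying
#'   mRNA, miRNA and mutation components over the same patients) and
#'   `truth` (a [SyntheticGroundTruth-class] with the realized latent
#'   activities, the effect-gene/effect-miRNA identities and the regulon
#'   table linking each TF to its target block).
#' @examples
#' sim <- simulateCohort(simulationConfig(nPatients = 50, seed = 7))
#' sim$bundle
#' @export
simulateCohort <- function(config = simulationConfig()) {
  if (!inherits(config, "simulationConfig"))
    stop("config must come from simulationConfig()")
  cf <- config
  set.seed(cf$seed)
  pts <- sprintf("SYN-%04d", seq_len(cf$nPatients))
  tfs <- cf$tfNames
  nTF <- length(tfs)

  # latent activities and disjoint target-gene blocks
  act <- matrix(stats::rnorm(nTF * cf$nPatients, cf$activityMean, cf$activitySd),
                nrow = nTF, dimnames = list(tfs, pts))
  targetNames <- unlist(lapply(tfs, function(tf)
    sprintf("%s_T%02d", tf, seq_len(cf$targetsPerTF))))
  targetTF <- rep(tfs, each = cf$targetsPerTF)
  targets <- act[targetTF, , drop = FALSE] +
    matrix(stats::rnorm(length(targetNames) * cf$nPatients, 0, cf$targetNoiseSd),
           nrow = length(targetNames))
  targets <- pmax(targets, 0)
  rownames(targets) <- targetNames

  # mutation events
  geneNames <- c(if (cf$nEffectGenes) sprintf("EFFGENE%02d", seq_len(cf$nEffectGenes)),
                 if (cf$nBackgroundGenes) sprintf("BGGENE%03d", seq_len(cf$nBackgroundGenes)))
  events <- NULL
  if (length(geneNames)) {
    events <- matrix(stats::rbinom(length(geneNames) * cf$nPatients, 1L,
                                   cf$mutationPrevalence),
                     nrow = length(geneNames),
                     dimnames = list(geneNames, pts))
  }
  effectGenes <- grep("^EFFGENE", geneNames, value = TRUE)

  # miRNA levels, floored at 0 before use
  mirnaNames <- c(if (cf$nEffectMirnas) sprintf("mir-eff-%02d", seq_len(cf$nEffectMirnas)),
                  if (cf$nBackgroundMirnas) sprintf("mir-bg-%03d", seq_len(cf$nBackgroundMirnas)))
  mirnaMat <- NULL
  if (length(mirnaNames)) {
    mirnaMat <- pmax(matrix(stats::rnorm(length(mirnaNames) * cf$nPatients,
                                         cf$mirnaMean, cf$mirnaSd),
                            nrow = length(mirnaNames),
                            dimnames = list(mirnaNames, pts)), 0)
  }
  effectMirnas <- grep("^mir-eff", mirnaNames, value = TRUE)

  y <- cf$intercept + drop(crossprod(act, cf$trueBeta[tfs]))
  if (length(effectGenes))
    y <- y + cf$mutationEffect *
      colSums(events[effectGenes, , drop = FALSE])
  if (length(effectMirnas))
    y <- y + cf$mirnaEffect *
      colSums(mirnaMat[effectMirnas, , drop = FALSE])
  y <- y + stats::rnorm(cf$nPatients, 0, cf$noiseSigma)
  y <- pmax(y, 0)

  mrnaMat <- rbind(targets, CD274 = y)
  bundle <- new("CohortBundle",
                mrna = ExpressionMatrix(mrnaMat, "synthetic"),
                mirna = if (is.null(mirnaMat)) NULL
                        else ExpressionMatrix(mirnaMat, "synthetic"),
                mutations = if (is.null(events)) NULL
                            else MutationEventTable(events),
                targetGene = "CD274")

  regulons <- RegulonTable(data.frame(tf = targetTF, target = targetNames,
                                      confidence = "A"))
  cf$geneNames <- geneNames
  cf$mirnaNames <- mirnaNames
  truth <- new("SyntheticGroundTruth", config = unclass(cf),
               activities = act, effectGenes = effectGenes,
               effectMirnas = effectMirnas, regulons = regulons)
  list(bundle = bundle, truth = truth)
}

#' Simulate a null cohort (background only)
#'
#' Convenience wrapper around [simulateCohort()] with all mutation and
#' miRNA effects set to zero: the genes and miRNAs are still generated
#' (as background features) but none of them shifts the dependent gene.
#' Used for type-I-error testing of the discovery stages.
#'
#' @param config a [simulationConfig()] list; its effect counts are moved
#'   into the background counts and the effect sizes zeroed.
#' @return As [simulateCohort()]; the ground truth has empty effect lists.
#' @export
nullCohort <- function(config = simulationConfig()) {
  if (!inherits(config, "simulationConfig"))
    stop("config must come from simulationConfig()")
  cf <- unclass(config)
  cf$nBackgroundGenes <- cf$nBackgroundGenes + cf$nEffectGenes
  cf$nEffectGenes <- 0L
  cf$nBackgroundMirnas <- cf$nBackgroundMirnas + cf$nEffectMirnas
  cf$nEffectMirnas <- 0L
  cf$mutationEffect <- 0
  cf$mirnaEffect <- 0
  cf$trueBeta <- cf$trueBeta[cf$trueBeta != 0]
  out <- do.call(simulationConfig, cf[setdiff(names(cf),
                                              c("geneNames", "mirnaNames"))])
  simulateCohort(out)
}

#' Write the four standard cohort files plus a ground-truth JSON
#'
#' Writes the mRNA TSV, the miRNA TSV, a minimal MAF and the regulon TSV
#' for a simulated cohort, plus `ground_truth.json` recording the
#' generating parameters and effect lists.
#'
#' @param sim the list returned by [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeCohortFiles <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- sim$bundle; tr <- sim$truth
  paths <- c(mrna = file.path(dir, "mrna_log2.tsv"),
             mirna = file.path(dir, "mirna_log2.tsv"),
             maf = file.path(dir, "mutations.maf"),
             regulons = file.path(dir, "regulons.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  writeExpressionTable(mrna(b), paths["mrna"])
  if (!is.null(mirna(b))) writeExpressionTable(mirna(b), paths["mirna"])
  if (!is.null(mutations(b))) writeMafEvents(mutations(b), paths["maf"])
  writeRegulonTable(tr@regulons, paths["regulons"])
  gt <- tr@config
  gt$trueBeta <- as.list(gt$trueBeta)
  gt$effectGenes <- tr@effectGenes
  gt$effectMirnas <- tr@effectMirnas
  jsonlite::write_json(gt, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
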