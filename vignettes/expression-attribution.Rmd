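---
title: "Attributing target-gene expression to TF activity, mutations and miRNAs"
author: "exprAttributor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing target-gene expression to TF activity, mutations and miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(exprAttributor))
```

## The question and the model

Immune-checkpoint biology makes the expression level of *CD274* (encoding
PD-L1) a quantity worth decomposing: in any one tumor, how much of the
observed mRNA level is driven by the transcription factors known to act on
the *CD274* promoter, and what explains the patients whose expression is far
higher than those TFs can account for?  `exprAttributor` implements that
decomposition as a pipeline over per-patient bulk expression, somatic
mutation calls and miRNA abundance.

**TF activity from regulons.**  A TF's own transcript is a poor proxy for
its activity (many TFs are regulated by nuclear translocation, not
transcription), so activity is estimated from its *regulon*: the per-patient
mean of the log2(x+1) expression of its target genes.  Targets are filtered
to the highest confidence grade, restricted to genes unique to a single TF
among those considered (shared targets carry ambiguous signal), and the
dependent gene itself is excluded so the response never feeds its own
predictor.  The default TF panel is the ten canonical PD-L1 regulators:
MYC, HIF1A, HIF2A, JUN, IRF1, STAT1, STAT3, NFKB, NRF2 and BRD4 (BRD4
regulons are supplied by the user or the simulator; it is treated like any
other TF).

**The sign-constrained regression.**  Per patient $i$ the model is

$$y_i = \beta_0 + \beta_1 x_{i1} + \dots + \beta_n x_{in} + \varepsilon_i,$$

with $y_i$ the log2 target expression and $x_{ij}$ the activity of TF $j$.
All TFs considered here are activators except (possibly) BRD4, so the fit
is bounded-variable least squares (BVLS): every coefficient is constrained
non-negative except BRD4's and the intercept.  Selection iterates a bounded
fit, removal of variables pinned at a zero bound, an ordinary
least-squares refit on the survivors, and backward elimination of the
least significant survivor until every coefficient has $p <$ `alpha`
(0.001 by default, one variable removed per iteration, ties broken
lexicographically so the procedure is deterministic and order-invariant).

*A deliberate interpretation:* p-values are not well defined under active
inequality constraints, so the package uses BVLS only to decide which
variables respect their signs and reports all inference (coefficients,
p-values, $R^2$, the overall F-test) from the unconstrained refit on the
surviving set.  When no constraint is active the two fits coincide
exactly, which is the situation every final model reported here ends in.

Coefficients are translated into per-patient percentage contributions
$$C_{ij} = \frac{\beta_j x_{ij}}{\sum_k \beta_k x_{ik}} \times 100\%,$$
whose denominator excludes the intercept and keeps negative terms, so
contributions always sum to 100% per patient even when a negative BRD4
term pushes one of them above 100%.  Multicollinearity of the selected
design is screened with variance inflation factors,
$\mathrm{VIF}_i = 1/(1 - R_i^2)$ with $R_i^2$ from regressing predictor
$i$ on the others; VIF 1 means orthogonality, above 4 problematic
estimation, above 10 substantial collinearity.

**Stratification.**  Patients are classified by the gap between observed
and predicted expression on the log2 scale: a gap above $\log_2 2 = 1$
means a more-than-two-fold difference, giving the *underpredicted*
(observed ≫ predicted) and *overpredicted* groups.  The threshold is
applied to the stored log2(x+1) values; the pseudo-count's distortion of
"two-fold" near zero expression is accepted and documented, because the
analysis only ever sees the transformed values.

**Attribution.**  For underpredicted patients two explanation channels are
screened, each in two passes (first on the accurately predicted patients
only, then on the whole cohort, whose critical sets are the ones used for
attribution since they separate the groups most strongly):

* *Critical genes* — genes whose mutated carriers (multiple mutations per
  gene and patient collapse to one event; type and position ignored) show
  elevated target expression: carrier prevalence > 1% within the analysis
  subset, fold change $2^{\bar y_\mathrm{mut} - \bar y_\mathrm{wt}} > 1.5$
  (a geometric-mean ratio, the natural choice when only log2 values
  exist; a linear-scale option is provided), and two-sided Mann–Whitney
  $p < 0.01$.  No multiple-testing correction is applied — the raw-p
  filter plus the fold-change floor is the published convention this
  pipeline reproduces — and an FDR flag would sit naturally on top.
* *Critical miRNAs* — miRNAs whose abundance correlates negatively with
  target expression (Pearson $r < 0$, $p < 0.01$).  Patients are binned
  by cohort quartiles of their mean critical-miRNA abundance into
  low / lower-midrange / upper-midrange / high; a value equal to a cut
  point falls in the upper bin (low: $< q_1$, …, high: $\ge q_3$).

Each underpredicted patient is then labeled **mutation** (≥ 1 critical
mutation), **miRNA** (lowest quantile), **mutation+miRNA** (both) or
**unexplained** (neither); accurately predicted and overpredicted patients
are labeled **TF** — the enum has no separate overprediction category and
overpredicted expression is, if anything, over-accounted by TF activity —
so the categories partition the cohort.  A combined regression augments
the TF design with the critical-mutation count (bounded ≥ 0) and the mean
critical-miRNA abundance (bounded ≤ 0, mirroring the strictly negative
regulator model; an unconstrained option exists) at $p < 0.01$.

**Generalization.**  Cohorts can be pooled, split 80/20 into train and
test sets, refitted on the training pool and evaluated as the fraction of
held-out (and fully external) patients predicted within the two-fold
band; repeated splits report per-seed coefficient tables rather than an
averaged model, so coefficient stability is inspectable.

## The synthetic cohort generator

Real tumor cohorts cannot ship with a package, and the pipeline's
correctness claims need known ground truth, so `simulateCohort()`
generates cohorts with exactly the structure the analysis assumes:

* latent TF activities $a_t \sim \mathcal N(4, 1)$ per patient (log2
  units, the scale of typical moderately expressed genes);
* 20 target genes per TF, each the TF's activity plus
  $\mathcal N(0, 0.5)$ noise, blocks disjoint across TFs;
* the target gene
  $y = \beta_0 + \sum_t \beta_t a_t + \sum_g 1.5\,\mathrm{event}_g +
  \sum_m (-0.3)\, \mathrm{level}_m + \mathcal N(0, \sigma)$, floored at 0
  and stored as an already-log2 value;
* true coefficients IRF1 0.6, STAT1 0.5, NFKB 0.8, all other TFs 0,
  intercept −4 (negative, as fitted intercepts on real cohorts are);
* 5 effect genes and 50 background genes mutated independently at 3%
  prevalence; 3 effect miRNAs and 50 background miRNAs with levels
  $\max(0, \mathcal N(1, 1))$ — the floored level is what enters the
  linear predictor, so the generating model stays exactly linear in the
  observed covariates and the floor introduces no model misspecification.

**Why $\sigma = 0.5$.**  The residual noise default matters for what the
underpredicted group *is*.  At $\sigma = 1$ about 16% of patients exceed
the one-log2-unit band through noise alone; the underpredicted group is
then dominated by patients with no mutation or miRNA cause, which no
attribution rule can explain — the opposite of the regime the pipeline is
designed for, where most underprediction has a discoverable cause.  At
$\sigma = 0.5$ the noise-only exceedance is $1 - \Phi(2) \approx 2.3\%$,
matching the low end of underpredicted fractions seen in real cohorts,
and the injected mutation (+1.5 log2 at 3% prevalence per effect gene)
and miRNA effects dominate the group.  This a-priori power analysis,
not any test outcome, fixed the default; $\sigma$ is a config knob and
several checks deliberately run at $\sigma = 1$.

The miRNA defaults (3 effect miRNAs, coefficient −0.3, levels centered at
1 log2 RPM) keep the generator's mean target expression near 2.9 with
marginal SD ≈ 1.3, so fewer than ~2% of patients hit the floor at 0 —
enough to respect the non-negativity invariant without biasing
coefficient recovery.  One seed drives a single generator stream, so the
same configuration is bit-reproducible.

What the generator deliberately does **not** emulate: TCGA marginal
distributions, gene-length or GC bias, batch effects, mutational
signatures, miRNA family structure, or any nonlinearity in the
mutation/miRNA effects.  Green tests therefore certify the pipeline's
statistical machinery under its own assumptions, not its biological
conclusions on real data.

## Worked example

```{r example}
sim <- simulateCohort(simulationConfig(seed = 1))
res <- suppressMessages(runPipeline(sim$bundle, sim$truth@regulons))
res$tfFit
round(100 * res$groupFractions, 1)
res$criticalGenesAll
round(res$attribution$summary$underpredicted, 3)
```

The fitted model recovers the three planted TFs with coefficients close
to (0.6, 0.5, 0.8); all five effect genes reappear as critical genes; and
only a few percent of the underpredicted group remains unexplained.

## Numerical and design choices

* **Solver.**  The BVLS solver is an active-set method (free-set least
  squares via QR, feasible-step line search, KKT check on bound
  variables) — exact for this convex problem and oracle-tested against
  closed-form OLS and a grid search.  Coefficients at an active bound
  are returned exactly at the bound value.
* **Degenerate inputs.**  Rank-deficient free sets raise an error rather
  than silently dropping columns; a constant response makes every
  p-value undefined and selection then returns the flagged
  intercept-only fit; contribution denominators smaller than
  $10^{-9}\,\mathrm{sd}(y)$ flag the patient as undefined and exclude it
  from the mean/SD summary; zero-variance miRNAs and genes with fewer
  than two patients per arm are skipped and counted.
* **Mann–Whitney conventions.**  Exact enumeration (via
  `stats::wilcox.test`) when both arms have ≤ 8 observations and no
  ties — so small worked examples match exhaustive enumeration
  exactly — and the tie-corrected normal approximation otherwise.
  Pearson screen p-values use the exact t reference, vectorised across
  thousands of miRNAs.
* **Quantile ties.**  Cut points are type-7 empirical quartiles;
  massive ties that empty a bin are flagged and reported as-is rather
  than silently re-binned.
* **Prevalence denominator.**  Carrier prevalence is computed within the
  analysis subset (the accurate group in the first pass), since that is
  the population the test is run on.
* **Problem sizes in the test suite.**  Simulation-based checks use
  cohorts of 200–5000 patients and 100–1500 replicates, sizes at which
  the monitored binomial/Poisson error bars are a fraction of the
  margins being asserted.

## Limitations

The pipeline inherits the method's own blind spots: it is linear in the
activity proxies (large mutation or miRNA effects are screened, not
modeled nonlinearly); activity proxies fail for TFs whose regulation is
invisible in target-transcript means; coding-region mutation calls miss
regulatory variants; and attribution is associational — a "mutation"
label marks a patient consistent with the mutation channel, not a proven
cause.  Sample identifiers are matched exactly after whitespace trimming;
TCGA-barcode normalization and multi-sample patient de-duplication are
left to the user.
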