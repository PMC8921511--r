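# exprAttributor

Quantifying how much of a target gene's per-patient mRNA expression is
explained by transcription-factor activity — and attributing the rest.

The motivating application is *CD274* (PD-L1) in tumor cohorts: its
expression integrates promoter-acting transcription factors, somatic
mutations and post-transcriptional repression by miRNAs, and knowing
*which* channel drives a given patient's high expression matters for
checkpoint-blockade biology.  `exprAttributor` implements the full
decomposition for any target gene:

1. **TF activity** is proxied per patient by the mean log2(x+1)
   expression of each TF's unique, highest-confidence regulon targets
   (the target gene itself excluded).
2. **Sign-constrained regression.**  The target's log2 expression is
   modeled as

   *y* = β₀ + β₁x₁ + … + βₙxₙ + ε,

   fitted by bounded-variable least squares with every TF coefficient
   constrained ≥ 0 (BRD4, a plausible repressor, and the intercept are
   unbounded), keeping only TFs with non-zero coefficients and
   *p* < 0.001 in an ordinary least-squares refit.  Coefficients are
   translated into per-patient percentage contributions
   C = βⱼxᵢⱼ / Σₖβₖxᵢₖ × 100% (they sum to 100% per patient), and the
   selected design is screened with variance inflation factors
   VIFᵢ = 1/(1 − Rᵢ²).
3. **Stratification.**  Patients whose observed expression exceeds the
   prediction by more than two-fold (1 log2 unit) form the
   *underpredicted* group; the symmetric *overpredicted* group is
   labeled but not analysed further.
4. **Attribution.**  Underpredicted expression is attributed to
   *critical genes* (mutation carriers with prevalence > 1%, fold change
   > 1.5 and Mann–Whitney *p* < 0.01) and/or *critical miRNAs*
   (negatively correlated with the target, Pearson *p* < 0.01; patients
   binned by quartiles of mean critical-miRNA abundance), each screened
   first on accurately predicted patients and then on the whole cohort.
   A combined TF + mutation-count + miRNA-average model and an 80/20
   train/test generalization across pooled cohorts round out the
   analysis.

A synthetic-cohort generator with recorded ground truth
(`simulateCohort()`) reproduces exactly the statistical structure the
analysis assumes, so every stage is testable without external data.  The
methods vignette (`vignettes/expression-attribution.Rmd`) documents the
model, the generator and all numerical choices.

## Worked example

```r
library(exprAttributor)

sim <- simulateCohort(simulationConfig(seed = 1))   # 1000 patients
res <- runPipeline(sim$bundle, sim$truth@regulons)

res$tfFit
#> FitResult: 3 selected variables, R^2 = 0.5909, F-test p = 9.52e-193
#>             coefficient    p.value
#> (Intercept)     -4.1870         NA
#> IRF1             0.5408  5.480e-68
#> STAT1            0.4523  1.916e-51
#> NFKB             0.7729 2.433e-121

round(100 * res$groupFractions, 1)
#>       accurate underpredicted  overpredicted
#>           75.6           13.3           11.1

res$criticalGenesAll
#>        gene            p foldChange prevalence        basis
#> 1 EFFGENE01 7.240368e-09   3.769037      0.030 all_patients
#> 2 EFFGENE03 1.246506e-08   2.867711      0.034 all_patients
#> 3 EFFGENE05 6.096002e-07   2.664505      0.040 all_patients
#> 4 EFFGENE04 9.204444e-07   2.553246      0.036 all_patients
#> 5 EFFGENE02 2.110981e-05   2.390157      0.031 all_patients

round(res$attribution$summary$underpredicted, 3)
#>             TF       mutation          miRNA mutation+miRNA    unexplained
#>          0.000          0.451          0.188          0.316          0.045
```

The selection recovers exactly the three TFs that truly drive the
simulated target (true β: IRF1 0.6, STAT1 0.5, NFKB 0.8) with estimates
within sampling error; all five genes simulated with a +1.5 log2
mutation effect reappear as critical genes (fold changes 2.4–3.8, i.e.
carriers above 2^1.5 ≈ 2.8-fold after noise); and 95.5% of the
underpredicted group is explained by mutations, low critical-miRNA
abundance, or both.  Selected-design VIFs are ~1.00, confirming the
unique-target construction decorrelates the activity proxies.

A command-line front end over the same functions is installed with the
package (`inst/scripts/expr-attributor.R`), with subcommands
`simulate`, `activity`, `fit`, `classify`, `mutations`, `mirnas`,
`attribute` and `run`.

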