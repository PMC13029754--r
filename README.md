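# dualnod

Dual-transcriptome analysis of legume–rhizobium nodules in R.

Mature nitrogen-fixing nodules contain two genomes' worth of mRNA at once:
the plant host's (dominant) and the endosymbiotic rhizobia's (a few percent
of reads). `dualnod` is for researchers comparing nodules induced by
different rhizobial strains — here a two-treatment design, strains `WE2` vs
`WWL2`, three biological replicates — who need the full downstream path from
paired host/symbiont count matrices to candidate genes:

* **IO & accounting** — dense/sparse count matrices, GMT gene sets, sample
  metadata, and the mixed-library *rhizobial mapped rate*
  (100 · symbiont-mapped / total clean reads, typically 1.64–5.04%).
* **Preprocessing** — adaptive low-expression filtering (CPM ≥
  10/median-lib-in-millions in ≥ k samples, total ≥ 15) and TMM
  normalization implemented from first principles (30%/5% trims,
  precision weights, geometric-mean-1 factors).
* **Differential expression** — a conditional exact negative-binomial test
  (`Var = μ + φμ²`, method-of-moments dispersion with shrinkage toward the
  median), BH-FDR, DEGs at FDR < 0.05 and |log₂FC| ≥ 1 with the global
  orientation log₂FC = log₂(WWL2/WE2), and sample PCA.
* **Module scores** — the per-sample gene-set statistic
  `Score_j = mean_i z_ij` with `z_ij` the per-gene z-score of
  `log2(FPKM + 1)`; scores sum to zero across samples, so 3-vs-3 group
  means are exact ± pairs. Cross-partner **coupling** is tested by Pearson
  correlation with the exact t-transform
  (`t = r√(n−2)/√(1−r²)`; r = 0.923, n = 6 → p ≈ 0.0087).
* **Enrichment** — one-sided hypergeometric over-representation against
  user-supplied GMT catalogs, BH-adjusted.
* **Phenotype & qPCR** — Welch t-tests, acetylene-reduction rates per gram
  nodule fresh weight, `2^-ΔΔCt` relative expression, and qPCR/RNA-seq
  direction concordance.
* **Synthetic experiments** — `simulate_experiment()` generates a complete
  calibrated dual-transcriptome study (counts, metadata, truth labels,
  phenotypes, qPCR) with planted module-concentrated effects and a latent
  factor coupling a host supply module to a symbiont N-fixation module.
* **Pipeline** — `run_all()` orchestrates everything under one seeded
  config and writes tab-separated outputs plus a JSON summary.

## Worked example

```r
library(dualnod)

sim <- simulate_experiment(sim_config(seed = 1))
sim$samples[, c("sample_id", "treatment", "total_clean_reads", "symbiont_mapped")]
round(mapped_rate(sim$samples$symbiont_mapped, sim$samples$total_clean_reads), 2)
#> [1] 2.55 2.95 1.69 2.94 4.60 2.80       # all inside the 1.64-5.04% band

kept <- filter_low_expression(sim$symbiont, sim$samples)
cf   <- unclass(sim$symbiont)[kept, ]
de   <- de_analysis(cf, sim$samples, tmm_factors(cf))
attr(de, "summary")
#>  n_total  n_higher_in_WE2 n_higher_in_WWL2
#>      112               27               85

ann <- setNames(sim$annotation$length_bp, sim$annotation$gene_id)
sc  <- module_scores(fpkm(cf, ann), Filter(function(m) m$partner == "symbiont", sim$modules))
score_group_summary(sc, sim$samples)[, 1:5]
#>             module_id mean_WE2 letter_WE2 mean_WWL2 letter_WWL2
#>           symbiontFix    0.610          a    -0.610           a
#>     nodulationSurface   -0.831          b     0.831           a
#>    chemotaxisMotility   -0.768          b     0.768           a
#>     transportNutrient   -0.757          b     0.757           a

sch <- module_scores(fpkm(sim$host, ann), sim$modules["hostSupply"])
coupling(unclass(sch)[1, ], unclass(sc)["symbiontFix", ])
#> module coupling: Pearson r = 0.998, p = 4.79e-06, n = 6
```

The mapped rates show the host-dominant accounting; the DEG summary counts
genes higher in each strain's nodules; group-mean scores come in exact ±
pairs with Welch-test letters (different letters = p < 0.05); and the
host-supply × symbiont-fixation coupling recovers the planted latent factor
(ρ = 0.9) as a strongly positive correlation.

Classifying printed per-gene statistics works directly on a data frame:

```r
call_degs(data.frame(gene_id = "ENOD93", log2fc = -2.079, fdr = 1.53e-10))$status
#> higher_in_WE2
```

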