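# rhizonet

Analysis pipeline for paired two-condition rhizosphere microbiome
surveys — the design used to ask how an invading plant reshapes the soil
fungal community relative to neighbouring native vegetation.  Given an
OTU count table, QIIME-style taxonomy and sample metadata with soil
variables, rhizonet computes:

* **Diversity** — seeded rarefaction, richness and Shannon index,
  Bray–Curtis PCoA, and the ANOSIM permutation test
  (R = (r̄_between − r̄_within)/(M/2) on ranked distances).
* **Biomarkers** — per-rank two-class discovery: Kruskal–Wallis screen
  (α = 0.05) followed by a bootstrap linear-discriminant effect size,
  score = log10(1 + ½(|w_j d_j| + |d_j|)) with a unit-norm discriminant
  w, thresholded at 3.0.
* **Co-occurrence networks** — per condition group: >50% prevalence
  filter, Spearman edges (|ρ| > 0.6, p < 0.05, signs kept), seeded
  Louvain modules, within-module degree z-score Zi and participation
  coefficient Pi = 1 − Σ(k_it/k_i)², node roles at Zi = 2.5 / Pi = 0.62,
  keystone taxa (the non-peripheral roles) and their between-group
  comparison.
* **Soil associations** — iterative VIF screen (threshold 10), canonical
  correspondence analysis with per-variable Monte Carlo tests,
  phylum × soil Spearman correlation matrix, and LMG decomposition of a
  linear model's R² into per-predictor importance shares.

A seeded synthetic-data generator (`synth_preset44()`: 22 paired sites,
44 samples, logistic-normal → multinomial counts) plants known
biomarkers, correlated OTU modules with hub nodes, and soil couplings,
so every stage is verifiable against ground truth without any raw
sequencing data.

## Worked example

```r
library(rhizonet)

cfg <- pipeline_config(synth = synth_preset44(seed = 7),
                       n_permutations = 999, seed = 7)
res <- run_pipeline(cfg, out_dir = "run7")

res$anosim[c("statistic", "p_value")]
#> $statistic [1] 0.6644  $p_value [1] 0.001
round(100 * res$pcoa$explained[1:2], 1)
#> [1] 18.6 14.2
subset(res$lefse, passes & rank == "genus")[, c("taxon", "enriched_group", "lda_score")]
#>        taxon enriched_group lda_score
#>   Alternaria              N      4.44
#>   Chaetomium             AP      4.38
#>  Colacogloea             AP      4.38
#>    Dioszegia             AP      4.38
#>          ...
res$networks$AP$topology
#>  node_count edge_count positive_edge_fraction average_degree modularity
#>         210        657                  0.779           6.26      0.547
```

The ANOSIM block says the invaded and native communities differ
(R = 0.66 at the permutation floor p = 0.001 — the synthetic preset
plants a strong contrast), the first two principal coordinates carry
18.6% and 14.2% of the Bray–Curtis variance, the five planted genera are
recovered with the correct enrichment direction at LDA scores above the
3.0 threshold, and the invaded-group network summarises 210 nodes /
657 edges with 78% positive edges.  `run7/` holds every stage's tables,
GraphML networks and a JSON manifest with the per-stage child seeds;
rerunning with the same config is byte-identical.

Real data enters the same way through file paths:

```r
cfg <- pipeline_config(counts = "otu_table.tsv", taxonomy = "taxonomy.tsv",
                       metadata = "metadata.tsv", seed = 1)
```

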