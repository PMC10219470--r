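---
title: "Methods: diversity, biomarkers, co-occurrence networks and soil associations in rhizonet"
author: "rhizonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, biomarkers, co-occurrence networks and soil associations in rhizonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizonet)
```

## Scope

rhizonet analyses paired two-condition microbiome surveys of the kind used
to study plant invasion: rhizosphere soil sampled at a set of sites, once
under the invading plant ("AP", for an invading *Amaranthus* population)
and once under neighbouring native vegetation ("N"), profiled as an OTU
count table with taxonomy and seven soil variables (pH, TC, TN, TP, AN,
NN, AP).  The pipeline covers five analysis stages — rarefaction and
diversity, two-class biomarker discovery, per-condition co-occurrence
networks with keystone classification, and soil–community association —
plus a synthetic-data generator that plants known structure so every stage
can be verified against ground truth.

## The synthetic generator

Counts are drawn from a logistic-normal–multinomial model.  For sample
$s$ at site $k$ and OTU $i$,

$$\eta_{si} = b_i + u_{ki} + \delta_i \mathbf{1}\{s \in \text{enriched group}\}
  + \sum_m \lambda_{mi} z_{sm} + \varepsilon_{si},$$

with composition $p_{si} = \exp(\eta_{si}) / \sum_j \exp(\eta_{sj})$ and
counts multinomial at a log-normal sequencing depth (mean 40,000 reads,
so rarefaction to the default depth of 30,815 is realistic).  The choices
behind each term:

* **Paired design.** $u_{ki} \sim N(0, 0.5^2)$ is a per-site, per-OTU
  intercept shared by the two samples of a site, mirroring a paired plot
  design without modelling plot-level replication (one composite sample
  per condition per site; 22 sites, 44 samples in the default preset).
* **Biomarkers.** $\delta_i = \log(2)\,\mathrm{lfc}_i$ plants genus-level
  fold changes.  The preset plants five genera at 8-fold change, four
  enriched under invasion and one under native vegetation, each carried
  by two dedicated OTUs.
* **Modules.** A latent Gaussian factor $z_{sm}$ per planted module
  induces correlated OTU blocks, which a Dirichlet-multinomial could not
  encode (its covariance is fixed by the mean).  Members load 0.6 on
  their factor.  The hub loads 1.0 and has its idiosyncratic noise and
  site intercept shrunk to 10%, making it a *high-communality* node: it
  correlates with every member near the members' communality ceiling
  while member–member correlations stay moderate.  This is the only
  latent structure that produces degree hubs under a hard correlation
  threshold: in a single-factor model, two members with communality $m$
  correlate at $m^2$ while the hub–member correlation approaches $m$, so
  a star-shaped module needs $m^2$ below and $m$ above the threshold.
  With 22 samples per condition the sampling noise of a Spearman
  coefficient (Fisher-z sd $\approx 0.23$) blurs this margin, so the
  module size (45) is what stabilises the hub's within-module degree
  z-score — the hub's degree excess grows linearly with module size while
  member-degree noise grows as its square root.  A balanced connector
  (links spread over $\ge 3$ modules) is *not* plantable at threshold
  0.6: loading a node equally on $k$ factors divides its correlation
  with any one module's members by $\sqrt{k}$, capping it at
  $1/\sqrt{3} \approx 0.58 < 0.6$ for $k = 3$.  Accordingly the planted
  ground truth promises hubs ("connector or hub" in the recovery tests),
  not balanced connectors; this matches field experience, where kinless
  hubs are rare to absent.
* **Soil variables.** Each variable is drawn around a realistic mean/sd
  (e.g. pH 7.9 ± 0.4, TC 20 ± 5 g/kg) and can be linearly coupled to the
  realized relative abundance of a phylum; the preset couples TC
  positively to Ascomycota and TP/AP negatively to Basidiomycota, and
  generates TN as a near-copy of TC (r = 0.97) so that the VIF screen has
  a genuinely collinear variable to remove.

What the generator does **not** emulate: sequencing error and chimeras,
overdispersion beyond the logistic-normal, phylogenetic signal,
spatial autocorrelation among sites, and zero-inflation mechanisms other
than sampling.  Passing tests therefore demonstrate the correctness of
the statistical machinery on data satisfying the generative assumptions,
not robustness to every artefact of real amplicon data.

## Diversity

Rarefaction subsamples each sample without replacement to a fixed depth
(default 30,815; a single seeded draw, not an average over draws),
dropping and reporting samples below depth.  Richness and Shannon
diversity (natural log — the dominant convention in the R ecosystem this
pipeline targets) are computed on the rarefied table.  Beta diversity
uses Bray–Curtis dissimilarity, ordinated by principal coordinate
analysis (Gower double-centering + eigendecomposition).  Negative
eigenvalues are reported but excluded from the explained-variance
denominator; no Lingoes/Cailliez correction is applied by default
(a Cailliez option exists).  Group separation is tested by ANOSIM with
$R = (\bar r_B - \bar r_W)/(M/2)$ over ranked distances and a
permutation p that counts ties as exceedances,
$p = (1 + \#\{R^* \ge R\})/(1 + B)$, default $B = 999$.  ANOSIM is
implemented in-package with a vectorised permutation core (the rank
matrix is computed once and every permutation reduces to an indicator
product), which makes thousand-replicate calibration studies cheap; the
statistic is cross-checked against vegan's implementation in the test
suite.

## Biomarker discovery

Per taxonomic rank (phylum, family, genus) the counts are aggregated —
an OTU unclassified at the target rank contributes to a composite
column named after its deepest classified ancestor, e.g.
`f_unclassified_o__Tremellales` — then total-sum scaled to $10^6$.
Each taxon is screened by Kruskal–Wallis (α = 0.05); screened taxa get a
bootstrap linear-discriminant effect size: over 30 resamples (2/3 of
each class, with replacement) a two-class LDA with pooled, ridge-
regularised covariance (ridge $10^{-6}$ relative to the mean diagonal;
Cholesky solve, escalating the ridge on failure) yields a unit-norm
discriminant $w$, and for feature $j$ with class-mean difference $d_j$

$$\text{effect}_j = \tfrac12\left(|w_j d_j| + |d_j|\right), \qquad
  \text{score}_j = \log_{10}(1 + \overline{\text{effect}_j}).$$

This formula is *this package's definition*: the published LEfSe tool's
effect size is under-documented, so correctness is established by
planted-truth recovery, monotonicity in the fold change, and null
calibration rather than numeric identity with the original tool.  The
subclass (within-class Wilcoxon) stage of the original is omitted — the
two-condition design has no subclass stratum, making it degenerate.  A
taxon passes at kw_p < 0.05 and score ≥ 3.0.  Bootstrap draws are made
in a canonical sample order, so results are invariant to how the input
rows were arranged.

## Co-occurrence networks

Built per condition group from the rarefied table: OTUs present in
strictly more than 50% of the group's samples are kept; relative
abundances are correlated all-against-all by Spearman (average ranks on
ties, two-sided t-approximation p); edges satisfy $|\rho| > 0.6$ and
raw $p < 0.05$ (the threshold is read as $|\rho|$ because negative
associations are biologically meaningful and retained with their sign;
BH adjustment is available behind a flag but off by default, matching
the raw-p convention).  Nodes are the OTUs incident to at least one
edge.  Modules maximise Newman–Girvan modularity via seeded Louvain on
the unweighted, unsigned graph; an edgeless graph degrades to singleton
modules with Q = 0.

Node roles use the degree-based within-module connectivity z-score and
participation coefficient: for node $i$ in module $s$,
$Z_i = (k_{is} - \overline{k_s})/\sigma_{k_s}$ (population sd; $Z_i = 0$
when the sd is 0) and $P_i = 1 - \sum_t (k_{it}/k_i)^2$.  Thresholds
2.5/0.62 classify peripherals, connectors ($P_i$ high only — requiring
low $Z_i$ so the kinless class stays distinct), provincial hubs ($Z_i$
high only) and kinless hubs (both); exact-equality cases fall to the
lower category.  The non-peripheral classes are the keystone taxa;
keystone sets of the two groups are compared per OTU by two-sided
Wilcoxon rank-sum on relative abundance with BH adjustment.  Topology
summaries report node/edge counts, the positive-edge fraction, average
degree $2E/N$, mean local clustering (0 for degree < 2 nodes), and the
average shortest-path length on the largest connected component only
(these thresholded networks are routinely fragmented).

## Soil associations

Environmental variables are screened iteratively by variance inflation
factor (drop the largest until all ≤ 10; ties broken toward the larger
column index, so the screen is deterministic).  The retained variables
constrain a canonical correspondence analysis (species-focused scaling
for reported scores); axis percentages are eigenvalue over *total*
inertia, the convention behind figure captions of the
"axis 1 explains 21.8%" kind.  Per-variable Monte Carlo tests are
marginal: the variable's constrained inertia is the drop from the full
model to the model without it, F-scaled by the residual inertia, with p
from freely permuting community rows, $(1+\text{exceed})/(1+B)$.  The
permutation core recomputes the chi-square-standardised projection
directly (QR on the weighted constraint matrix) rather than refitting a
full ordination object each round; the projection is verified against
vegan::cca eigenvalues in the tests.  Phylum–soil associations use
pairwise Spearman correlations on predominant phyla (mean relative
abundance > 1%) with p < 0.05 marks.  The contribution of soil
variables to keystone taxa is quantified by LMG decomposition of a
linear model's $R^2$ (exact subset enumeration, ≤ 10 predictors;
shares sum to $R^2$ to machine precision), with the per-sample summed
keystone relative abundance as the default response.  LMG was chosen as
the canonical importance measure because it is the method the named
`lm`/`calc.relimp` workflow actually computes; a random-forest
permutation importance is available as an optional cross-check
(`rf_importance()`).

## Orchestration and determinism

`run_pipeline()` executes load/generate → rarefy → {diversity,
biomarkers} → per-group networks → keystone comparison → soil
association, writing per-stage TSVs, GraphML networks and a JSON
manifest.  A master seed spawns per-stage child seeds through a
counter-based derivation, so adding a stage never perturbs earlier
stages' draws and identical configuration yields byte-identical outputs.
Metadata without soil columns skips the soil stage with a
machine-readable warning in the manifest.

## Numerical choices and problem sizes

Tolerances: Zi/Pi and modularity identities are tested to $10^{-12}$;
eigen-oracle agreement (PCoA, CCA) to $10^{-8}$; LMG decomposition to
$10^{-10}$.  Calibration studies in the test suite use 1,000 ANOSIM
null replicates (999 permutations each), 500 CCA null replicates, 50
biomarker-recovery replicates of the 44-sample preset and 2,000
rarefaction draws — sizes chosen to keep Monte-Carlo error well inside
the asserted bounds while the whole suite stays fast on a single CPU.
Degenerate inputs (all-zero samples, zero-variance OTUs, empty graphs,
perfect collinearity) are either rejected with informative errors or
handled by documented conventions, as described per stage above.

## Known limitations

The LDA effect size is a fixed in-package definition, not a re-
implementation of the published LEfSe internals.  Module detection by
Louvain is seeded but heuristic; very sparse planted modules can split,
which the keystone tests accommodate by accepting connector-or-hub
recovery.  Average path length ignores nodes outside the largest
component.  CCA permutation is unrestricted (no site blocking).  The
rank-based screen runs slightly above nominal size at n = 44 because of
the chi-square approximation; the null-calibration test quantifies this.
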