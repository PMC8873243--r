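# srnet

Network-perturbation features for missense variant interpretation.

Most variant-effect predictors look at a mutation through the lens of one
protein: its sequence, conservation, structure. `srnet` adds the lens of the
interactome. It builds a **structurally resolved protein–protein interaction
network** — a graph whose every edge carries the interface residues that
physically mediate the interaction, and whose residues are labelled core
(RSA < 5%), surface (RSA > 15%) or interface — and models a missense
mutation as an **edgetic perturbation**: core mutations delete all of the
protein's edges, interface mutations delete exactly the edges their residue
participates in, surface mutations delete none.

From this it derives 16 network features per mutation:

* **7 protein-level centralities** of the mutated protein — degree,
  betweenness, closeness (reachable-set scaling), eigenvector, clustering
  coefficient, load and PageRank;
* **9 residue-level features** — the 3D location (core/surface/interface)
  plus, for each centrality *c*, the change *c*(original) − *c*(perturbed),
  and the percent degree change 100·(k₀ − k₁)/k₀.

An optional block of 83 substitution-level amino-acid descriptors extends
the vector to 99 features. A random forest (1000 trees, √p features per
split; score = fraction of trees voting "disease") is trained and evaluated
under **gene-holdout cross-validation**, with per-gene capped 1:4
negative:positive balancing, auROC/auPRC/accuracy/F1/MCC metrics, paired
DeLong comparison of ROC curves, Fisher odds-ratio location enrichment and
Mann–Whitney group tests. A seeded synthetic-data module generates complete
study systems (scale-free interactome, structural annotations, mutations
labelled by a planted logistic model, amino-acid tables) so the entire
pipeline is testable end to end without external downloads.

Who this is for: anyone studying how network context shapes the impact of
point mutations — building variant classifiers that use interactome
features, or quantifying interface/core enrichment of a mutation set.

## Worked example

```r
library(srnet)

# a complete synthetic study system: 300 proteins, preferential attachment,
# 2000 mutations labelled by a planted logistic model on network position
bundle <- synthetic_bundle(seed = 1)
bundle$network
#> Structurally resolved PPI network
#>   proteins:     300
#>   interactions: 596
#>   interface residues: 5960

features <- featurize(bundle$network, bundle$mutations)
attr(features, "coverage")
#> [1] 1

cv <- cross_validate(features, feature_set = "net", k = 5, seed = 1)
cv$report
#> auROC 0.748 | auPRC 0.540 | acc 0.821 | F1 0.431 | MCC 0.353 (threshold 0.50, 402+/1598-)

location_enrichment(bundle$network, bundle$mutations)
#>               analysis   group1   group2   a   b    c    d odds_ratio ...
#> 1      surface_vs_core positive negative 264 138 1187  411  0.662 ...
#> 2 interface_vs_surface positive negative  65 199   36 1151 10.443 ...
```

Reading the output: the cross-validated auROC of 0.748 is essentially the
ceiling allowed by the planted model (scoring with the true linear
predictor gives ≈ 0.77 on these conditions) — the network features recover
the planted signal. The enrichment table mirrors the planted coefficients:
positives are *depleted* at the surface relative to the core
(OR 0.66 < 1, planted β_core = 1) and strongly *enriched* at interfaces
among surface-exposed residues (OR 10.4 > 1, planted β_iface = 2;
exp(β) = 7.4 lies inside the reported confidence interval).

Real data enter through three plain-text tables: an interface-residue table
(`Uniprot1  Uniprot2  Uniprot1_residue`, one row per interface residue),
an RSA table (`protein  chain  position  rsa`), and a mutation table
(`protein  position [ref_aa alt_aa gene label]`); see
`parse_interface_table()`, `read_rsa_table()`, `read_mutations()` /
`read_maf_lite()`, then `filter_interactions()` → `build_network()` →
`featurize()`. A thin command-line wrapper with `simulate`, `build`,
`featurize`, `train` and `enrich` subcommands lives at
`inst/cli/srnet.R`.

## Package layout

* `R/interactome.R` — interface/RSA parsing, filtering, network building
* `R/centrality.R`, `src/load_centrality.cpp` — the seven centralities
* `R/perturb.R` — edge mapping, perturbation features, feature assembly
* `R/mlframe.R` — balancing, gene-holdout CV, forest, metrics, DeLong
* `R/enrichstats.R` — Fisher OR, Mann–Whitney, Pearson correlation tools
* `R/synthetic.R` — seeded generators with planted signal
* `vignettes/network-perturbation-features.Rmd` — model, assumptions,
  numerical choices, limitations
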