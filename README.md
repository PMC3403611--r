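# katznet

Network-based prioritization of candidate disease genes on a weighted
protein–protein interactome, for researchers who have heterogeneous
evidence about a complex disease — a short causative-gene list, a
proteomics hit list, case–control expression data — and want to turn it
into a ranked gene list, a disease-specific subnetwork, and enriched
pathways.

## The method

Given a symmetric weighted interactome `W` (confidences in [0, 1], zero
diagonal) and a 0/1 seed indicator `x` over genes assumed disease-active,
every gene is scored by the seeded Katz index

```
s = x + φ W s      ⇔      s = (I − φW)⁻¹ x = Σ_t φᵗ Wᵗ x ,
```

which accumulates evidence along walks of every length from the seeds,
discounted by `φ` per step; the series converges for
`φ < 1/ρ(W)`.  Both a direct sparse solve and the Jacobi iteration
`sᵢ ← xᵢ + φ Σ_{j≠i} w_ij s_j` are provided and agree to solver
precision.

The propagation strength `φ` is calibrated with held-out causative genes:
each one is ranked within its ~100-gene chromosomal candidate set, and
`φ*` minimizes the mean **r-ratio** (rank / set size; 0.5 for a random
gene, 1/N for perfect recovery) over a log-spaced grid.  The held-out
genes are then added to the seeds, the network is rescored, the top
fraction of genes (default 10%) spans the disease subnetwork (edges with
weight ≥ 0.5 only), whose topology is characterized by k-core
decomposition, core layers and an inner/medium/outer core–periphery
partition.  Annotation terms, reference gene sets and tissue-abundance
composition are tested with the hypergeometric upper tail
`p = P(X ≥ k)` for an overlap `k` between an `n`-gene query and a
`K`-gene term in an `N`-gene background.

Seeds can come straight from data: the expression module harmonizes
multi-platform probe-level matrices (probe averaging, common-gene
intersection), applies a 1.5-fold filter on case/control mean ratios, a
within-sample rank transform, a two-sided Wilcoxon rank-sum test and
Benjamini–Hochberg FDR at 0.10 per dataset, and unions the selections.
A synthetic-data module generates every input with a planted disease
module and known ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(katznet)

scenario <- synthetic_scenario(rng_seed = 11)      # 2000 genes, 50-gene planted module
inputs   <- simulate_inputs(scenario, "example/inputs")
config   <- config_from_paths(inputs$paths, out_dir = "example/results",
                              cut_outer = 8, cut_medium = 20, rng_seed = 11)
run      <- run_pipeline(config)

run$results$seeds
#> seed_collection: 7 causative + 12 proteomics + 21 microarray = 40 genes in union
run$results$calibration
#> calibration_result: 30 grid points, phi* = 1e-06 (mean r-ratio 0.0286)
run$results$subnetwork
#> subnetwork: 53 nodes, 755 edges (weight floor 0.5)
head(run$results$enrichment[, c("term_id", "K", "n", "k", "p_value", "significant")], 3)
#>   term_id  K   n  k      p_value significant
#> 1   T0001 46 200 38 4.428206e-32        TRUE
#> 2   T0010 21 200  6 1.394385e-02        TRUE
#> 3   T0041 18 200  5 2.756698e-02        TRUE
```

Reading the output: the DE screen recovered 21 microarray-derived seeds
(the 20 planted DE genes plus one borderline gene), giving 40 seeds in
all.  Calibration drove the mean r-ratio of the 7 held-out causative
genes to 0.0286 — they rank in the top ~3% of their ~100-gene locus
candidate sets, far below the 0.5 of a random gene — with the flat grid
minimum resolved to the smallest `φ`.  The top 10% of the 2000-gene
network (200 genes) spans a 53-node subnetwork once sub-0.5 edges and
isolated genes are dropped, and the planted annotation term `T0001` is
the top enrichment hit (38 of its 46 members among the 200 selected
genes).  Every output lands in `example/results/` (scores, calibration
table, node attributes with core numbers and partition, GraphML export,
run log); rerunning with the same config and seed reproduces the files
byte for byte.

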