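---
title: "Methods: seeded Katz propagation, locus calibration, and disease-network topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seeded Katz propagation, locus calibration, and disease-network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katznet)
```

## The model

Complex chronic diseases are rarely explained by a single causal gene:
genes whose products participate in the same pathological process tend to
lie close together in the protein--protein interaction (PPI) network.
`katznet` exploits this by propagating a prior "disease activity" signal
through a weighted interactome and ranking every gene by how much signal
reaches it.

Let $W$ be the symmetric $n \times n$ matrix of interaction confidences in
$[0,1]$ (zero diagonal), and let $x \in \{0,1\}^n$ indicate a set $D$ of
seed genes assumed disease-active a priori.  The score vector $s$ solves

$$ s = x + \varphi W s \qquad\Longleftrightarrow\qquad
   s = (I - \varphi W)^{-1} x = \sum_{t \ge 0} \varphi^t W^t x , $$

the seeded form of Katz centrality: a gene accumulates contributions from
every walk connecting it to a seed, discounted by $\varphi$ per step and
by the edge weights along the walk.  Small $\varphi$ keeps the prior
dominant; large $\varphi$ emphasizes network coupling.  The series
converges iff $\varphi < 1/\rho(W)$, where $\rho(W)$ is the spectral
radius; `katz_score_direct()` and `katz_score_jacobi()` both refuse
$\varphi$ at or beyond this bound.

All seed sources enter $x$ with equal weight 1.  Differential confidence
weighting of sources is deliberately not attempted: it adds free
parameters that the locus calibration below cannot identify, so a flat
weighting is the defensible default (per-source weights can still be
passed as a numeric `x`).

### Solvers

Two solvers are provided and cross-checked against each other in the test
suite:

* **Direct.** $(I-\varphi W)$ is symmetric positive definite whenever
  $\varphi < 1/\rho(W)$ (its eigenvalues are $1 - \varphi\lambda_i > 0$),
  so the sparse Cholesky path is used.  The reported `residual` is the
  max-norm of $(I-\varphi W)s - x$.
* **Jacobi.** Because $\operatorname{diag}(W)=0$, the fixed-point sweep
  $s_i \leftarrow x_i + \varphi \sum_{j \ne i} w_{ij} s_j$ is exactly the
  Jacobi method.  Initialization is $s^{(0)} = x$ (the $t=0$ series term);
  iteration stops when the max-norm update falls below `tol`
  (default `1e-10`, `max_iter = 10000`); non-convergence is an error
  carrying the last update norm.  The two solvers agree within
  $10\cdot\texttt{tol}$ on random networks up to $n = 500$ in the tests.

The spectral-radius guard uses 100 power-iteration steps from a constant
start vector, which converges quickly for the nonnegative symmetric
matrices used here; it is an estimate, so $\varphi$ very slightly below
the true bound may still be accepted (with slow Jacobi convergence and a
clean error if `max_iter` is hit).

## Calibrating the propagation strength

$\varphi$ is a free parameter and is calibrated against known causative
genes using their genomic loci.  For each held-out causative gene we form
a **candidate set**: the $N \approx 100$ genes nearest to it (base-pair
midpoint distance) on its chromosome region — the plausible candidates a
linkage interval would offer.  Scoring the network from the *remaining*
seeds and ranking the candidate set by score gives the causative gene a
rank $r$; the **r-ratio** $r/N$ measures how well propagation singles it
out (a random gene sits near 0.5; perfect recovery gives $1/N$).
`calibrate_phi()` scans a grid of $\varphi$ values — by default 30
log-spaced points in $[10^{-6}, 10^{-2})$ — and returns the minimizer of
the mean r-ratio over the held-out genes, ties resolved toward the
smallest $\varphi$ (the weakest coupling that achieves the optimum).
After calibration the held-out causative genes are added to the seeds and
the whole network is scored once more.

Candidate genes that are absent from the interactome carry no score and
are clipped from the candidate set during calibration (the effective $N$
shrinks accordingly); `r_ratio()` used directly warns instead.

Ranking ties (common at $\varphi = 0$, where all non-seeds score 0) are
broken by gene identifier in C-locale order — an arbitrary but
deterministic rule, so reruns and relabelings are reproducible.

## From scores to a disease subnetwork

`select_top_fraction()` takes the top $q$ (default 10%) of genes.  The
denominator of the fraction is deliberately explicit
(`all_genes` vs `positive_score`): on sparse seed sets most genes receive
a strictly positive but negligible score, and which universe "top 10%"
refers to materially changes the selection size, so the package refuses
to guess and exposes both modes (default `all_genes`, the literal
reading).

The subnetwork is the subgraph induced by the selected genes keeping only
edges with weight at least the **weight floor** (default 0.5,
medium-confidence interactions).  Selected genes isolated by the floor
are pruned by default (`prune_isolated = TRUE`), which is why the node
count can be smaller than the selection; the flag turns pruning off.

### k-core topology

The $k$-core is the maximal subgraph in which every node keeps at least
$k$ neighbors inside the subgraph, computed by recursive minimum-degree
peeling on the thresholded, *unweighted* subnetwork (weights have already
acted through the floor; weighted-core variants are out of scope).  The
$k$-core **layer** $l_k$ is the set of nodes with core number exactly
$k$; layers partition the nodes and the $k$-core is
$\bigcup_{j \ge k} l_j$.  `partition_core_periphery()` splits nodes into
outer / medium / inner parts by two core-number cutpoints (defaults 10
and 35).  The cutpoints are descriptive, data-derived choices — no
automatic cutpoint search is attempted, because the choice in the
motivating analyses comes from visual inspection of the layer histogram,
not an optimization criterion.

## Enrichment

With a background of $N$ genes of which $K$ carry an annotation, a query
of $n$ genes overlapping the annotation in $k$, the enrichment p-value is
the hypergeometric upper tail

$$ p = P(X \ge k) = 1 - \sum_{i=0}^{k-1}
   \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}} , $$

evaluated through log-space binomial coefficients (`stats::phyper`), with
an exhaustive draw-enumeration oracle verifying every instance with
$N \le 12$ in the tests.  The background is always an explicit argument
and is echoed in each record, since "total genes" counts differ between a
genome and an interactome background.  No multiple-testing correction is
applied by default (raw $p$ against $\alpha$, matching the descriptive
use of these tables); a BH flag exists for screening use.  Query genes
outside the background are clipped with a warning rather than erroring.

Terms are flat sets: no ontology-graph propagation of annotations to
ancestor terms is performed, so term sizes mean literal membership
counts.

## The synthetic-data generator

The generator exists so every stage can be tested end-to-end with known
ground truth; its defaults were fixed once, as a desk-scale analog of a
genome-wide study, and are the conditions under which the acceptance
checks run:

| parameter | default | why |
|---|---|---|
| universe | 2000 genes | large enough for a 100-gene locus per held-out gene, small enough for seconds-scale solves |
| planted module | 50 genes | a disease module a few percent of the universe |
| seed split | 7 causative / 12 proteomics / 15 module-DE (+5 background DE) | mirrors a causative-list : proteomics : microarray provenance mix; sources disjoint by default, with an overlap parameter |
| edge densities | 0.6 in-module, 0.01 background | module markedly denser than background, background degree ~20 |
| edge weights | U(0.6, 1) in-module, U(0.1, 0.5) background | the 0.5 medium-confidence floor separates the two regimes, so the floor filter acts nontrivially |
| expression effect | 2-fold on planted DE genes | comfortably beyond the 1.5-fold screen threshold |
| noise | log-normal, sd 0.25 (log scale) | multiplicative noise, the microarray convention; ratios stay well defined |
| samples | 12 cases vs 12 controls per platform | typical small clinical series |
| probes | 1–3 per gene | exercises probe averaging |
| shared genes | 90% of the universe (module and DE genes always shared) | platform harmonization has something to discard |

Weights are quantized to 3 decimals at generation so that the
STRING-style integer-score (0–1000) file format round-trips exactly.  One
integer seed drives every generator (each derives a fixed offset stream),
making all outputs bit-for-bit reproducible; the end-to-end pipeline
writes no timestamps, so whole runs are byte-identical under a fixed
config.

What the generator does **not** emulate: scale-free degree structure,
array chemistry and normalization artifacts, probe cross-hybridization,
linkage disequilibrium in loci, or ontology term overlap.  Passing tests
therefore demonstrate correctness of the algorithms under the assumed
statistical structure, not performance on real interactomes, where
hub effects and annotation bias can degrade both prioritization and
enrichment.

## The expression screen

The screen reproduces a deliberately simple two-stage design: (1) fold
filter on the ratio of group means of harmonized values — a gene survives
iff the ratio is $\le 1/1.5$ or $\ge 1.5$ (the boundary values survive);
(2) within-sample rank transform over the common genes, two-sided
Wilcoxon rank-sum test per surviving gene, and BH-FDR at level 0.10
computed over the tested genes only, per dataset, with the final list the
union across datasets (a pooled-FDR flag exists because the per-dataset
choice, though implied, is not forced).  The fold filter operates on raw
(not rank) values; ranks feed only the test.  A zero control mean gives
an infinite ratio: the gene is retained with a warning rather than
silently dropped.

One consequence worth knowing: because the filter preselects extreme
ratios and the rank-sum statistic is correlated with the ratio, the
two-stage screen does not inherit BH's formal FDR guarantee.  Under the
default conditions (12 vs 12 samples, noise sd 0.25) the filter is a
$\approx 4\sigma$ event for a null gene and the null screen stays quiet
(the acceptance suite measures a median of zero selections over 100 null
replicates); with substantially fewer samples or more noise the filter
loosens and small numbers of null selections appear.

## Problem sizes used in the tests

Unit tests run on a 300-gene / 20-gene-module compact scenario; the
acceptance suite runs the default 2000-gene scenario for parameter
recovery and end-to-end determinism, 100 random networks up to $n = 500$
for solver agreement, exhaustive enumeration up to $N = 12$ for the
hypergeometric and $k$-core oracles, all group splits with
$n_1 + n_2 \le 10$ for the exact Wilcoxon path, and 100 null replicates
for the screen.  These sizes were chosen as the smallest at which each
property is informative.

## Known limitations

* The propagation kernel is the Katz resolvent only; random walk with
  restart and heat diffusion are out of scope.
* Gene identifiers are opaque strings matched exactly; no identifier
  mapping or resolution service is included.
* The calibration objective is a grid minimum of a mean of few r-ratios;
  with very few held-out genes it is a noisy objective, and the
  smallest-$\varphi$ tie rule means flat stretches resolve conservatively.
* Enrichment assumes flat, complete annotation sets and an exchangeable
  background; neither holds exactly for real ontologies.
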