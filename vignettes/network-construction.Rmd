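---
title: "Co-occurrence network construction from metagenomic counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence network construction from metagenomic counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micronet)
```

## The problem

16S rRNA sequencing reduces a microbial community to a table of read counts
`X` (n samples by m taxa).  Most comparative analyses stop at abundance;
`micronet` instead asks which taxa *co-occur*: which pairs remain associated
after the influence of every other taxon is held fixed.  Marginal
correlations are a poor tool for this — counts are overdispersed,
non-normal, zero-inflated, and a shared partner taxon induces spurious
pairwise association.  The package therefore (i) measures taxon–taxon
similarity nonparametrically and (ii) estimates a *sparse inverse* of the
similarity matrix, whose off-diagonal support plays the role of a
partial-correlation (conditional-dependence) network.

## Similarity measures

Two families are available via `similarity_matrix()`:

* **Sin-transformed rank correlations.**  Spearman's rho (mid-ranks for
  ties) or Kendall's tau-b, mapped through `sin(pi r / 2)`.  Under a latent
  bivariate normal this transform recovers the Pearson correlation of the
  latent scale, which makes the transformed matrix a legitimate covariance
  surrogate for inversion.  Rank correlations are computed on raw counts by
  default: they are already invariant to monotone per-taxon distortions,
  while per-sample normalisation can itself perturb within-taxon ranks
  (`use_relative = TRUE` is available).
* **Gaussian kernels of ecological distances.**  Hellinger, chi-square, or
  Bray-Curtis distances between taxon profiles, mapped through
  `exp(-D^2 / sigma)`.  These are computed on per-sample relative abundance
  by default (sequencing-depth adjustment).  The bandwidth defaults to
  `sigma = 1`; it is exposed but there is no principled in-package
  estimator for it, so treat changes as sensitivity analysis.

Degenerate inputs are handled conservatively: zero-variance taxa produce a
warning and a similarity of 0 (the correlation is undefined); taxa with
zero total count are an error for the profile-based distances because no
profile exists.

Finite-sample rank-correlation matrices and Bray-Curtis kernels need not be
positive semidefinite, while the log-determinant objective requires it.
`psd_repair()` floors the spectrum at `1e-8` and renormalises the diagonal;
matrices already PSD pass through unchanged.  A note on conventions:
Bray-Curtis is evaluated exactly as classically defined,
`1 - 2 sum min / sum`, on whatever abundances it is handed — it is *not*
invariant to rescaling one taxon's column, unlike Hellinger and chi-square,
which normalise within the formula.

## Sparse inverse of a similarity matrix

`sparse_inverse(S, lambda)` minimises

    E(A) = -log det A + tr(SA) + lambda * ||A||_1

over positive-definite `A`, with the elementwise l1 norm (diagonal
included).  The solver is primal block coordinate descent: cycling over
columns in fixed index order, each column subproblem is an l1-penalised
quadratic in the off-diagonal block (solved by cyclic coordinate descent
with soft-thresholding), and the diagonal entry follows in closed form from
its stationarity condition, `a22 - a12' A11^{-1} a12 = 1/(s22 + lambda)`.
The iterate's inverse is maintained by rank-one updates, so each sweep costs
O(m^3).  Because every column update exactly minimises the objective over
that column, the per-sweep objective trace is non-increasing — a property
the test suite asserts.

Numerical choices:

* initialisation `A0 = (S + lambda I)^{-1}`;
* convergence when the mean absolute change of `A` entries per sweep falls
  below `tol = 1e-4` (200-sweep cap, warning and `converged = FALSE`
  beyond it);
* entries below `1e-8` in magnitude are snapped to exact zeros so the edge
  support is well defined;
* exact block screening: the solution is block-diagonal over connected
  components of `{|S_ij| > lambda}`, so each component is solved
  independently — this is what keeps 500-taxon problems at second scale —
  and a test verifies it changes nothing.

The network adjacency is `|A|` with the diagonal zeroed.  At `lambda = 0`
and nonsingular `S` the estimate is the plain inverse (checked to
`1e-6`).

## Choosing the penalty: stability selection

`stability_select()` draws `p = 50` subsamples of size `floor(2n/3)`
without replacement, fits the network on each over a penalty grid (20
log-spaced values in `[0.01, 1]` by default), and measures the edge
instability `D(lambda) = sum_{j<k} abar(1-abar) / C(m,2)`, `abar` being the
per-edge selection frequency.  Scanning from the sparse end, the selected
penalty is the smallest grid value whose running-maximum instability stays
at or below `alpha = 0.05`: the densest network that is still reproducible
across subsamples.  Two conventions deserve comment:

* **Denominator.**  Dividing the edge sum by the number of node pairs
  `C(m,2)` makes `D` an average disagreement fraction per edge, bounded by
  0.25, and matches the stability-selection literature; dividing by the
  number of subsample pairs `C(p,2)` is offered as
  `denominator = "pairs_of_subsamples"` for fidelity to an alternative
  printed convention, and only rescales the profile.
* **Monotonisation direction.**  The instability is monotonised from the
  sparse end (running maximum over larger penalties), the StARS convention.
  Monotonising from the dense end instead would select the *densest* grid
  point whenever fully dense fits are stable — a degenerate rule for sparse
  network estimation, although we note (see "Known limitations") that dense
  fits can still rank edges well.

`early_stop = TRUE` abandons the grid once the monotonised instability
exceeds `alpha`; the selection is provably unchanged and the expensive
dense end of the path is never visited.

## Modules, node statistics, differential networks

`detect_modules()` maximises Newman-Girvan modularity by the two-phase
local greedy (Louvain-type) algorithm: single-node moves to the
neighbouring community with the best positive gain (ties to the lowest
community id), then aggregation of communities into super-nodes whose
self-loops carry intra-module weight, repeated until the gain falls below
`1e-10`.  Node visit order is a seeded random permutation per pass, so a
seed makes the result fully deterministic.  Isolated taxa keep singleton
modules.  On graphs small enough for exhaustive search the greedy optimum
is verified exactly on clique fixtures and attains the global optimum on at
least 90% of random sparse graphs in the test suite.

`node_statistics()` reports weighted degree, binary degree, triangle count,
clustering coefficient and participation coefficient per taxon.  Triangles
and clustering are computed on the *binarised* graph: the classical
normalisation `K(K-1)` counts links, so mixing weighted triangle mass with
count-based normalisation would be internally inconsistent; the weighted
degree is reported alongside.

`permutation_test()` compares two conditions by the mean absolute distance
between either their similarity matrices or their sparse adjacencies,
refitting both networks for every permutation of the condition labels.
Label assignments are enumerated exactly when `choose(n, n1)` is at most
`exact_limit` (exhausting assignments by raw sample size alone is
combinatorially impossible — `choose(90, 45)` exceeds 10^25), otherwise
Monte-Carlo with the add-one estimator `(1+B)/(1+L)` so the p-value is
never zero.  When the penalty is stability-selected it is selected once per
condition on the observed grouping and held fixed across permutations.

## The simulator and what the benchmarks mean

`make_graph()` provides three ground-truth families: a Watts-Strogatz ring
(`nei = 1`, `p_rewire = 0.1` — each taxon tied to its neighbours with
occasional long-range rewiring), Barabasi-Albert preferential attachment
(2 links per node, power-law degrees), and a range-dependent model with
edge probability `0.9 * 0.3^(|i-j|-1)`.  The precision matrix places weight
`-1` on each edge and `sum |row| + 1` on the diagonal, which guarantees
positive definiteness by diagonal dominance.  The *negative* off-diagonal
is deliberate: it makes linked taxa positively associated in the implied
covariance, the ecological meaning of co-occurrence.  With `+1` weights
linked taxa would be anti-correlated, and distance-kernel similarities
would rank true edges *below* noise — a sign convention worth knowing about
when plugging in custom precision matrices.

`simulate_counts()` draws per-sample log-rates from `N(mu 1, Sigma)` with
`Sigma` the precision inverse (`mu = 3` by default, giving counts of a few
dozen reads), then counts per entry from a negative binomial with mean
`lambda_ij` and dispersion `gamma = 2` (`Var = lambda + lambda^2/gamma`),
or Poisson.  What this emulates: overdispersed, correlated count data with
a known conditional-independence graph.  What it does not emulate:
compositional closure from fixed sequencing depth, zero inflation, and
uneven library sizes — so passing benchmarks here says the estimator
recovers conditional structure from idealised counts, not that it is
immune to compositional artefacts in real data.

`edge_auc()` scores recovery by treating `|A|` off-diagonals as scores for
the true edge labels (ties, including the mass of exact zeros of a sparse
fit, count one half) and `run_benchmark()` wires the whole loop together
with replicate seeds derived from a master seed by fixed offsets.

## Problem sizes used in the shipped checks

The acceptance script and test suite run the 20-taxon benchmarks at 500
negative-binomial samples with 20 replicates, and the 500-taxon Poisson
benchmarks with 10 replicates (6 in the test suite), selecting the penalty
by stability selection with 12 subsamples over a 10-point grid once per
cell and reusing it across that cell's replicates.  These sizes keep the
full suite at desk scale; the estimator itself handles thousands of taxa.

## Known limitations

* **Kernel similarities at large m with weak per-pair signal.**  When
  profiles are nearly uniform (many taxa, moderate counts), Gaussian-kernel
  similarities concentrate around a large common baseline; the sparse
  inverse at any penalty inside the stable region then carries little
  signal, and stability selection correctly reports that no sparse network
  is reproducible (selecting the empty end of the grid).  The *dense*
  inverse of such a kernel can still rank true edges well — but that is an
  unregularised estimate outside the scope of the selection rule.  Rank
  similarities do not suffer from this because their baseline is zero.
* **Penalty calibration is implementation-relative.**  Reported "optimal"
  penalties from other implementations of the same objective need not
  transfer exactly; compare stability profiles, not raw penalty values.
* **The test suite's greedy-modularity guarantee is statistical** (90% of
  random graphs), because Louvain-type algorithms can stop in local optima.
* Two-group comparison only; no edge-level differential tests.
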