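---
title: "Multi-scale clustering on sparse planar cell networks: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale clustering on sparse planar cell networks: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msclust)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The pipeline has two halves: building a sparse
cell–cell network (similarity → local embedding → edge screens) and mining it
top-down for a hierarchy of clusters (resolution scan → breakpoint →
quality-gated splits). A Gaussian block simulator and overlap-aware metrics
close the loop for validation.

## 1. The cell similarity network

### Similarity

Two modes are supported: Pearson correlation across (optionally masked)
features — the default for expression input — and negated Euclidean distance
for reduced coordinates such as principal components. Distances are negated
so that every downstream step uniformly maximises similarity. "Expressed"
means strictly positive value throughout; the package deliberately performs
no normalisation, imputation or integration, which belong upstream.

### Local embedding

For cell $i$ and neighbourhood size $k$, a planar maximally filtered graph
(PMFG) is built over $\{i\} \cup \{k \text{ most similar cells}\}$: candidate
edges are inserted in decreasing similarity and kept iff the graph stays
planar, stopping at the Euler bound $3(N-2)$. Planarity testing is exact
(left–right criterion, implemented in C++); for $N \le 4$ the PMFG is the
complete graph. The cells adjacent to $i$ typically stop changing at
$k' \sim \log N$; we declare a plateau after `stall = 3` consecutive
unchanged increments and cap the scan at
$k_{\max} = \max(10, \lceil 3\ln N\rceil)$ (natural logarithm). The union of
the per-cell adjacencies — an edge $(i,j)$ exists iff $j$ is an embedded
neighbour of $i$ or vice versa — is the raw locally embedded network (LEN).
Only edges incident to the focal cell contribute; the other PMFG edges are a
byproduct of the local construction.

Every source of order-dependence is pinned down: candidate edges sort by
(similarity descending, smaller cell index, larger cell index), and the same
rule orders top-$k$ selection, so runs are bit-reproducible. Cells with
fewer than three other cells take all of them as neighbours.

### Edge screens

Two post-hoc filters remove low-quality edges; they only ever delete edges,
never nodes or weights, and the component count of the result is reported,
never repaired.

*Low-similarity screen.* The number of genes two cells co-express modulates
the similarity one can expect of them. We fit similarity against the
expressed-set Jaccard index $J_{ij}$ with LOESS (span 0.5, quadratic local
fit, linear-model fallback if the smoother fails) and remove edges more than
two global residual standard deviations *below* the fitted mean. The screen
is one-sided — high similarity is never penalised — and it is skipped, with
a warning, for Euclidean-mode graphs ($J$ is an expression-space quantity),
for graphs with fewer than 30 edges, and for constant $J$. The global-SD
band is a choice; a local (per-$J$) spread estimate would need far more
edges per bin than small data sets offer.

*Low-centrality screen.* For adjacent cells the shared-neighbour ratio
$M_{ij} = |N(i) \cap N(j)| / |N(i) \cup N(j)|$ (open neighbourhoods)
measures second-order support. The lowest `contested_quantile = 0.25` of
edges by similarity are visited in ascending similarity; an edge is removed
iff $M_{ij}$ computed without it strictly exceeds $M_{ij}$ with it and
neither endpoint would drop to degree zero. Removing an edge shrinks the
neighbourhood union while leaving the intersection unchanged, so the
contested edges that fall are exactly the *redundant* ones — pairs that
remain locally connected through shared neighbours — while bridges
($M = 0$) always survive. Removals apply immediately, so later contests see
the updated graph. The quantile default follows the convention of contesting
the lower quarter; the degree guard prevents orphaning cells.

## 2. AdaptSplit and the hierarchy

### Resolution scan

Each (sub-)network is clustered by the Leiden algorithm under the
Reichardt–Bornholdt configuration-model objective at every
$\gamma \in \{0.05, 0.10, \dots, 2.00\}$; the grid covers the neutral
resolution $\gamma = 1$ and the range used in practice. Clustering is
*unweighted* (all edge weights 1): the intra-cluster link count
$K_\mathrm{in}$ and the modularity objective are both defined through link
counts here, and correlation weights can be negative, which modularity does
not accept. Leiden runs with 10 iterations under a seed derived from the
single user seed, so scans are deterministic.

### Breakpoint and $\gamma_f$

$K_\mathrm{in}(\gamma)$ — the number of edges with both endpoints in the
same cluster — is piecewise stable: it stays flat across a regime of
resolutions and drops when the solution fragments. We fit a step function by
recursive binary partitioning (anova splitting, single-point leaves allowed)
and keep a split only if it reduces the total sum of squares by at least
$cp = 0.01$ of the root sum of squares. This rule is deterministic,
invariant to affine rescaling of $K_\mathrm{in}$, keeps genuine steps even
on short grids, and never invents splits inside noiseless plateaus.
(Cross-validated pruning was tried and rejected: on the short grids a split
produces, fold noise is of the order of the signal, making an otherwise
deterministic quantity seed-dependent and over-pruned.) The surviving split
points cut the grid into regimes, and a regime only counts as *stable* if it
spans at least two grid points: stability means constant $K_\mathrm{in}$
across a range, and a single grid point has no range. This matters at the
low end of the grid, where the very first resolution sometimes carries a
transient coarse solution one step before the real plateau; averaging that
transient into the first regime would let the median pick an off-plateau
clustering. The clustering at the first stable regime's *lower median*
$\gamma_f$ is the split result; $\gamma'$ is that regime's upper boundary.
The low-$\gamma$ regime yields the coarsest stable solution, which is what
a top-down pass wants at each level.

### Quality gates

A candidate child is accepted iff:

* **size**: at least `min_cluster_size = 10` cells and strictly fewer than
  the parent (guaranteeing termination);
* **compactness**: $v(\alpha) = \overline{SPD} / (\ln N_c)^\alpha$ strictly
  decreases relative to the parent, where $\overline{SPD}$ is the mean
  unweighted shortest-path distance over node pairs. A disconnected
  candidate is scored per component with a size-weighted mean; a
  disconnected *parent* has no defined $\overline{SPD}$ and counts as
  infinitely non-compact, so splitting it into components is always a
  compactness improvement. The scaling $\alpha$ is calibrated once per
  top-level component as the median of
  $\alpha_0 = \ln(\overline{SPD}) / \ln(\ln N_c)$ over 100 sampled 3-hop
  neighbourhoods (samples need $N_c \ge 4$; $\overline{SPD} = 1$, as in a
  complete graph, legitimately gives $\alpha_0 = 0$), with fallback
  $\alpha = 1$ when fewer than 10 samples qualify and a warning if the
  calibrated value reaches 2;
* **connectivity**: the intra-cluster connectivity
  $\lambda_c = e_{cc}/e_c$ (internal edges over incident edges) must be
  permutation-significant at $p < 0.05$. Each of the 100 permutations picks
  $\lceil 0.10\,n\rceil$ cells (at least 2 — a single relabelled cell could
  never change the assignment) and reassigns every one to a uniformly drawn
  *different* child; $p = (1 + \#\{\lambda_\mathrm{perm} \ge
  \lambda_\mathrm{obs}\}) / (1 + n_\mathrm{perm})$, so the smallest
  attainable value is $1/101$. Moving cells across clusters, rather than
  shuffling labels among the selected cells, is essential: a label shuffle
  frequently reproduces the observed assignment (e.g. both selected cells in
  the same child), which inflates ties and leaves even perfectly separated
  children non-significant.

Connected components of the screened network with at least
`min_cluster_size` cells become top-level clusters; smaller components are
reported as unassigned. Nodes with at least `min_split_size = 20` cells are
split recursively (smaller parents would make the permutation test
degenerate). Cells of rejected candidates stay covered by their parent only;
rejected candidates do not seed further split attempts. Membership is
cumulative: a cell belongs to every node on its root-to-leaf path, so the
hierarchy is an overlapping cluster collection by construction.

All randomness (Leiden, permutations, $\alpha$ sampling, the simulation
draw) derives from one user seed through fixed stage offsets plus a
per-node counter, recorded in the run manifest.

## 3. The simulator

Samples are drawn from $X \sim \mathcal N(0, \Sigma)$ with unit diagonal, so
covariance equals correlation: $\Sigma_{ij} = \rho_\mathrm{in}$ within an
inner block, $\rho_\mathrm{out}$ for pairs sharing an outer cluster only,
and 0 otherwise; independent $\mathcal N(0, \sigma^2)$ noise is added per
entry, attenuating observable correlations to $\rho/(1+\sigma^2)$. Each of
the `n_features = 500` rows is an independent draw (Cholesky factorisation,
with a $10^{-10}$ diagonal jitter if the factorisation fails numerically);
features are deliberately fewer than cells, as in real scRNA-seq.

Scenario presets: **I** — single layer, 12 blocks of 25 + 6 of 50 + 3 of
100 (900 cells), defaults $\rho_\mathrm{in} = 0.4$, $\sigma = 1$;
**II** — 21 blocks of 50 (1050 cells) adjoined into 6 outer clusters,
defaults $\rho_\mathrm{in} = 0.25$, $\Delta\rho = 0.125$; **III** — the
scenario-I blocks adjoined so that each outer cluster merges 4×25 + 2×50 +
1×100 = 300 cells. Where the block-to-outer assignment is not dictated by
the design, blocks are adjoined contiguously (II: groups of 4,4,4,3,3,3) —
the labels are exchangeable under the model, so any fixed assignment is
equivalent; contiguity keeps it deterministic. For the two-layer scenarios
the default $\sigma = 0.2$ sits in the low-noise regime where both layers
are resolvable. Noise is i.i.d. per entry (per-column noise would act as a
sample-specific offset, which Pearson similarity removes anyway).

What the generator emulates: correlation-structured populations with
controlled hierarchy depth, block sizes and noise. What it does not: counts
(no negative binomial), dropout zeros, library-size variation, batch
effects, or feature selection noise. Passing the simulation suite therefore
demonstrates the *clustering machinery* — sparsity of the network, layer
recovery, metric behaviour — not robustness to scRNA-seq technical
artefacts, which the upstream preprocessing the package intentionally omits
is responsible for.

## 4. Evaluation metrics

For a result collection $\Psi'$ and truth $\Psi^o$ (both may overlap):
inclusion rate is the size-weighted mean over result clusters of their best
precision against any truth cluster; coverage rate is the size-weighted mean
over truth clusters of their best recall; detection accuracy replaces recall
with the Jaccard index, which penalises both over- and under-segmentation.
All three are invariant to cluster names and order, and
$JI \le \min(P, R)$ pairwise. The adjusted Rand index is restricted to
proper partitions and errors on overlapping input. Cluster–sample
enrichment uses a one-sided Fisher test per (cluster, sample) pair —
one-sided because the question is enrichment — with Benjamini–Hochberg
correction across all pairs jointly, and a cluster is labelled for a
condition when at least half of that condition's samples are enriched.

## 5. Numerical choices and degenerate inputs

* Exact symmetry of similarity matrices is enforced by averaging with the
  transpose; read similarity files may deviate by at most $10^{-8}$.
* PMFG of $N = 2$ is the single edge; zero-variance cells, NaN coordinates,
  duplicate ids, negative expression (without explicit opt-in) and
  asymmetric similarity input all raise descriptive errors.
* Ties anywhere resolve by cell index; even-length regimes take the lower
  median; `contested_quantile = 0` and an empty contest list are no-ops.
* The step fit requires at least 5 grid points; a constant profile has no
  breakpoint and the whole grid is its first regime.
* An all-singleton or single-cluster solution at $\gamma_f$ signals "no
  meaningful split" and terminates that branch.

## 6. Known limitations

* **Outer-layer fragility at low noise.** In two-layer simulations with a
  small correlation gap (e.g. $\Delta\rho = 0.125$, $\sigma = 0.2$), the
  within-block similarity ranks are so clean that a cell's top-$k'$
  neighbours almost never leave its 50-cell block; outer-level edges then
  hinge on a handful of tail fluctuations, and in some replicates one outer
  cluster arrives as two network components (the inner layer is still
  recovered in full). This mirrors the noise-window dependence of
  outer-layer detection reported for the method, and is visible in the
  acceptance suite, which runs one fixed replicate.
* The LOESS screen's rationale is expression sparsity; on continuous
  simulated data it degenerates to trimming the lowest-similarity tail.
* Modularity-based scanning is unweighted by design; similarity magnitudes
  influence network construction and screening but not the community
  objective.
* The per-cell embedding is exact ($O(N)$ PMFGs of $O(\log N)$ nodes each,
  each built with an exact planarity test); no approximate nearest-neighbour
  index is used, so very large $N$ pays an $O(N^2)$ similarity cost.

Test suites run the full pipeline at up to 1050 cells × 500 features (the
two-layer preset) and verify the generator's correlation calibration at
5000 features; unit tests work on instances of 2–50 cells where brute-force
oracles (BFS shortest paths, exhaustive single-split SSE, exhaustive
permutation enumeration) are feasible.
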