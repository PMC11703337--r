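# msclust

Unsupervised **multi-scale clustering (MSC)** of single-cell expression
profiles on sparse planar similarity networks.

Graph-based single-cell clustering usually starts from a k-nearest-neighbour
(kNN/SNN) graph and optimises Reichardt–Bornholdt modularity

> Q_RB(γ) = (1/2m₀) Σ_c ( e_c − γ K_c² / (2m₀) )

at a user-chosen resolution γ. Two practical problems follow: the kNN graph
is dense (m₀ ~ N²·k), which tightens the modularity resolution limit and
hides small populations, and a single γ cannot expose cell types *and* their
subtypes at once. `msclust` addresses both:

1. **Locally embedded network (LEN).** For every cell, neighbourhood size k
   grows from 3 while a *planar maximally filtered graph* (PMFG) is built on
   the cell plus its k most similar cells; the cells adjacent to the focal
   cell stabilise at k′ ~ log N and become its embedded neighbours. Planarity
   caps each local graph at 3(N−2) edges (Euler's relation), so the union
   over cells is sparse by construction — in practice 3 ≤ m/N ≤ 5 versus
   ~28–40 for SNN graphs. Two screens then drop low-quality edges: a LOESS
   band on similarity versus the expressed-gene Jaccard index removes
   low-similarity outliers, and a shared-neighbour contest removes redundant
   weak edges while preserving bridges.
2. **AdaptSplit + top-down hierarchy.** Each network (or sub-network) is
   clustered by Leiden across γ ∈ (0, 2]; the intra-cluster link count
   K_in(γ) is fitted with a step function and the clustering at the median γ
   of the first stable regime is taken as the split. Children are accepted
   only if they are more compact than the parent (v(α) = mean shortest-path
   distance / (log N_c)^α, with α calibrated from sampled 3-hop
   neighbourhoods) and their intra-cluster connectivity λ_c = e_cc/e_c is
   permutation-significant. Accepted children are split recursively; the
   result is a hierarchy of nested, overlapping cell clusters.

The package also ships the hierarchical Gaussian simulator used to study the
method (block-correlated samples with optional two-layer structure and
additive noise), overlap-aware evaluation metrics (inclusion rate, coverage
rate, detection accuracy), the adjusted Rand index, and cluster–sample
Fisher enrichment with condition labels.

Intended users: computational biologists who want unsupervised discovery of
cell types *and* subtypes from scRNA-seq (or any cells × features matrix)
without committing to a single clustering resolution.

## Worked example

Simulate a small two-layer dataset — 6 correlated blocks of 25 cells
(ρ_in = 0.25) adjoined into 2 outer clusters (ρ_out = 0.125), noise
σ = 0.2 — and run the full pipeline:

```r
library(msclust)
spec <- scenario_spec("II", inner_sizes = rep(25L, 6),
                      outer_grouping = rep(1:2, each = 3),
                      rho_in = 0.25, delta_rho = 0.125, sigma = 0.2,
                      n_features = 500, seed = 5)
sim <- simulate_dataset(spec)
res <- run_pipeline(sim, config = msc_config(seed = 7), verbose = TRUE)
#> stage similarity: Pearson correlation
#> stage len: local embedding of 150 cells
#>   raw union: 641 edges (m/N = 4.27)
#> stage screen: similarity + centrality screens
#>   final network: 493 edges (m/N = 3.29), 2 components
#> stage cluster: iterative top-down splits
#>   hierarchy: 8 nodes, 0 unassigned cells
h <- res$hierarchy
h$nodes[, c("id", "parent", "size", "gamma_f", "v", "lambda", "p_value")]
#>   id parent size gamma_f         v    lambda    p_value
#> 1 M1   root   75    0.70 1.6075579        NA         NA
#> 2 M2   root   75    0.75 1.0399969        NA         NA
#> 3 M3     M1   25      NA 0.8824923 0.9866667 0.00990099
#> 4 M4     M1   25      NA 0.9655143 0.9687500 0.00990099
#> 5 M5     M1   25      NA 0.8086951 0.9687500 0.00990099
#> 6 M6     M2   25      NA 0.7838827 0.9029126 0.00990099
#> 7 M7     M2   25      NA 0.9272213 0.8356164 0.00990099
#> 8 M8     M2   25      NA 0.7913483 0.9009901 0.00990099
```

Reading the table: the screened network falls into 2 components — the outer
clusters — which become the roots M1 and M2 (75 cells each). AdaptSplit
picked γ_f = 0.70 and 0.75 for the two roots and their children M3–M8 are
the six inner blocks: each child is more compact than its parent (smaller v), keeps
84–99 % of its incident edges internal (λ), and its coherence is
permutation-significant (p ≈ 0.0099, the smallest value attainable with 100
permutations). Against the ground truth:

```r
detection_accuracy(hierarchy_clusters(h), truth_clusters(sim, "inner"))$overall
#> [1] 1
hierarchy_newick(h)
#> ((M3:25,M4:25,M5:25)M1:75,(M6:25,M7:25,M8:25)M2:75)root;
```

Both layers are recovered exactly: every inner block is matched at Jaccard
index 1 by a leaf, and the outer clusters by the roots.

## Command line

A thin CLI wraps the same functions (installed at `exec/msclust`, or run via
`Rscript exec/msclust`):

```sh
msclust simulate --scenario II --rho-in 0.25 --delta-rho 0.125 --sigma 0.2 \
                 --n-features 500 --seed 1 --out sim
msclust run --input sim.data.tsv --format tsv_dense --allow-negative \
            --similarity pearson --outdir msc_out --seed 1
msclust evaluate --result result.tsv --truth truth.tsv --out metrics.json
```

`run` writes the screened edge list, a screen report, the hierarchy JSON,
the long cell–node membership table, metrics (when ground truth is given)
and a reproducibility manifest; identical inputs and seed reproduce the
files byte for byte.

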