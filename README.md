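# tfcooc — proximity-based TF co-occurrence graphs and clustering

Transcription factors (TFs) bind the genome cooperatively: complexes of
"anchor" TFs on DNA and "association" TFs bound to the anchors leave their
binding sites — ChIP-seq peaks or motif matches — within a few hundred base
pairs of one another.  ChIP-seq and motif scanning say *where* a TF binds
but nothing about *with whom*.  `tfcooc` is for regulatory genomicists who
have per-TF binding-site coordinates for one cell type and want (a) the
TF–TF interaction graph and its clusters, and (b) a way to use that graph
to clean up noisy motif-scan site predictions.

## The method

For each TF *t* with sites *B_t*, an *n* × *m_t* binary co-occurrence
matrix **M**_t records which of the *n* TFs has a site within `window_bp`
(default 1000 bp, radius) of each site of *t*.  Row means give the
co-occurrence frequency vector **f**_t; subtracting the background vector
**f**_all (each TF's genome-wide windowed prevalence, the row mean of all
**M**_t concatenated) yields the normalized, signed

> **f**′_t = **f**_t − **f**_all

which form the columns of the directed adjacency **A**; the undirected
weight matrix is **W** = (**A** + **A**ᵀ)/2.  The complete graph over *n*
TFs has *n*(*n*+1)/2 edges, self-loops included.

Edges are filtered to a user-chosen false-positive rate by a permutation
null: co-occurrence matrices are replaced by Bernoulli dummies whose row
sparsities match **f**_all, the construction is rerun 25 times, and all
25 *n*² directed dummy weights form the null pool.  The FPR-α threshold is
the smallest pooled weight with at most a fraction α of the pool strictly
above it.  The filtered graph is partitioned with a native Markov
Clustering (MCL) implementation (expansion / inflation / pruning;
inflation default 2.5, useful range 2–5).  Separately, the *unfiltered*
signed graph scores each putative site of a target TF by the sum of edge
weights from the target to every neighboring putative site in the window;
sweeping the retention cutoff traces precision–recall curves against
held-out actual sites.  Seeded generators for planted co-binding clusters,
independent-binding null data and true/decoy site fixtures make every
stage testable without downloads.

## Worked example

```r
library(tfcooc)

# a synthetic dataset with 2 planted co-binding clusters of 6 TFs each
cfg <- planted_config(n_tfs = 12, n_clusters = 2, tfs_per_cluster = 6,
                      complexes_per_cluster = 120, background_rate = 150)
sim <- generate_planted(cfg, seed = 1)

graph <- build_graph(sim$collection, window_bp = 1000)
print(graph)
#> TF co-occurrence graph: 12 nodes, 78 undirected edges (incl. self-loops)
#>   window: 1000 bp; built from 3014 sites
#>   edge weights: [-0.1380, 0.1905]

pool <- dummy_pool(graph, n_reps = 25, seed = 2)
thr <- threshold_for_fpr(pool, fpr = 0.01)
print(thr)
#> FPR threshold: 0.0493158 (target FPR 0.01, achieved 0.01, pool 3600)

filtered <- filter_graph(graph, thr)
clustering <- mcl_cluster(filtered, inflation = 2.5)
print(clustering)
#> MCL clustering: 2 clusters over 12 TFs (0 unclustered), inflation 2.5
#>   cluster sizes: 6, 6
#>   converged in 10 iterations
```

The 78 edges are all TF pairs including self-loops (12·13/2); the
threshold 0.049 is the smallest dummy weight with ≤ 1% of the null pool
above it; the two recovered clusters are exactly the planted ones.
Reusing the unfiltered signed graph to filter noisy putative sites of the
first TF (500 uniform decoys mixed into its true sites):

```r
fx <- generate_filter_fixture(cfg, decoy_count = 500, seed = 3)
res <- run_filter_workflow(fx$putative, fx$actual, cfg$target_tf, seed = 4)
print(res$summary, digits = 3)
#>           method cutoff n_retained precision recall     f
#> 1            sum 0.1993         96     1.000  0.990 0.995
#> 2 normalized_sum 0.0625        109     0.890  1.000 0.942
#> 3         length 2.0000         98     0.980  0.990 0.985
#> 4 length_flipped    Inf        597     0.163  1.000 0.280
#> 5     unfiltered   -Inf        597     0.163  1.000 0.280
#> 6         random     NA         96     0.170  0.168 0.169
```

Keeping only sites whose neighborhoods carry positive summed edge weight
lifts the F-score from 0.28 (unfiltered) to 0.99 at the best cutoff, while
removing the same number of sites at random leaves F at 0.17 — the score's
*identity* information, not the removal itself, does the work.

A command-line front-end wrapping these functions ships in
`inst/cli/tfcooc.R` (subcommands `build-graph`, `calibrate-fpr`,
`cluster`, `score-tfbs`, `evaluate`, `simulate`).

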