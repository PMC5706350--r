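---
title: "Proximity-based TF co-occurrence graphs: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity-based TF co-occurrence graphs: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcooc)
```

## The model

Transcription factors (TFs) rarely act alone: they assemble into complexes,
with "anchor" TFs contacting DNA and "association" TFs binding the anchors.
Wherever a complex is active, the binding sites of its members — ChIP-seq
peaks or motif matches — end up within a few hundred base pairs of one
another.  `tfcooc` turns that spatial signal into a weighted TF–TF graph.

For each TF $t$ with sites $B_t = (b_1, \dots, b_m)$, the binary
co-occurrence matrix $M_t$ has entry $(i, j) = 1$ when TF $i$ has at least
one site within the proximity window of site $b_j$.  Row means give the
co-occurrence frequency vector

$$ f_t[i] = \frac{1}{m_t} \sum_j M_t[i, j], $$

the fraction of $t$'s sites at which TF $i$ appears nearby.  Raw
frequencies are dominated by how often a partner binds *anywhere*: a
ubiquitous binder such as CTCF co-occurs with everything.  The background
vector $f_{all}$ — the row mean of all $M_t$ concatenated, i.e. each TF's
genome-wide windowed prevalence — is therefore subtracted:

$$ f'_t = f_t - f_{all}. $$

Subtraction, rather than division, penalizes every TF by the same absolute
amount, and deliberately produces *negative* entries where a TF appears
near $t$ less often than it appears anywhere — evidence of avoidance that
the site-scoring stage exploits.  The $f'_t$ assembled column-wise form the
directed adjacency matrix $A$; the undirected edge weight is the symmetric
average $W = (A + A^\top)/2$.  The unfiltered graph is complete: all
$n(n+1)/2$ unordered pairs, self-loops included, carry a signed weight.

Three conventions here were genuinely open and are worth stating:

* **Window semantics.** "Within $w$ bp" is read as *radius*: a site
  co-occurs with focal site $b$ when it intersects $b$ extended by
  `window_bp` on each side (half-open, BED-convention arithmetic).  A
  total-width reading would halve the effective window; `window_bp` is a
  parameter everywhere, so either convention is reachable.
* **Focal-site exclusion.** A site is not its own neighbor — otherwise
  every diagonal entry of $M_t$ would be identically 1 — but *other* sites
  of the same TF do count, which is what gives self-loops informative
  weights (homotypic clustering is real signal).
* **Symmetrization.** $A$ is asymmetric because $f_t$ conditions on $t$'s
  sites ($t$ may always appear near a promiscuous partner while being a
  negligible fraction of that partner's neighborhoods).  The arithmetic
  mean is the symmetric estimator that stays inside $[-1, 1]$.

## Edge filtering by empirical false-positive rate

The normalized weights are differences between a sample mean over a
non-random set of sites and a population mean, so no parametric null is
trustworthy.  The cutoff below which edges are deemed noise is instead
calibrated by permutation: each $M_t$ is replaced by a dummy matrix whose
row $i$ is i.i.d. Bernoulli($f_{all}[i]$) — per-TF abundance preserved,
genomic order destroyed — and the whole adjacency construction is rerun,
including recomputing the background vector from the dummy matrices.  All
$n^2$ *directed* entries of each dummy $A$ are pooled over `n_reps = 25`
repeats (the pool is directed because symmetrizing first would halve the
pool; pool sizes then equal $25\,n^2$).  Only row sums of a dummy matrix
ever enter the construction, so the implementation draws each row sum
directly as a Binomial($m_t$, $f_{all}[i]$) count — distributionally
identical to materializing the Bernoulli entries and far cheaper.

Given a target FPR $\alpha$, the threshold $\theta$ is the smallest pooled
weight such that the fraction of dummy weights *strictly above* $\theta$ is
at most $\alpha$; graph edges with weight *below* $\theta$ are removed, so
ties at the threshold survive.  The achieved FPR is reported, since ties
can leave it below the target.  On an independent-binding synthetic dataset
(30 TFs, 200 sites each, 100 Mb genome) the realized fraction of directed
null weights above $\theta$ stays within three binomial standard errors of
$\alpha$ for $\alpha \in \{0.1, 0.01\}$ — the calibration property the test
suite checks.

## Markov Clustering

The filtered graph is partitioned with a native implementation of MCL:
iterate *expansion* (squaring the column-stochastic flow matrix),
*inflation* (entrywise power `inflation`, then column renormalization) and
*pruning* (zero entries below `prune_below`, renormalize) until the largest
entrywise change falls below $10^{-8}$, capped at `max_iter` iterations.
Clusters are the connected components of the converged matrix's nonzero
support, which also resolves nodes attracted to two attractor systems
deterministically (overlapping systems merge).  Numerical choices:

* `inflation = 2.5` by default; the useful range is about 2–5, larger
  values giving finer partitions.  `sweep_inflation()` tabulates metrics
  over a grid for empirical selection.
* `prune_below = 1e-5` and the $10^{-8}$ convergence tolerance follow
  common MCL practice; results are insensitive to both on all fixtures.
* **Self-loops.** Surviving data-derived self-loops are kept as flow.  A
  node whose self-loop was filtered away gets one added at its *maximum
  incident edge weight*.  The textbook convention adds unit loops, which is
  correct for unweighted graphs but catastrophic here: data weights are
  $O(0.1)$, so a unit loop dominates every column and each node becomes its
  own attractor.  Matching the strongest incident edge preserves the
  loop's role (damping parity effects of the random walk) without drowning
  the data.  Isolated nodes get a unit loop and become absorbing singleton
  states.
* **Singletons are "unclustered".** Every reported cluster has at least two
  members; singleton components join the unclustered set, which is how an
  unclustered percentage coexists with clusters of size $\ge 2$.
* Negative edge weights are refused with a pointer to FPR filtering: MCL
  interprets weights as flow capacities, for which sign has no meaning.

## Scoring putative binding sites

The second use of the graph needs the *unfiltered, signed* version.  A
putative site of a target TF is plausible when its window is full of the
target's habitual partners, and suspect when the neighborhood is dominated
by TFs the target avoids.  The sum-score of a site is the sum of
$W[\text{target}, \text{tf}(s)]$ over every neighboring putative site $s$
in the window — per site *instance*, not per distinct TF, so several
co-occurring partners boost the score; other sites of the target itself
count through the self-loop weight.  The normalized variant divides by the
neighbor count (0 for isolated sites, a division guard); the "length" score
is the bare neighbor count.

Retention at a cutoff keeps sites with score $\ge$ cutoff.  Sweeping the
cutoff over the distinct observed scores (preceded by $-\infty$, the
unfiltered set) traces a precision–recall curve: recall is the fraction of
actual sites whose window contains a retained putative interval; precision
is the fraction of *merged* retained intervals whose window contains an
actual site.  Merging first (interval union per chromosome) keeps the
denominator well defined — with raw counts a single actual site flanked by
many overlapping putative matches could push precision past 1.  Cutoffs
that would empty the retained set are not visited, since precision is
undefined there.  The neighbor-count score is additionally swept in the
flipped direction (retain $\le$ cutoff), because it can be negatively
correlated with the sum-score.  The random baseline removes the same
number of sites uniformly at random, isolating the contribution of score
*identity* from that of mere set shrinkage.

## What the synthetic generators do and do not emulate

All tests and calibration runs use seeded generators, not downloads:

* `generate_planted()` draws complex loci uniformly on a single uniform
  chromosome; each cluster member binds each locus with
  `participation_prob = 0.8` at a position jittered uniformly within
  ±300 bp, on top of Poisson(300) uniform background sites per TF.  The
  default study condition is 3 clusters × 8 TFs, 200 complexes per
  cluster, 200 bp sites, a 100 Mb genome.  Jitter is kept below the
  1000 bp window so planted partners register as co-occurring; the genome
  length keeps background collisions (~1% per site pair) well below the
  planted signal (~30% co-occurrence).
* `generate_null()` places every TF's sites independently and uniformly —
  the genomic-space realization of the dummy-matrix null, used for FPR
  calibration.
* `generate_filter_fixture()` builds a putative/actual pair: actual = the
  target's complex-derived sites; putative = re-jittered copies of those
  plus uniform decoys plus all other TFs' sites.

What this *does not* emulate: chromatin domains, peak-width and
peak-height heterogeneity, mappability artifacts, motif self-overlap, or
multiple chromosomes (supported throughout, but the generators default to
one, as nothing in the method couples chromosomes).  Decoys are uniform,
so on fixtures the neighbor-count score is also informative — true sites
sit in dense complex neighborhoods — whereas on real motif-scan data
dense regions are not necessarily enriched for true sites.  Passing the
planted-recovery and filtering-benefit tests therefore demonstrates
correctness of the machinery under the model's own assumptions, not
performance on any particular organism's data.

## Evaluation utilities

`compare_to_reference()` restricts the graph and a reference interaction
table (STRING `protein.links.detailed` layout, combined-score threshold
400 = "medium confidence" by default, exposed as a flag) to their shared
TFs, then counts TP/FP/FN/TN over unordered pairs, self-loops excluded
(protein-interaction references have no self-pairs).  Precision with zero
predicted edges is reported as 0 with a warning, keeping sweeps total.
`channel_enrichment()` compares each evidence channel's scores between
reference pairs matched and unmatched by the graph with a one-sided
Wilcoxon rank-sum test (normal approximation): channel scores are bounded,
zero-inflated and far from normal, so a rank test is the defensible
default; if every score is tied the test carries no evidence and p = 1 is
returned.  `similarity_regression()` is ordinary least squares of edge
weight on averaged PWM-similarity scores; a low $R^2$ indicates the graph
captures interactions that motif similarity cannot.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to run in
minutes on a laptop: oracle-equivalence checks use 50 randomized
collections of ≤ 200 sites against brute-force $O(m^2)$ interval loops;
planted recovery uses 20 seeded end-to-end runs of the 24-TF condition
above; the filtering benefit uses 20 fixtures with 1000 decoys, 10 random
draws each.  Every stochastic component takes an explicit seed
(`withr::with_seed`, global RNG untouched), identical seeds give
byte-identical artifacts, and workflow manifests record seed, parameters
and the achieved FPR.

## Known limitations

* Cluster assignments are putative, with no per-cluster confidence level;
  the FPR controls edge-level, not cluster-level, error.
* The permutation null preserves per-TF abundance but not local chromatin
  context; in real genomes accessibility co-localizes all TFs, so
  thresholds calibrated on the dummy null are liberal in hotspots.
* The graph is cell-type-specific by construction; clusters from one
  dataset do not transfer.
* Weights are associations between site sets, not physical contacts:
  indirect co-occupancy (two TFs sharing a third partner) is
  indistinguishable from direct interaction.
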