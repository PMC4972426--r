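---
title: "Clustering binding-site motifs with per-node maximal cliques"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering binding-site motifs with per-node maximal cliques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climpr)
```

## The model

A motif is the set of binding sites recognized by one transcription
factor, summarized by a position frequency matrix (PFM, per-column base
counts) or a position weight matrix (PWM, per-column log-odds against a
background). Motif-finding tools recover a factor's motif piecemeal: the
same well-conserved *sub-motif* is predicted many times, and a factor with
several sub-motifs is recovered as several partially overlapping groups of
predictions. On a similarity graph — nodes are motifs, an edge connects
two motifs whose similarity reaches a cutoff γ — each sub-motif's
predictions are expected to form a clique, and a factor's motif the union
of a few overlapping cliques. That picture motivates the clustering model
implemented here (`climp()`): find one maximal clique per node, then merge
overlapping cliques into clusters.

The key assumption is that within-factor similarity generally exceeds
between-factor similarity at the chosen γ, so that blocks of the graph are
dense and between-block edges are rare. Clustering quality degrades
gracefully, not catastrophically, when this fails: the merge thresholds
and the redundancy-removal step (below) localize mistakes to the cliques
involved.

## Parameters that matter

* **γ (gamma)**, dimensionless similarity cutoff in [0, 1], default 0.6.
  Only pairs scoring ≥ γ become edges. On our self-normalized score scale
  (score of a motif with itself is exactly 1) the informative range is
  roughly 0.4–0.7; 0.6 gives a sparse graph that still keeps most
  within-family pairs connected (measured on the synthetic replica below:
  ~87% of within-family pairs, <0.1% of cross-family pairs).
* **α (alpha)**, overlap threshold in (0, 1], default 0.5: the fraction of
  a candidate clique's nodes that must already be in a cluster for the
  clique to merge into it.
* **β (beta)**, adjacency threshold in (0, 1], α ≤ β, default 0.5: the
  fraction of the clique's nodes that must be in the cluster *or* adjacent
  to it. Nodes already inside the cluster count toward β (they are
  adjacent to other members whenever the cluster has ≥ 2 nodes), which
  guarantees the β-ratio is never below the α-ratio and keeps the
  constraint α ≤ β meaningful.
* **min_overlap**, default 4 columns: the shortest ungapped alignment
  considered by the similarity score.
* **pseudocount**, default 0.25 per PFM cell, and a uniform background:
  standard smoothing so single-site motifs have finite log-odds. The
  background must be strand-symmetric for the score's reverse-complement
  invariance to hold exactly.
* **workers**: a performance knob for the per-node clique loop and the
  all-pairs score matrix; it never changes any output (the test suite
  asserts bit-identical results for 1, 2, 4 and 8 workers).

## The similarity score

The score is a reconstruction of the SPIC idea — weight the
cross-likelihood between one motif's PWM and the other's column
frequencies by column information content, compute it in both directions,
and average — specified here completely because only its outline is
published. For columns *i* of motif 1 and *j* of motif 2:

s(i, j) = ½ [ IC₁(i) · Σ_b f₂(b, j) · pwm₁(b, i) + IC₂(j) · Σ_b f₁(b, i) · pwm₂(b, j) ]

with f the pseudocount-smoothed frequencies, pwm the log₂ odds against the
background, and IC(i) = 2 + Σ_b f log₂ f. The raw score of an ungapped
alignment is the sum of s over its aligned column pairs divided by
min(L₁, L₂); the raw similarity is the maximum over all offsets with
overlap ≥ `min_overlap` and over both orientations of the second motif;
the final score is raw(m₁, m₂) / √(raw(m₁, m₁) · raw(m₂, m₂)), clipped to
[−1, 1] and floored at 0. It is symmetric, equals 1 on self, and is
invariant to reverse-complementing either argument.

**Why divide by min(L₁, L₂) rather than the overlap length?** Dividing by
the overlap makes a chance 4-column match score as well per column as a
full-length match; empirically that connects a few percent of unrelated
motif pairs at γ = 0.6 and fuses the graph into one component, which
contradicts both the intended sparsity of the metric and the recovery
experiment it must support. Scaling by the shorter motif's length leaves
full-overlap comparisons untouched (for equal lengths it *is* the mean)
and penalizes partial overlaps in proportion to the columns they ignore.
This is the one place we deviate from a plain per-column mean, and it is a
design choice of this package. No numeric parity with the original SPIC
program is claimed; precomputed similarity files from any external metric
can be used instead via `read_edge_list()`, which is the compatibility
path for reproducing published runs.

## Numerical and procedural choices

* **Cutoff comparison** is exact `>=` on the parsed decimal weight; no
  epsilon. Duplicate unordered edge records keep the maximum weight (the
  conservative rule: an edge that would pass the cutoff under either
  record survives), with a warning.
* **Clique search stopping rule**: deletion stops when all nodes of C_v
  have equal degree; because the seed v is adjacent to every remaining
  node, equal degrees are equivalent to completeness, and the
  implementation tests completeness in O(1) via the internal edge count.
* **Re-insertion** scans the deleted nodes from u₍k−1₎ down to u₁. The
  last-deleted node u_k is excluded; a node whose deletion completed the
  clique can never be adjacent to all remaining members, so the exclusion
  is also a no-op — it is kept for fidelity to the published procedure.
* **Merge target**: the pseudo-code merges C_j "into C_i" while C_i grows,
  leaving ambiguous whether later tests compare against the seed clique or
  the accumulated cluster. Default is the accumulated cluster (matching
  the in-place merge); `climp_config(merge_target = "seed")` selects the
  alternative.
* **Tie-breaks** (the published procedure specifies none): neighbor scan
  order ties break by ascending node id; clique and cluster ranking ties
  break by larger size, then smallest member id; a node with equal
  incident sums in two clusters stays in the higher-ranked one. All
  orderings use locale-independent (radix) string order, so runs are
  reproducible across machines.
* **Degenerate ARI**: when the denominator of the adjusted Rand index is
  0 (both partitions trivial) the value is defined as 1 if the numerator
  is 0 and 0 otherwise.
* **Degenerate motifs**: an exactly uniform motif has zero information
  content everywhere, hence zero self-similarity; its score against
  anything is defined as 0 (with a warning).
* **Isolated nodes** are dropped when reading an edge list unless
  `keep_isolated = TRUE`; nodes present in the graph always end up in
  exactly one cluster (isolated ones as singletons). The CLI suppresses
  singleton clusters in its output by default (`--keep-singletons`
  restores them); the evaluation utilities operate on whatever cluster
  list they are given, so the ARI universe is the clustered nodes.

## What the synthetic world does and does not establish

The generators encode the benchmark design, with sizes fixed up front:

* `split_motif()` reproduces the sub-motif benchmark: a motif of *n* sites
  is split, for each k = 1..⌊n/2⌋, into random disjoint subsets of sizes k
  and n−k (2⌊n/2⌋ sub-motifs per motif, full site set reused across k);
  the parent id is the truth label.
* `random_motif_family()` stands in for curated profiles: independent
  random consensus sequences, sites copying the consensus with probability
  `conservation` (default 0.9, length 8, 20 sites in the desk-scale
  replica — values chosen once to model short, well-conserved eukaryotic
  TFBS profiles at a size that runs in seconds).
* `planted_partition_graph()` skips motifs entirely and plants blocks
  (default 5 × 20 nodes, within-block edge probability 0.9 and weights
  U(0.6, 1), between-block 0.02 and U(0.4, 0.6)).

A green end-to-end test establishes that the pipeline recovers planted
structure when the within/between similarity separation assumption holds
at desk scale (ARI ≥ 0.8 with all thresholds above, and strictly better
than a connected-components baseline on the same graph). It does *not*
establish performance on real JASPAR-scale collections (hundreds of
thousands of nodes, heterogeneous motif lengths and conservation, an
externally computed score scale), nor anything about the published
genome-wide numbers, which depend on external datasets and the original
metric binary. Random consensus families can occasionally be mutually
similar by chance; the acceptance thresholds leave room for that, and the
redundancy/ranking steps are what keep such collisions local.

## Known limitations

* Only ungapped motif alignment; no E-values for similarity; no support
  for directed or multi-graphs.
* The greedy per-node clique is order-dependent by design (that is the
  point: it biases toward the seed's strongest neighbors); it does not
  find maximum cliques.
* `merge_cliques()` is worst-case quadratic in the number of unique
  cliques; fine up to tens of thousands of cliques, not tuned beyond that.
* The similarity scale is this package's own; cutoffs quoted for other
  SPIC implementations transfer only approximately.
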