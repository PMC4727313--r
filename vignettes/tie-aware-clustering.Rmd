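---
title: "Tie-aware hierarchical clustering: enumeration, contrasts and cluster frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tie-aware hierarchical clustering: enumeration, contrasts and cluster frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tieclust)
```

## The problem

Agglomerative hierarchical clustering repeatedly merges the two closest
clusters. When two candidate pairs are *exactly* equidistant — a tie in
proximity — the merge is not determined, and off-the-shelf implementations
resolve it by an accident of input order. With discrete, counted or
low-precision attributes such exact coincidences are common, so the
dendrogram a single run reports is one member of a possibly large family of
equally valid results. `tieclust` enumerates that family and quantifies how
often any given cluster occurs in it.

A *dendrogram* here is a rooted, strictly binary, leaf-labeled tree; on a
set of n items, any of its dendrograms contains 2n − 1 clusters including
singletons, and n − 1 *nontrivial* clusters (subtrees with at least two
leaves). Multifurcations are deliberately rejected rather than collapsed:
grouping several tied clusters in one node is a different modelling choice
(multidendrograms) from the one taken here, which keeps each binary
resolution as its own outcome.

## Enumeration by branching on ties

`tie_hclust()` performs a depth-first search over merge sequences. At each
state (a set of active clusters) it computes all inter-cluster
dissimilarities under the chosen linkage, finds the minimum d*, and opens
one branch for every pair within tolerance of d*; each branch merges its
pair at the pair's own dissimilarity (recorded as the node's merge height)
and recurses. Completed trees are deduplicated by canonical form, so the
reported m counts *distinct* dendrograms, each once — the only reading under
which the nine-point toy example below yields six dendrograms rather than a
multiplicity-weighted count.

Two implementation points matter for correctness and speed:

* **Path-independent distances.** For the four supported linkages the
  inter-cluster dissimilarity can be computed directly from the original
  leaf-level matrix: minimum (single), maximum (complete), plain mean over
  cross pairs (group average / UPGMA) or a mean weighted by 2^−depth of
  each leaf in its cluster tree (simple average / WPGMA). This is
  equivalent to the Lance–Williams recursion but makes the dissimilarity a
  function of the active cluster *trees* alone, independent of the merge
  order that produced them.
* **State memoization.** Different orders of merging disjoint tied pairs
  pass through identical states. Because distances are path-independent,
  the set of completions reachable from a state depends only on the
  multiset of canonical cluster keys, which is used as a memo key; each
  state is explored once.

### Canonical forms

Equality of trees and subtrees is decided by a canonical key: the key of a
leaf is its label, and the key of an internal node combines its children's
keys with the child containing the smallest leaf label first. Two trees
have equal keys iff they are isomorphic as rooted, unordered, leaf-labeled
trees (the test suite checks this against a brute-force isomorphism search
on all topologies with up to 5 leaves). `write_newick()` emits children in
the same order, so serialized output is a deterministic function of the
topology. Newick input is parsed with `ape`; branch lengths and internal
labels are accepted and ignored, since the contrasts depend only on
topology and leaf membership — correspondingly, the distance matrix can be
scaled by any positive factor without changing the enumerated set.

### Tunable parameters

* `method` (default `"group_average"`): UPGMA; `"simple_average"` (WPGMA),
  `"single"` and `"complete"` are also available. On the toy example
  group and simple average enumerate the same six trees, because the
  branching happens among singleton merges where the two rules coincide.
* `abs_tol`, `rel_tol` (defaults 0 and 1e−9, dissimilarity units and
  dimensionless): a pair at dissimilarity d ties the minimum d* when
  d ≤ d* + max(abs_tol, rel_tol·d*). The ties of interest are exact
  equalities, but floating-point distance updates can split an exact tie
  by a few ulps (in the toy data, the planted equilateral triangle has one
  side computed as 4 and two as 4 − 2⁻⁵¹); the relative default recovers
  such ties while keeping genuinely distinct values apart. Raising
  `abs_tol` turns the tool into a near-tie sensitivity analysis.
* `cap` (default 200 000 trees): the number of distinct dendrograms is
  exponential in the worst case — F(n) = (2n−3)!! on an equidistant matrix —
  so enumeration stops collecting at the cap and flags the result
  `capped` rather than truncating silently.

Items at distance zero are *not* auto-merged; `dedupe_zero_distance()`
collapses each zero-distance equivalence class to one representative as an
explicit, inspectable preprocessing step, mirroring how duplicated
descriptor columns are reduced before clustering.

## Contrasts and frequency

A query cluster C (built by `cluster_query()`) is characterized as a graph
— a small dendrogram carrying its internal hierarchy — and/or as the set
L(C) of its leaves. Writing P(T) for the set of nontrivial subtrees of T
(n − 1 of them) and N = {s_j} for their leaf sets:

| contrast | value | reads |
|---|---|---|
| `cc_graph` | 1 iff P(C) = P(g_j) for some subtree g_j of D | C is a branch of D (or D itself) |
| `cc_relaxed_graph` | max_j J(P(C), P(g_j)) | best subtree-set Jaccard overlap |
| `cc_set` | 1 iff L(C) = s_j for some j | C's members form a branch, hierarchy ignored |
| `cc_relaxed_set` | max_j J(L(C), s_j) | best leaf-set Jaccard overlap |

Since a rooted binary leaf-labeled tree is uniquely determined by its set of
subtree leaf sets, P(C) = P(g_j) is equivalent to canonical-key equality of
C and g_j, which is how `cc_graph` is implemented (and why the Jaccard
numerators are computed on canonical-key sets). The maxima in the relaxed
contrasts range over *all* nontrivial subtrees of D, the root included.

`cluster_frequency()` averages a contrast over a dendrogram set sharing one
leaf set: f_j(C) = (1/m) Σ CC_j(C, D_i). Structural identities, all
property-tested: CC_g ≤ CC_rg, CC_s ≤ CC_rs and CC_g ≤ CC_s pointwise
(hence the same orderings for frequencies); CC_rg = 1 ⇔ CC_g = 1;
CC_rg = 0 ⇒ CC_g = 0; CC_rg > 0 iff C and D share a cherry; CC_s = 1 ⇔
CC_rs = 1. For a two-leaf C, `cc_graph`, `cc_relaxed_graph` and `cc_set`
coincide in {0, 1} and `cc_relaxed_set` equals 1 exactly when they do.
Note that `cc_relaxed_set` is *positive* for any C whose leaves lie in D —
its Jaccard with the root subtree is at least |L(C)|/n — so the four
contrasts do not literally take a common value on size-2 clusters; the
worked two-element example with value 2/3 shows exactly this.

In the maximal-tie case (an equidistant metric space) every topology is
reachable, and a cluster with k leaves is, as a graph, in exactly
F(n − k + 1) of the F(n) dendrograms: collapsing the cluster to a single
leaf maps the trees containing it bijectively onto the trees on the reduced
leaf set. `tiecase_graph_frequency()` evaluates this ratio with the common
double-factorial prefix cancelled, so the value is exact in floating point
for n ≤ 16 (beyond that `felsenstein_count()` itself exceeds the 2⁵³ exactly
representable integer range and warns). The identity is verified measured-vs-analytic
over the full topology sets for n = 3, 4, 5 and every cluster size.

Frequencies of the 0/1 contrasts are exact multiples of 1/m computed in
double precision (m is far below 2⁵³, so sums and the final division are
exact to rounding); reports display a rounded column (default 2 decimals,
so 1/3 prints as 0.33) beside a full-precision column.

## Synthetic data: what it does and does not emulate

The generators are pure functions of their arguments and reproduce the
regimes the method distinguishes:

* `toy_table1()` — nine points in two coordinates forming three
  well-separated groups with planted exact ties (an equidistant pair
  within one group, an equilateral triangle as another). Group merge
  order is strict, so all ambiguity is within-group: 1 × 2 × 3 = 6
  dendrograms.
* `equidistant_space(n, c)` — the maximal-tie case; enumeration must
  return all F(n) topologies, which the brute-force enumerator
  `enumerate_all_topologies()` (recursive leaf insertion; at most 8
  leaves, F(8) = 135 135) independently confirms.
* `random_tied_matrix(n, n_levels, seed)` — off-diagonal distances drawn
  from `n_levels` discrete values; fewer levels mean more ties, emulating
  discrete or low-precision attributes. One level degenerates to the
  equidistant space. These matrices need not be metric, which the
  enumeration does not require.
* `separated_clusters_with_ties()` — clusters of integer-coordinate
  "stars" (ties exact by construction, since equal distances arise from
  identical floating-point expressions) around geometrically spaced
  centers, so between-cluster merges are strictly resolved and the total
  m factorizes as the product of per-cluster counts.

What passing on these inputs does *not* show: behaviour on real descriptor
matrices, where ties arise from data precision rather than planted
symmetry, distances are high-dimensional Euclidean, and tie sets can reach
the cap (tens of thousands of items at desk scale are out of reach — the
sampling driver `cli_sample()` instead probes principal submatrices, the
design used for large studies). The problem sizes exercised in the tests —
enumeration up to n = 7 with heavy ties, full-topology oracles up to n = 6,
property sweeps on trees with up to 8 leaves — were chosen to keep the
whole suite near interactive speed while still covering every code path
and every analytic identity at more than one size.

## Degenerate inputs and edge behaviour

Two-item inputs return the single cherry. Zero distances are legal
(identical items); see `dedupe_zero_distance()` for the explicit reduction.
A capped enumeration flags `capped = TRUE`, propagates that flag into
frequency reports, and the CLI maps it to a non-zero exit status, since
frequencies over a partial set are estimates, not the tie-complete values.
Graph contrasts on a set-only query are a hard error rather than a silent
fall-back to the set contrast: the two answer different questions, and the
worked examples show them disagreeing. Cluster leaves must be a subset of
every dendrogram's leaves; anything else is an error, not a zero.

## Known limitations

* Exponential worst case: the cap bounds memory and time but makes the
  result partial; there is no sampling of the tie set itself (only of the
  input matrix via `cli_sample()`).
* Only the four listed linkages; Ward-style merging-criterion ties and
  similarity coefficients such as Tanimoto are out of scope.
* `felsenstein_count()` is exact only to n = 16; tie-case analytics beyond
  that scale are approximate.
* Dendrograms are strictly binary throughout; multifurcating inputs are
  rejected by design.
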