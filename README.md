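# tieclust

Hierarchical cluster analysis (HCA) breaks ties in proximity — situations
where two cluster pairs are exactly equidistant at a merge step — arbitrarily,
usually by input order. The single dendrogram a standard implementation
returns is then just one of possibly many, and any conclusion drawn from a
cluster in it ("these molecular descriptors belong together, keep one of
them") may be an artifact of the tie-breaking. This is routine with discrete
or low-precision data, as in chemoinformatics descriptor selection for QSAR
modelling.

`tieclust` makes the ambiguity measurable:

* **Enumeration.** `tie_hclust()` runs agglomerative clustering
  (group-average/UPGMA, simple-average/WPGMA, single or complete linkage)
  but branches on *every* tied minimum, collecting the full set
  {D_1, …, D_m} of distinct dendrograms the tie resolutions can produce
  (deduplicated by canonical topology, capped against combinatorial
  explosion). On n items at most F(n) = (2n−3)!! topologies exist
  (`felsenstein_count()`); with no ties m = 1, and on an equidistant matrix
  m = F(n).
* **Cluster contrasts.** Four functions decide whether a query cluster C
  occurs in a dendrogram D, from most to least stringent:
  - `cc_graph`: 1 iff C, *with* its internal hierarchy, is a branch of D;
  - `cc_relaxed_graph`: max_j |P(C) ∩ P(g_j)| / |P(C) ∪ P(g_j)|, the best
    Jaccard overlap between the nontrivial-subtree sets of C and of a
    subtree g_j of D;
  - `cc_set`: 1 iff C's leaf set equals the leaf set of some subtree of D;
  - `cc_relaxed_set`: max_j |L(C) ∩ s_j| / |L(C) ∪ s_j| over the subtree
    leaf sets s_j of D.
* **Frequency.** `cluster_frequency()` averages a contrast over any
  dendrogram set sharing one leaf set, f_j(C) = (1/m) Σ_i CC_j(C, D_i) —
  the empirical probability of the cluster. Because the contrasts depend
  only on topology and membership, the same machinery measures cluster
  *stability* across dendrograms from perturbed data or varied linkages,
  not just tie sets.

Deterministic generators (`toy_table1()`, `equidistant_space()`,
`random_tied_matrix()`, `separated_clusters_with_ties()`), Newick and
CSV/TSV I/O, and a command-line front end (`inst/cli/tieclust.R`, with
`enumerate`, `freq` and `sample` subcommands) round out the tool.

## Worked example

Nine points a–i in the plane form three well-separated groups
A = {a,b,c}, B = {g,h,i}, C = {d,e,f}, with ties planted inside B (the pairs
(g,i) and (h,i) are equidistant) and C (an equilateral triangle):

```r
library(tieclust)

fit <- tie_hclust(toy_table1(), method = "group_average")
fit
#> Tie-aware hierarchical clustering (group_average linkage)
#>   items: 9
#>   distinct dendrograms: 6
#>   merge states visited: 25; states with ties: 3

write_newick(fit$trees[[1]])
#> [1] "((((a,b),c),((g,i),h)),((d,e),f));"

frequency_report(list("(a,b);", "(g,i);", "(d,e);"), fit, methods = "g")
#>   cluster_id method frequency frequency_full m capped
#> 1     (a,b);      g      1.00      1.0000000 6  FALSE
#> 2     (g,i);      g      0.50      0.5000000 6  FALSE
#> 3     (d,e);      g      0.33      0.3333333 6  FALSE
```

The ties admit m = 6 dendrograms. (a,b) is a branch of all of them
(frequency 1); B can start with either (g,i) or (h,i), so each occurs in
half the set (0.5); the equilateral triangle gives (d,e) one of three
starts (0.33). Each complete dendrogram has frequency 1/6 — so a single
ordinary HCA run would be showing you one outcome among six equally valid
ones. A contrast on its own:

```r
cc_relaxed_set("a,d", parse_newick("((c,d),a);"))
#> [1] 0.6666667
```

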