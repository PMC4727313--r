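# The four cluster-contrast functions and the cluster-frequency estimator.
#
# A query cluster C is characterized in two ways: as a graph (a small
# dendrogram on its leaves, carrying hierarchical structure) and as a set
# (its leaf labels only).  Each characterization has a strict contrast
# (exact membership, 0/1) and a relaxed one (a maximum Jaccard index in
# [0, 1]), giving four contrasts from most to least stringent:
# graph > relaxed graph > set > relaxed set.

#' Build a cluster query
#'
#' A cluster can be given in graph form (a Newick subtree, keeping its
#' internal hierarchy) or in set form (just its leaf labels).  Graph-form
#' queries support all four contrasts; set-form queries support only the set
#' contrasts -- requesting a graph contrast on a set-only query is an error,
#' never a silent fallback, because the two answer different questions.
#'
#' @param x one of: a Newick string ending in `;` (graph form); a single
#'   comma-separated string or a character vector of two or more labels (set
#'   form); a `"dendro"` object (graph form); or an existing
#'   `"cluster_query"`, returned unchanged.
#' @param id optional identifier used in reports; defaults to a compact
#'   rendering of the query.
#' @return an object of class `"cluster_query"` with fields `id`, `graph`
#'   (a `"dendro"` or NULL) and `leaves` (sorted labels, at least 2).
#' @examples
#' cluster_query("(g,i);")   # graph form
#' cluster_query("d,e,f")    # set form
#' @export
cluster_query <- function(x, id = NULL) {
  if (inherits(x, "cluster_query")) {
    if (!is.null(id)) x$id <- id
    return(x)
  }
  if (inherits(x, "dendro")) {
    graph <- x
    leaves <- x$leaves
  } else if (is.character(x) && length(x) == 1L && grepl(";\\s*$", x)) {
    graph <- parse_newick(x)
    leaves <- graph$leaves
  } else if (is.character(x)) {
    leaves <- if (length(x) == 1L) trimws(strsplit(x, ",")[[1L]]) else trimws(x)
    leaves <- leaves[nzchar(leaves)]
    if (anyDuplicated(leaves)) stop("duplicate labels in cluster: ", paste(x, collapse = ","))
    graph <- NULL
    leaves <- sort(leaves)
  } else {
    stop("cannot interpret cluster query of class ", paste(class(x), collapse = "/"))
  }
  if (length(leaves) < 2L) stop("a cluster needs at least 2 leaves")
  if (is.null(id)) {
    id <- if (is.null(graph)) paste(leaves, collapse = ",") else write_newick(graph)
  }
  structure(list(id = id, graph = graph, leaves = leaves), class = "cluster_query")
}

#' @export
print.cluster_query <- function(x, ...) {
  cat("Cluster query [", x$id, "]: ",
      if (is.null(x$graph)) "set form" else "graph form",
      ", ", length(x$leaves), " leaves\n", sep = "")
  invisible(x)
}

check_query <- function(C, D, need_graph = FALSE) {
  C <- cluster_query(C)
  stopifnot(inherits(D, "dendro"))
  if (need_graph && is.null(C$graph)) {
    stop("cluster '", C$id, "' has no graph form; graph contrasts need a Newick subtree")
  }
  if (!all(C$leaves %in% D$leaves)) {
    stop("cluster leaves {", paste(setdiff(C$leaves, D$leaves), collapse = ","),
         "} are not leaves of the dendrogram")
  }
  C
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Graph-cluster contrast
#'
#' Strict presence of C as a graph: 1 iff C (with its internal hierarchy) is
#' a branch of D or the whole dendrogram, i.e. iff C's canonical key occurs
#' among the canonical keys of D's nontrivial subtrees; otherwise 0.  (A
#' rooted binary leaf-labeled tree is determined by its subtree partition, so
#' key equality decides partition equality.)
#'
#' @param C a cluster query in graph form (see [cluster_query()]).
#' @param D a `"dendro"` object whose leaves include C's.
#' @return 0 or 1.
#' @export
cc_graph <- function(C, D) {
  C <- check_query(C, D, need_graph = TRUE)
  as.numeric(C$graph$key %in% subtree_partition(D))
}

#' Relaxed-graph-cluster contrast
#'
#' Quantified presence of C as a graph: the maximum, over D's nontrivial
#' subtrees g, of the Jaccard index between the subtree partitions P(C) and
#' P(g) (sets of canonical keys; single leaves never enter a partition).
#' Equals 1 iff [cc_graph()] does, and is positive iff C and D share a
#' two-leaf subtree (a cherry).
#'
#' @inheritParams cc_graph
#' @return a value in [0, 1].
#' @export
cc_relaxed_graph <- function(C, D) {
  C <- check_query(C, D, need_graph = TRUE)
  PC <- subtree_partition(C$graph)
  max(vapply(tree_tables(D)$fams, jaccard, 0, a = PC))
}

#' Set-cluster contrast
#'
#' Strict presence of C as a set: 1 iff C's leaf set equals the leaf set of
#' some nontrivial subtree of D, otherwise 0.  The hierarchy inside C is
#' ignored.
#'
#' @param C a cluster query (graph or set form).
#' @param D a `"dendro"` object whose leaves include C's.
#' @return 0 or 1.
#' @export
cc_set <- function(C, D) {
  C <- check_query(C, D)
  sets <- leafset_family(D)
  as.numeric(any(vapply(sets, identical, NA, y = C$leaves)))
}

#' Relaxed-set-cluster contrast
#'
#' Quantified presence of C as a set: the maximum Jaccard index between C's
#' leaf set and the leaf sets of D's nontrivial subtrees.  Equals 1 iff
#' [cc_set()] does.
#'
#' @inheritParams cc_set
#' @return a value in [0, 1].
#' @export
cc_relaxed_set <- function(C, D) {
  C <- check_query(C, D)
  max(vapply(leafset_family(D), jaccard, 0, a = C$leaves))
}

contrast_fun <- function(method) {
  switch(method,
    g = cc_graph,
    rg = cc_relaxed_graph,
    s = cc_set,
    rs = cc_relaxed_set,
    stop("unknown contrast method '", method, "' (use g, rg, s or rs)")
  )
}

as_tree_list <- function(trees) {
  if (inherits(trees, "tie_hclust")) return(trees$trees)
  if (inherits(trees, "dendro")) return(list(trees))
  stopifnot(is.list(trees), length(trees) >= 1L)
  lapply(trees, function(t) {
    if (!inherits(t, "dendro")) stop("trees must be 'dendro' objects")
    t
  })
}

#' Cluster frequency over a set of dendrograms
#'
#' The frequency of a cluster C is the arithmetic mean of a chosen contrast
#' over a set of dendrograms sharing one leaf set -- the empirical
#' probability of C in that set.  The set is typically the tie enumeration
#' from [tie_hclust()], but any dendrogram collection with a common leaf set
#' is accepted (e.g. trees from perturbed data or varied linkages, for
#' cluster-stability analysis).
#'
#' @param trees a `"tie_hclust"` fit or a nonempty list of `"dendro"`
#'   objects sharing one leaf set.
#' @param cluster a cluster query (see [cluster_query()]).
#' @param method contrast: `"g"` (graph), `"rg"` (relaxed graph), `"s"`
#'   (set) or `"rs"` (relaxed set).
#' @return a value in [0, 1]; for methods `g` and `s` an integer multiple of
#'   1/m, m the number of trees.
#' @examples
#' fit <- tie_hclust(toy_table1())
#' cluster_frequency(fit, "(g,i);", "g")  # 0.5
#' @export
cluster_frequency <- function(trees, cluster, method = c("g", "rg", "s", "rs")) {
  method <- match.arg(method)
  trees <- as_tree_list(trees)
  lv <- trees[[1L]]$leaves
  for (t in trees) {
    if (!identical(t$leaves, lv)) stop("all dendrograms must share one leaf set")
  }
  C <- cluster_query(cluster)
  f <- contrast_fun(method)
  mean(vapply(trees, function(D) f(C, D), 0))
}

#' @importFrom stats frequency
#' @export
frequency.tie_hclust <- function(x, cluster, method = c("g", "rg", "s", "rs"), ...) {
  cluster_frequency(x, cluster, method)
}

#' Analytic cluster frequency in the maximal-tie (equidistant) case
#'
#' On an equidistant metric space every topology on the n items is reachable,
#' so a cluster with k leaves occurs, under the graph contrast, in exactly
#' F(n - k + 1) of the F(n) dendrograms (collapse the cluster to a single
#' leaf and count the trees on the reduced set).  The ratio is computed with
#' the shared double-factorial prefix cancelled, so it is exact: 1 over the
#' product of the odd numbers from 2(n-k+1) - 1 to 2n - 3.
#'
#' @param n number of items (>= 2).
#' @param cluster_size number of leaves of the cluster, in [2, n].
#' @return the frequency F(n - cluster_size + 1) / F(n), in (0, 1].
#' @examples
#' tiecase_graph_frequency(3, 2)  # 1/3
#' tiecase_graph_frequency(4, 2)  # 1/5
#' @export
tiecase_graph_frequency <- function(n, cluster_size) {
  if (length(n) != 1L || n < 2 || n != floor(n)) stop("n must be an integer >= 2")
  if (length(cluster_size) != 1L || cluster_size < 2 || cluster_size > n ||
      cluster_size != floor(cluster_size)) {
    stop("cluster_size must be an integer in [2, n]")
  }
  k <- n - cluster_size + 1
  # F(k)/F(n) = 1 / ((2k-1)(2k+1)...(2n-3)); empty product when k = n
  if (k == n) return(1)
  1 / prod(seq(2 * k - 1, 2 * n - 3, by = 2))
}

#' Frequency report for several clusters and methods
#'
#' One row per cluster and contrast method, in the long layout the
#' command-line tool writes as TSV.
#'
#' @param clusters a list (or character vector) of cluster queries.
#' @param trees a `"tie_hclust"` fit or list of `"dendro"` objects sharing
#'   one leaf set.
#' @param methods subset of `c("g", "rg", "s", "rs")`; graph methods are
#'   skipped with an error if a query lacks graph form.
#' @param decimals digits for the display column `frequency`; the
#'   `frequency_full` column always carries full precision.
#' @return a data frame with columns `cluster_id`, `method`, `frequency`,
#'   `frequency_full`, `m`, `capped`.
#' @export
frequency_report <- function(clusters, trees, methods = c("g", "rg", "s", "rs"),
                             decimals = 2L) {
  stopifnot(decimals >= 0)
  methods <- match.arg(methods, c("g", "rg", "s", "rs"), several.ok = TRUE)
  capped <- if (inherits(trees, "tie_hclust")) trees$capped else FALSE
  tl <- as_tree_list(trees)
  if (is.character(clusters)) clusters <- as.list(clusters)
  qs <- lapply(clusters, cluster_query)
  rows <- list()
  for (q in qs) {
    for (meth in methods) {
      f <- cluster_frequency(tl, q, meth)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = q$id, method = meth,
        frequency = round(f, decimals), frequency_full = f,
        m = length(tl), capped = capped,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
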