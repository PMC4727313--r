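# Tie-aware agglomerative clustering: enumerate every distinct dendrogram
# reachable by breaking ties in proximity in all possible ways.

LINKAGES <- c("group_average", "simple_average", "single", "complete")

# Coerce a dist object or a labeled symmetric matrix to a square matrix with
# unique labels, zero diagonal, non-negative entries.
as_dist_matrix <- function(x) {
  if (inherits(x, "dist")) {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- colnames(m) <- as.character(seq_len(nrow(m)))
  } else if (is.matrix(x) && is.numeric(x)) {
    m <- x
    if (is.null(rownames(m)) && !is.null(colnames(m))) rownames(m) <- colnames(m)
    if (is.null(rownames(m))) rownames(m) <- colnames(m) <- as.character(seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- rownames(m)
  } else {
    stop("expected a 'dist' object or a numeric matrix")
  }
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 items")
  if (ncol(m) != n) stop("distance matrix must be square")
  if (anyDuplicated(rownames(m))) stop("duplicate item labels")
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(m) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(m < 0)) stop("dissimilarities must be non-negative")
  m
}

#' Euclidean distance matrix from a feature table
#'
#' @param features a numeric matrix or data frame, rows = items (rownames are
#'   the item labels), columns = numeric attributes; no missing values.
#' @return a labeled symmetric matrix of pairwise Euclidean distances.
#' @examples
#' euclidean_matrix(toy_table1())["a", "b"] # 1
#' @export
euclidean_matrix <- function(features) {
  m <- as.matrix(features)
  if (!is.numeric(m)) stop("features must be numeric")
  if (anyNA(m)) stop("features must not contain missing values")
  if (nrow(m) < 2L) stop("need at least 2 items")
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate item labels")
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Number of rooted binary leaf-labeled tree topologies
#'
#' The Felsenstein count F(n) = (2n-3)!/(2^(n-2) (n-2)!) = (2n-3)!!, i.e. the
#' number of distinct dendrograms on n labeled leaves; F(1) = F(2) = 1.
#' Computed by the double-factorial product in exact double-precision integer
#' arithmetic, which is exact for n <= 16 (F(16) < 2^53).
#'
#' @param n number of leaves, an integer >= 1.
#' @return the count as a numeric (exact integer for n <= 16).
#' @examples
#' felsenstein_count(4)  # 15
#' felsenstein_count(9)  # 2027025
#' @export
felsenstein_count <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop("n must be a single integer >= 1")
  }
  if (n > 16) warning("F(n) exceeds 2^53 for n > 16; the result is approximate")
  if (n <= 2) return(1)
  prod(seq(3, 2 * n - 3, by = 2))
}

# Insert a new leaf above every node of `node` (including a new root),
# returning one tree per insertion point; a tree with j leaves has 2j - 1
# nodes, matching F(j + 1) / F(j) = 2j - 1.
insert_leaf <- function(node, lf) {
  out <- list(list(kids = list(node, list(leaf = lf)), height = NA_real_))
  if (!node_is_leaf(node)) {
    for (i in 1:2) {
      for (sub in insert_leaf(node$kids[[i]], lf)) {
        nn <- node
        nn$kids[[i]] <- sub
        out <- c(out, list(nn))
      }
    }
  }
  out
}

#' Enumerate all rooted binary topologies on a leaf set
#'
#' Brute-force construction by recursive leaf insertion; produces every
#' rooted, strictly binary, leaf-labeled topology exactly once.  Serves as
#' the independent oracle for the tie-aware enumeration on equidistant data.
#'
#' @param leaves character vector of unique leaf labels (2 to `bound` of them).
#' @param bound refuse larger sets (F(n) grows as (2n-3)!!; the default keeps
#'   the output at desk scale, F(8) = 135135).
#' @return a list of `"dendro"` objects of length `felsenstein_count(length(leaves))`.
#' @export
enumerate_all_topologies <- function(leaves, bound = 8L) {
  leaves <- as.character(leaves)
  if (anyDuplicated(leaves)) stop("leaf labels must be unique")
  n <- length(leaves)
  if (n < 2L) stop("need at least 2 leaves")
  if (n > bound) stop("refusing to enumerate ", n, " leaves (bound = ", bound, ")")
  trees <- list(list(kids = list(list(leaf = leaves[1L]), list(leaf = leaves[2L])),
                     height = NA_real_))
  for (k in seq_len(n - 2L) + 2L) {
    trees <- unlist(lapply(trees, insert_leaf, lf = leaves[k]), recursive = FALSE)
  }
  lapply(trees, new_dendro)
}

# Inter-cluster dissimilarity by linkage, from the original leaf-level matrix.
# Each active cluster carries its leaf indices and per-leaf weights; for the
# average linkages the cluster-level Lance-Williams recursion collapses to a
# weighted average of original distances (uniform weights for group average /
# UPGMA, 2^-depth weights for simple average / WPGMA), which makes the
# distance a function of the cluster trees alone, independent of merge order.
cluster_dist <- function(ci, cj, D, linkage) {
  block <- D[ci$idx, cj$idx, drop = FALSE]
  switch(linkage,
    single = min(block),
    complete = max(block),
    group_average = mean(block),
    simple_average = as.numeric(ci$w %*% block %*% cj$w)
  )
}

merge_clusters <- function(ci, cj, h, linkage) {
  a <- ci$node; b <- cj$node
  node <- list(kids = list(a, b), height = h)
  key <- if (ci$min <= cj$min) {
    paste0("(", ci$key, ",", cj$key, ")")
  } else {
    paste0("(", cj$key, ",", ci$key, ")")
  }
  w <- if (linkage == "simple_average") {
    c(ci$w, cj$w) / 2
  } else {
    rep(1 / (length(ci$idx) + length(cj$idx)), length(ci$idx) + length(cj$idx))
  }
  list(node = node, idx = c(ci$idx, cj$idx), w = w,
       key = key, min = min(ci$min, cj$min))
}

#' Tie-aware hierarchical clustering
#'
#' Agglomerative clustering that, instead of breaking ties in proximity
#' arbitrarily, branches on every tied minimum and collects all distinct
#' dendrograms the tie resolutions can produce.  At each agglomeration step
#' the minimum inter-cluster dissimilarity d* is found and one branch is
#' opened for every cluster pair whose dissimilarity lies within tolerance of
#' d*; after each merge, distances are updated by the Lance-Williams rule of
#' the chosen linkage and the search recurses.  Completed trees are
#' deduplicated by canonical topology, so each distinct dendrogram counts
#' once.  A memo on the canonical state of the active cluster set prunes
#' paths that merge disjoint tied pairs in different orders.
#'
#' With no ties (all current minima strict at every step) the result is the
#' single ordinary agglomerative dendrogram, m = 1.  On an equidistant matrix
#' every topology is reachable and m = F(n) (see [felsenstein_count()]).
#'
#' @param x a feature table (numeric matrix or data frame with row labels;
#'   Euclidean distances are computed), a `dist` object, or a labeled
#'   symmetric distance matrix with zero diagonal.
#' @param method linkage: `"group_average"` (UPGMA, the default),
#'   `"simple_average"` (WPGMA), `"single"` or `"complete"`.
#' @param abs_tol,rel_tol a pair with dissimilarity d is tied with the step
#'   minimum d* when d <= d* + max(abs_tol, rel_tol * d*).  The defaults
#'   (0, 1e-9) treat exact equalities -- up to floating-point rounding in the
#'   distance updates -- as ties.
#' @param cap stop collecting after this many distinct dendrograms; the
#'   result is then flagged `capped` (the set is partial, not silently
#'   truncated).  Tie explosions are combinatorial, so a cap is essential on
#'   real data.
#' @return an object of class `"tie_hclust"`: a list with elements
#'   \describe{
#'     \item{trees}{list of `"dendro"` objects, the distinct dendrograms;}
#'     \item{m}{their number;}
#'     \item{capped}{TRUE if the cap was hit;}
#'     \item{tie_log}{data frame (step, min_distance, n_tied_pairs), one row
#'       per distinct merge state visited;}
#'     \item{method, labels, n, dist, call}{bookkeeping.}
#'   }
#' @examples
#' fit <- tie_hclust(toy_table1())
#' fit$m  # 6
#' @export
tie_hclust <- function(x, method = c("group_average", "simple_average",
                                     "single", "complete"),
                       abs_tol = 0, rel_tol = 1e-9, cap = 200000L) {
  method <- match.arg(method)
  stopifnot(abs_tol >= 0, rel_tol >= 0, cap >= 1)
  D <- if (inherits(x, "dist") ||
           (is.matrix(x) && nrow(x) == ncol(x) &&
            isTRUE(all.equal(unname(x), unname(t(x)))) && all(diag(x) == 0))) {
    as_dist_matrix(x)
  } else {
    euclidean_matrix(x)
  }
  n <- nrow(D)
  labels <- rownames(D)

  env <- new.env(parent = emptyenv())
  env$memo <- new.env(parent = emptyenv())
  env$capped <- FALSE
  env$log_step <- integer(0)
  env$log_dmin <- numeric(0)
  env$log_ntied <- integer(0)

  clusters0 <- lapply(seq_len(n), function(i) {
    list(node = list(leaf = labels[i]), idx = i, w = 1,
         key = labels[i], min = labels[i])
  })

  enum_state <- function(clusters) {
    if (length(clusters) == 1L) {
      cl <- clusters[[1L]]
      return(list(list(node = cl$node, key = cl$key)))
    }
    skey <- paste(sort(vapply(clusters, `[[`, "", "key")), collapse = "|")
    hit <- env$memo[[skey]]
    if (!is.null(hit)) return(hit)

    k <- length(clusters)
    pd <- matrix(Inf, k, k)
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        pd[i, j] <- cluster_dist(clusters[[i]], clusters[[j]], D, method)
      }
    }
    dmin <- min(pd)
    thr <- dmin + max(abs_tol, rel_tol * dmin)
    tied <- which(pd <= thr, arr.ind = TRUE)

    env$log_step <- c(env$log_step, n - k + 1L)
    env$log_dmin <- c(env$log_dmin, dmin)
    env$log_ntied <- c(env$log_ntied, nrow(tied))

    res <- list()
    seen <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(tied))) {
      i <- tied[r, 1L]; j <- tied[r, 2L]
      merged <- merge_clusters(clusters[[i]], clusters[[j]], pd[i, j], method)
      rest <- c(clusters[-c(i, j)], list(merged))
      for (tr in enum_state(rest)) {
        if (is.null(seen[[tr$key]])) {
          seen[[tr$key]] <- TRUE
          res[[length(res) + 1L]] <- tr
        }
      }
      if (length(res) > cap) {
        env$capped <- TRUE
        res <- res[seq_len(cap)]
        break
      }
    }
    env$memo[[skey]] <- res
    res
  }

  out <- enum_state(clusters0)
  trees <- lapply(out, function(tr) new_dendro(tr$node))
  structure(
    list(
      trees = trees,
      m = length(trees),
      capped = env$capped,
      tie_log = data.frame(
        step = env$log_step,
        min_distance = env$log_dmin,
        n_tied_pairs = env$log_ntied
      ),
      method = method,
      labels = labels,
      n = n,
      dist = D,
      call = match.call()
    ),
    class = "tie_hclust"
  )
}

#' Collapse zero-distance equivalence classes
#'
#' Items at distance zero from one another (e.g. descriptors with identical
#' values on every molecule) are grouped into equivalence classes and each
#' class is replaced by its first member.  This is a deliberate preprocessing
#' step, not an automatic merge inside the clustering: the reduction is kept
#' explicit and inspectable.
#'
#' @param x a `dist` object or labeled symmetric distance matrix.
#' @return a list with `dist` (the reduced matrix), `classes` (a list of
#'   character vectors, one per equivalence class, representative first) and
#'   `kept` (the representative labels).
#' @export
dedupe_zero_distance <- function(x) {
  D <- as_dist_matrix(x)
  n <- nrow(D)
  labels <- rownames(D)
  # union-find over the zero-distance graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  zero <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  for (r in seq_len(nrow(zero))) {
    a <- find(zero[r, 1L]); b <- find(zero[r, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, 0L)
  classes <- split(labels, roots)
  reps <- vapply(classes, `[[`, "", 1L)
  keep <- match(reps, labels)
  list(dist = D[keep, keep, drop = FALSE],
       classes = unname(classes),
       kept = unname(reps))
}

#' @export
print.tie_hclust <- function(x, ...) {
  cat("Tie-aware hierarchical clustering (", x$method, " linkage)\n", sep = "")
  cat("  items:", x$n, "\n")
  cat("  distinct dendrograms: ", x$m,
      if (x$capped) "  [CAPPED: the set is partial]" else "", "\n", sep = "")
  nt <- x$tie_log$n_tied_pairs
  cat("  merge states visited: ", nrow(x$tie_log),
      "; states with ties: ", sum(nt > 1L), "\n", sep = "")
  invisible(x)
}

#' @export
summary.tie_hclust <- function(object, ...) {
  structure(
    list(
      method = object$method, n = object$n, m = object$m,
      capped = object$capped,
      f_n = if (object$n <= 16) felsenstein_count(object$n) else NA_real_,
      tie_log = object$tie_log
    ),
    class = "summary.tie_hclust"
  )
}

#' @export
print.summary.tie_hclust <- function(x, ...) {
  cat("Tie-aware hierarchical clustering (", x$method, " linkage)\n", sep = "")
  cat("  items (n):              ", x$n, "\n")
  cat("  distinct dendrograms m: ", x$m,
      if (x$capped) "  [capped]" else "", "\n", sep = "")
  if (!is.na(x$f_n)) cat("  possible topologies F(n):", format(x$f_n, big.mark = ","), "\n")
  tl <- x$tie_log
  if (nrow(tl)) {
    cat("  tie log: ", nrow(tl), " merge states, ",
        sum(tl$n_tied_pairs > 1L), " with >1 tied pair (max ",
        max(tl$n_tied_pairs), ")\n", sep = "")
  }
  invisible(x)
}

#' Plot some of the enumerated dendrograms
#'
#' @param x a `"tie_hclust"` object.
#' @param k how many dendrograms to draw (first `k`).
#' @param ... passed to `ape::plot.phylo`.
#' @export
plot.tie_hclust <- function(x, k = min(6L, x$m), ...) {
  k <- min(k, x$m)
  op <- graphics::par(mfrow = grDevices::n2mfrow(k))
  on.exit(graphics::par(op))
  for (i in seq_len(k)) plot(x$trees[[i]], main = paste0("D", i), ...)
  invisible(x)
}
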