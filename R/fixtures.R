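# Deterministic generators for test and demonstration inputs.  All are pure
# functions of their arguments (seeded generators restore the caller's RNG
# state), so every experiment is replayable.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' The nine-point toy feature table
#'
#' Nine items a..i in the plane, forming three well-separated groups
#' A = \{a,b,c\}, B = \{g,h,i\}, C = \{d,e,f\} with planted ties: in B the
#' pairs (g,i) and (h,i) are equidistant; C is an equilateral triangle (the
#' coordinate 6 + sqrt(12) makes d, e, f pairwise at distance 4).  Under
#' Euclidean distance and average linkage the tie resolutions yield six
#' distinct dendrograms.
#'
#' @return a 9 x 2 data frame with columns `P1`, `P2` and row names a..i.
#' @examples
#' fit <- tie_hclust(toy_table1())
#' fit$m  # 6
#' @export
toy_table1 <- function() {
  data.frame(
    P1 = c(1, 2, 1.5, 10, 14, 12, 0, 2, 1),
    P2 = c(1, 1, 2, 6, 6, 6 + sqrt(12), 9, 11, 10),
    row.names = letters[1:9]
  )
}

#' Equidistant metric space (maximal-tie case)
#'
#' All off-diagonal dissimilarities equal c > 0; this satisfies the metric
#' axioms and is the extreme tie case, in which every rooted binary topology
#' on the n items is reachable by some tie resolution.
#'
#' @param n number of items (>= 2); labels are x1..xn.
#' @param c the common positive distance.
#' @return a labeled symmetric matrix.
#' @export
equidistant_space <- function(n, c = 1) {
  stopifnot(n >= 2, n == floor(n))
  if (c <= 0) stop("c must be positive")
  m <- matrix(c, n, n)
  diag(m) <- 0
  labels <- paste0("x", seq_len(n))
  dimnames(m) <- list(labels, labels)
  m
}

#' Random distance matrix with controlled tie density
#'
#' Off-diagonal dissimilarities are drawn uniformly from `n_levels` discrete
#' positive values; few levels mean many coincidences, mimicking discrete or
#' low-precision data where ties in proximity abound.  `n_levels = 1` is the
#' equidistant space.
#'
#' @param n number of items (>= 2).
#' @param n_levels number of distinct distance values (>= 1).
#' @param seed integer seed; the same arguments always give the same matrix,
#'   and the caller's RNG state is left untouched.
#' @return a labeled symmetric matrix.
#' @export
random_tied_matrix <- function(n, n_levels, seed) {
  stopifnot(n >= 2, n == floor(n), n_levels >= 1, n_levels == floor(n_levels))
  vals <- with_seed(seed, sample(seq_len(n_levels), n * (n - 1) / 2, replace = TRUE))
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  labels <- paste0("x", seq_len(n))
  dimnames(m) <- list(labels, labels)
  m
}

# Exact-tie point stars: up to 9 points per cluster at integer coordinates
# around a center, so equal distances are computed from identical floating
# point expressions and ties survive arithmetic exactly.
star_offsets <- matrix(c(
  0, 0,
  1, 0,   0, 1,  -1, 0,   0, -1,
  2, 0,   0, 2,  -2, 0,   0, -2
), ncol = 2, byrow = TRUE)

#' Well-separated clusters with planted within-cluster ties
#'
#' Generates k point clusters far apart in the plane, with exact ties only
#' inside clusters: each cluster is a star of points at integer offsets
#' around its center (so e.g. the center is at distance exactly 1 from
#' several points).  Cluster centers are placed at geometrically spaced
#' positions, making every between-cluster merge strictly resolved; the
#' enumerated dendrograms therefore differ only in within-cluster structure,
#' and the total count m factorizes as the product of the per-cluster
#' counts.
#'
#' @param k_clusters number of clusters.
#' @param sizes integer vector of cluster sizes (each in 1..9), recycled to
#'   `k_clusters`.
#' @param separation distance scale between cluster centers; must dwarf the
#'   within-cluster radius (<= 2).
#' @param seed kept for interface uniformity; the construction is
#'   deterministic and ignores it.
#' @return a feature data frame with row labels `c<k>_<i>` and columns
#'   `P1`, `P2`.
#' @export
separated_clusters_with_ties <- function(k_clusters, sizes, separation = 100,
                                         seed = 1L) {
  stopifnot(k_clusters >= 1, separation > 10)
  sizes <- rep_len(as.integer(sizes), k_clusters)
  if (any(sizes < 1L | sizes > 9L)) stop("cluster sizes must be in 1..9")
  rows <- list()
  for (k in seq_len(k_clusters)) {
    cx <- separation * 3^(k - 1)  # pairwise center distances all distinct
    off <- star_offsets[seq_len(sizes[k]), , drop = FALSE]
    rows[[k]] <- data.frame(
      P1 = cx + off[, 1], P2 = off[, 2],
      row.names = paste0("c", k, "_", seq_len(sizes[k]))
    )
  }
  do.call(rbind, rows)
}
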