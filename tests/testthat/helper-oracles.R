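# Independent oracles, deliberately written against the plain list structure
# of trees rather than through the package's canonical-key machinery.

# Brute-force enumeration of rooted binary leaf-labeled trees by recursive
# bipartition (the first leaf pins down one side of the root split, so each
# unordered split is produced once).  Independent of the package's
# leaf-insertion enumerator.
split_trees <- function(leaves) {
  if (length(leaves) == 1L) return(list(list(leaf = leaves)))
  rest <- leaves[-1L]
  out <- list()
  for (mask in 0:(2^length(rest) - 1L)) {
    inA <- as.logical(bitwAnd(mask, 2^(seq_along(rest) - 1L)))
    A <- c(leaves[1L], rest[inA])
    B <- rest[!inA]
    if (!length(B)) next
    for (ta in split_trees(A)) {
      for (tb in split_trees(B)) {
        out[[length(out) + 1L]] <- list(kids = list(ta, tb), height = NA_real_)
      }
    }
  }
  out
}

# Brute-force rooted-tree isomorphism on node lists (tries both child
# pairings at every level).
trees_iso <- function(a, b) {
  la <- is.null(a$kids); lb <- is.null(b$kids)
  if (la || lb) return(la && lb && identical(a$leaf, b$leaf))
  (trees_iso(a$kids[[1L]], b$kids[[1L]]) && trees_iso(a$kids[[2L]], b$kids[[2L]])) ||
    (trees_iso(a$kids[[1L]], b$kids[[2L]]) && trees_iso(a$kids[[2L]], b$kids[[1L]]))
}

# Scan a dendro for its cherries (two-leaf subtrees) without going through
# the subtree-partition code.
cherries_of <- function(d) {
  out <- list()
  walk <- function(node) {
    if (is.null(node$kids)) return(invisible())
    k1 <- node$kids[[1L]]; k2 <- node$kids[[2L]]
    if (is.null(k1$kids) && is.null(k2$kids)) {
      out[[length(out) + 1L]] <<- sort(c(k1$leaf, k2$leaf))
    }
    walk(k1); walk(k2)
  }
  walk(d$root)
  out
}

# Newick text straight off a node list (arbitrary child order).
node_newick <- function(node) {
  if (is.null(node$kids)) return(node$leaf)
  paste0("(", node_newick(node$kids[[1L]]), ",", node_newick(node$kids[[2L]]), ")")
}

as_dendro <- function(node) parse_newick(paste0(node_newick(node), ";"))

# Random dendro on the given leaves, by uniformly merging random pairs.
random_dendro <- function(leaves) {
  nodes <- lapply(leaves, function(l) list(leaf = l))
  while (length(nodes) > 1L) {
    ij <- sample(length(nodes), 2L)
    merged <- list(kids = nodes[ij], height = NA_real_)
    nodes <- c(nodes[-ij], list(merged))
  }
  as_dendro(nodes[[1L]])
}

# Merge heights along every root-to-leaf path, for monotonicity checks.
heights_monotone <- function(d) {
  ok <- TRUE
  walk <- function(node) {
    if (is.null(node$kids)) return(0)
    h1 <- walk(node$kids[[1L]]); h2 <- walk(node$kids[[2L]])
    if (node$height < max(h1, h2) - 1e-9) ok <<- FALSE
    node$height
  }
  walk(d$root)
  ok
}

key_set <- function(trees) sort(vapply(trees, canonical_key, ""))
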