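# Internal tree representation: a node is either
#   list(leaf = "<label>")                              -- a tip, or
#   list(kids = list(<node>, <node>), height = <num>)   -- a strictly binary
# internal node; `height` is the dissimilarity at which its two children were
# merged (NA when the tree did not come from an agglomeration).

node_is_leaf <- function(node) !is.null(node$leaf)

node_leaves <- function(node) {
  if (node_is_leaf(node)) return(node$leaf)
  c(node_leaves(node$kids[[1L]]), node_leaves(node$kids[[2L]]))
}

# Canonical form: children are ordered by the lexicographically smallest leaf
# label in their subtree (the two subtrees of a node have disjoint leaf sets,
# so this is a strict order).  The canonical key of a node is its Newick-like
# string in that order, which two rooted, unordered, leaf-labeled trees share
# iff they are isomorphic.
node_canon <- function(node) {
  if (node_is_leaf(node)) return(list(key = node$leaf, min = node$leaf))
  a <- node_canon(node$kids[[1L]])
  b <- node_canon(node$kids[[2L]])
  if (a$min <= b$min) {
    list(key = paste0("(", a$key, ",", b$key, ")"), min = a$min)
  } else {
    list(key = paste0("(", b$key, ",", a$key, ")"), min = b$min)
  }
}

new_dendro <- function(root) {
  lv <- node_leaves(root)
  if (anyDuplicated(lv)) {
    stop("duplicate leaf labels: ", paste(unique(lv[duplicated(lv)]), collapse = ", "))
  }
  if (length(lv) < 2L) stop("a dendrogram needs at least 2 leaves")
  structure(
    list(root = root, leaves = sort(lv), key = node_canon(root)$key),
    class = "dendro"
  )
}

#' Parse a Newick string into a dendrogram
#'
#' Reads a single rooted, strictly binary, leaf-labeled tree.  Branch lengths
#' and internal node labels are accepted on input and ignored: the cluster
#' contrasts depend only on topology and leaf membership.  Multifurcating
#' nodes are rejected, not collapsed, because the dendrogram model is strictly
#' binary.
#'
#' @param text a Newick string, terminated by `;`.
#' @return an object of class `"dendro"`.
#' @examples
#' d <- parse_newick("((c,d),a);")
#' leafset_family(d)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr)) stop("malformed Newick string: ", text)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, got ", length(tr))
    tr <- tr[[1L]]
  }
  n <- length(tr$tip.label)
  if (n < 2L) stop("a dendrogram needs at least 2 leaves")
  kids <- split(tr$edge[, 2L], factor(tr$edge[, 1L], levels = seq_len(n + tr$Nnode)))
  build <- function(v) {
    if (v <= n) return(list(leaf = tr$tip.label[v]))
    ch <- kids[[v]]
    if (length(ch) != 2L) {
      stop("non-binary node with ", length(ch),
           " children: multifurcations are not supported")
    }
    list(kids = list(build(ch[1L]), build(ch[2L])), height = NA_real_)
  }
  new_dendro(build(n + 1L))
}

#' Serialize a dendrogram to Newick
#'
#' Children are emitted in canonical order (subtree with the smallest leaf
#' label first), so the output is a deterministic function of the topology.
#' With `with_heights = TRUE`, branch lengths are derived from per-node merge
#' heights (leaves sit at height 0); this requires the tree to carry heights,
#' as trees produced by [tie_hclust()] do.
#'
#' @param x a `"dendro"` object.
#' @param with_heights write branch lengths derived from merge heights.
#' @return a Newick string ending in `;`.
#' @export
write_newick <- function(x, with_heights = FALSE) {
  stopifnot(inherits(x, "dendro"))
  if (!with_heights) return(paste0(x$key, ";"))
  # the linkages in use are monotone; clamp the sub-epsilon negatives that
  # floating-point tie arithmetic can leave on a branch
  fmt <- function(v) sprintf("%.12g", max(v, 0))
  emit <- function(node, parent_h) {
    if (node_is_leaf(node)) {
      return(list(s = paste0(node$leaf, ":", fmt(parent_h)), min = node$leaf))
    }
    h <- node$height
    if (is.na(h)) stop("tree carries no merge heights; use with_heights = FALSE")
    a <- emit(node$kids[[1L]], h)
    b <- emit(node$kids[[2L]], h)
    inner <- if (a$min <= b$min) paste0(a$s, ",", b$s) else paste0(b$s, ",", a$s)
    s <- paste0("(", inner, ")")
    if (!is.na(parent_h)) s <- paste0(s, ":", fmt(parent_h - h))
    list(s = s, min = min(a$min, b$min))
  }
  paste0(emit(x$root, NA_real_)$s, ";")
}

#' Canonical key of a dendrogram
#'
#' An opaque string; two dendrograms (or subtrees) have equal keys iff they
#' are isomorphic as rooted, unordered, leaf-labeled trees.  The key of a
#' leaf is its label; the key of an internal node combines its children's
#' keys in canonical order.
#'
#' @param x a `"dendro"` object.
#' @return a character scalar.
#' @export
canonical_key <- function(x) {
  stopifnot(inherits(x, "dendro"))
  x$key
}

# Post-order sweep computing, per internal node, its canonical key, the set of
# canonical keys of all its nontrivial subtrees (itself included), and its
# sorted leaf set.  The lists are in post-order; the last entry is the root.
tree_tables <- function(x) {
  keys <- character(0)      # one per internal node
  fams <- list()            # P(g) per internal node: its internal keys
  sets <- list()            # L(g) per internal node, sorted
  walk <- function(node) {
    if (node_is_leaf(node)) {
      return(list(key = node$leaf, min = node$leaf, all = character(0),
                  leaves = node$leaf))
    }
    a <- walk(node$kids[[1L]])
    b <- walk(node$kids[[2L]])
    key <- if (a$min <= b$min) {
      paste0("(", a$key, ",", b$key, ")")
    } else {
      paste0("(", b$key, ",", a$key, ")")
    }
    all <- c(a$all, b$all, key)
    lv <- c(a$leaves, b$leaves)
    keys[[length(keys) + 1L]] <<- key
    fams[[length(fams) + 1L]] <<- all
    sets[[length(sets) + 1L]] <<- sort(lv)
    list(key = key, min = min(a$min, b$min), all = all, leaves = lv)
  }
  walk(x$root)
  list(keys = keys, fams = fams, sets = sets)
}

#' Nontrivial subtree partition of a dendrogram
#'
#' Every internal node (the root included) defines a nontrivial subtree, i.e.
#' one with at least two leaves; singletons are excluded.  For a tree on n
#' leaves there are exactly n - 1 of them.  Subtrees are returned as their
#' canonical keys, which is how subtree identity is decided throughout.
#'
#' @param x a `"dendro"` object.
#' @return a character vector of n - 1 canonical keys.
#' @export
subtree_partition <- function(x) {
  stopifnot(inherits(x, "dendro"))
  tree_tables(x)$keys
}

#' Leaf-set family of a dendrogram
#'
#' The image of the subtree partition under L(.): for each nontrivial subtree,
#' its set of leaf labels.  For a binary tree distinct internal nodes have
#' distinct leaf sets, so the family has n - 1 members, the full leaf set
#' (root) among them.
#'
#' @param x a `"dendro"` object.
#' @return a list of n - 1 sorted character vectors.
#' @export
leafset_family <- function(x) {
  stopifnot(inherits(x, "dendro"))
  tree_tables(x)$sets
}

#' @export
print.dendro <- function(x, ...) {
  cat("Dendrogram on", length(x$leaves), "leaves:", write_newick(x), "\n")
  invisible(x)
}

#' @importFrom ape as.phylo
#' @export
as.phylo.dendro <- function(x, ...) {
  has_h <- !is.na(x$root$height %||% NA_real_)
  ape::read.tree(text = write_newick(x, with_heights = has_h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.dendro <- function(x, ...) {
  plot(as.phylo.dendro(x), ...)
}
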