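# Plain-text readers and writers for the formats the command-line tool
# speaks: labeled distance matrices and feature tables (CSV/TSV), multi-tree
# Newick files (one dendrogram per line) and cluster-query files.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a labeled distance matrix from CSV/TSV
#'
#' Two layouts are accepted: a full square matrix whose first row and first
#' column hold the item labels (the top-left corner cell may be empty or
#' arbitrary), or a lower-triangular layout without a header where each line
#' holds a label followed by the distances to the previously listed items
#' (the first line is a bare label).
#'
#' @param path file path.
#' @param sep field separator; by default inferred from the first line
#'   (tab if present, else comma).
#' @return a labeled symmetric matrix with zero diagonal.
#' @export
read_distance_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- detect_sep(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(fields)
  n_first <- lens[1L]
  square <- length(lines) >= 2L && all(lens == n_first)
  if (square) {
    labels <- trimws(fields[[1L]][-1L])
    n <- length(labels)
    if (length(lines) != n + 1L) stop("square matrix file must have n+1 rows")
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n)) {
      row <- fields[[i + 1L]]
      if (trimws(row[1L]) != labels[i]) {
        stop("row label '", trimws(row[1L]), "' does not match column label '",
             labels[i], "'")
      }
      m[i, ] <- as.numeric(row[-1L])
    }
  } else {
    # lower triangular: line i has label_i then i-1 distances
    if (!all(lens == seq_along(lines))) {
      stop("file is neither a square labeled matrix nor lower-triangular")
    }
    n <- length(lines)
    labels <- vapply(fields, function(f) trimws(f[1L]), "")
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n)[-1L]) {
      v <- as.numeric(fields[[i]][-1L])
      m[i, seq_len(i - 1L)] <- v
      m[seq_len(i - 1L), i] <- v
    }
  }
  as_dist_matrix(m)
}

#' Write a labeled distance matrix as square CSV/TSV
#'
#' @param d a `dist` object or labeled symmetric matrix.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_distance_matrix <- function(d, path, sep = "\t") {
  m <- as_dist_matrix(d)
  utils::write.table(m, path, sep = sep, quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Read a feature table (label column first) from CSV/TSV
#'
#' @param path file path; first row is a header, first column holds item
#'   labels, remaining columns are numeric attributes.
#' @param sep field separator; inferred by default.
#' @return a data frame with row names set to the labels.
#' @export
read_feature_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(vapply(df, is.numeric, NA))) stop("feature columns must be numeric")
  df
}

#' Write a feature table as CSV/TSV
#'
#' @param features a data frame or matrix with row labels.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_feature_table <- function(features, path, sep = "\t") {
  utils::write.table(features, path, sep = sep, quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Read a multi-tree Newick file
#'
#' One dendrogram per line, each terminated by `;`.
#'
#' @param path file path.
#' @return a list of `"dendro"` objects.
#' @export
read_trees <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no trees in ", path)
  lapply(lines, parse_newick)
}

#' Write dendrograms to a multi-tree Newick file
#'
#' One tree per line, in canonical child order so the file is a
#' deterministic function of the tree set.
#'
#' @param trees a `"tie_hclust"` fit or list of `"dendro"` objects.
#' @param path output file path.
#' @param with_heights also write branch lengths from merge heights.
#' @export
write_trees <- function(trees, path, with_heights = FALSE) {
  trees <- as_tree_list(trees)
  writeLines(vapply(trees, write_newick, "", with_heights = with_heights), path)
  invisible(path)
}

#' Read a cluster-query file
#'
#' One cluster per line: a line ending in `;` is parsed as a Newick subtree
#' (graph form); any other line as a comma-separated leaf list (set form).
#'
#' @param path file path.
#' @return a list of `"cluster_query"` objects.
#' @export
read_clusters <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no clusters in ", path)
  lapply(lines, cluster_query)
}
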