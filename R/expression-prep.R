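#' Filter genes by the multi-tree expression criterion
#'
#' Keeps a gene if its VST-scale expression exceeds `vst_threshold` in at
#' least `min_samples` sections of each of at least `min_trees` distinct
#' trees. This is the expressed-gene filter applied before network
#' inference; gene order is preserved.
#'
#' @param series A [section_series()].
#' @param vst_threshold Expression threshold (VST units, default 3).
#' @param min_samples Minimum qualifying sections per tree (default 2).
#' @param min_trees Minimum number of qualifying trees (default 3).
#' @return The filtered [section_series()].
#' @export
filter_expressed <- function(series, vst_threshold = 3, min_samples = 2,
                             min_trees = 3) {
  stopifnot(inherits(series, "section_series"))
  trees <- unique(series$section_meta$tree)
  if (min_trees > length(trees))
    stop("min_trees exceeds the ", length(trees), " tree(s) present")
  above <- series$values > vst_threshold
  per_tree <- vapply(trees, function(tr) {
    rowSums(above[, series$section_meta$tree == tr, drop = FALSE]) >=
      min_samples
  }, logical(nrow(series$values)))
  per_tree <- matrix(per_tree, nrow = nrow(series$values))
  keep <- rowSums(per_tree) >= min_trees
  section_series(series$values[keep, , drop = FALSE], series$section_meta)
}

#' Standardize each gene's profile to mean zero and unit variance
#'
#' Scaling is across all sections of all trees. Rows with zero variance
#' become all zeros rather than NaN.
#'
#' @param series A [section_series()].
#' @return The scaled [section_series()].
#' @export
scale_per_gene <- function(series) {
  stopifnot(inherits(series, "section_series"))
  v <- series$values
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  v <- sweep(v, 1, mu)
  nz <- s > 0
  v[nz, ] <- v[nz, , drop = FALSE] / s[nz]
  v[!nz, ] <- 0
  section_series(v, series$section_meta)
}

#' Hierarchically cluster genes or sections
#'
#' Genes are clustered on correlation distance (1 - Pearson r) of their
#' scaled profiles with average linkage; sections on Euclidean distance of
#' their expression columns with Ward linkage. The linkage tree is cut into
#' `k` groups.
#'
#' @param series A [section_series()]; for `cluster_genes` the rows are
#'   scaled internally via [scale_per_gene()].
#' @param k Number of clusters (1 <= k <= number of items).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A `cluster_assignment`: list with `cluster` (named integer
#'   vector of labels 1..k), `tree` (the `hclust` object) and `k`.
#' @export
cluster_genes <- function(series, k, linkage = "average") {
  stopifnot(inherits(series, "section_series"))
  if (nrow(series$values) < 2) stop("need at least 2 genes")
  if (k < 1 || k > nrow(series$values)) stop("k must be in 1..n_genes")
  s <- apply(series$values, 1, sd)
  if (any(s == 0))
    stop("zero-variance gene(s) under Pearson distance: ",
         paste(head(rownames(series$values)[s == 0]), collapse = ", "))
  scaled <- scale_per_gene(series)$values
  d <- as.dist(1 - cor(t(scaled)))
  tree <- hclust(d, method = linkage)
  new_cluster_assignment(cutree(tree, k = k), tree, k)
}

#' @rdname cluster_genes
#' @export
cluster_sections <- function(series, k, linkage = "ward.D2") {
  stopifnot(inherits(series, "section_series"))
  if (ncol(series$values) < 2) stop("need at least 2 sections")
  if (k < 1 || k > ncol(series$values)) stop("k must be in 1..n_sections")
  d <- dist(t(series$values), method = "euclidean")
  tree <- hclust(d, method = linkage)
  new_cluster_assignment(cutree(tree, k = k), tree, k)
}

new_cluster_assignment <- function(labels, tree, k) {
  structure(list(cluster = labels, tree = tree, k = k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x$cluster), "items in", x$k,
      "clusters\n")
  print(table(x$cluster))
  invisible(x)
}

#' Write a cluster assignment as TSV and its linkage tree as JSON
#'
#' @param assignment A `cluster_assignment`.
#' @param tsv_path Path for the (item, cluster) table.
#' @param tree_path Optional path for the linkage tree (merge order and
#'   heights) as JSON.
#' @export
write_cluster_assignment <- function(assignment, tsv_path,
                                     tree_path = NULL) {
  write_tsv(data.frame(item = names(assignment$cluster),
                       cluster = unname(assignment$cluster)), tsv_path)
  if (!is.null(tree_path)) {
    tr <- assignment$tree
    jsonlite::write_json(list(merge = tr$merge, height = tr$height,
                              order = tr$order, labels = tr$labels),
                         tree_path, auto_unbox = FALSE, digits = NA)
  }
  invisible(assignment)
}
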