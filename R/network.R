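#' Sign of the co-expression between two genes
#'
#' The sign of the Pearson correlation of the two expression profiles;
#' exact zero correlation resolves to `"+"`. Edge signs distinguish genes
#' with the same (positive) versus opposite (negative) expression profile.
#'
#' @param series A [section_series()].
#' @param i,j Gene ids present in the series.
#' @return `"+"` or `"-"`.
#' @export
edge_sign <- function(series, i, j) {
  stopifnot(inherits(series, "section_series"))
  v <- series$values
  if (!all(c(i, j) %in% rownames(v))) stop("unknown gene id")
  if (sd(v[i, ]) == 0 || sd(v[j, ]) == 0)
    stop("zero-variance profile; filter such genes upstream")
  if (cor(v[i, ], v[j, ]) < 0) "-" else "+"
}

#' Build the signed co-expression network from CLR scores
#'
#' Genes i and j are linked iff their CLR z-composite score reaches
#' `threshold`; the edge carries the CLR score as weight and the sign of
#' the Pearson correlation of the two profiles. All genes are kept as
#' nodes, so genes with no edge at the cutoff appear isolated.
#'
#' @param clr CLR score matrix from [clr_transform()].
#' @param series The [section_series()] the scores were computed from
#'   (provides profiles for edge signs); gene ids must match `clr`.
#' @param threshold Co-expression cutoff on the CLR score (default 5).
#' @return A `coexpression_network`: list with `graph` (an
#'   [igraph::igraph] with edge attributes `clr` and `sign`), `genes` and
#'   `threshold`.
#' @export
build_network <- function(clr, series, threshold = 5) {
  stopifnot(is.matrix(clr))
  if (threshold < 0) stop("threshold must be nonnegative")
  genes <- rownames(clr)
  if (inherits(series, "section_series")) {
    if (!identical(genes, rownames(series$values)))
      stop("clr and series must share gene ids")
    vals <- series$values
  } else stop("'series' must be a section_series")
  Z <- unclass(clr)
  idx <- which(upper.tri(Z) & Z >= threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  if (nrow(idx)) {
    # sign of Pearson r via inner products of centered/scaled rows
    std <- vals - rowMeans(vals)
    rs <- sqrt(rowSums(std^2))
    rs[rs == 0] <- 1
    std <- std / rs
    r <- rowSums(std[idx[, 1], , drop = FALSE] *
                 std[idx[, 2], , drop = FALSE])
    edges <- rbind(genes[idx[, 1]], genes[idx[, 2]])
    g <- igraph::add_edges(g, as.vector(edges))
    g <- igraph::set_edge_attr(g, "clr", value = Z[idx])
    g <- igraph::set_edge_attr(g, "sign",
                               value = ifelse(r < 0, "-", "+"))
  }
  structure(list(graph = g, genes = genes, threshold = threshold),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network:", length(x$genes), "genes,",
      igraph::ecount(x$graph), "edges at CLR threshold", x$threshold, "\n")
  invisible(x)
}

#' Edge list of a co-expression network
#'
#' @param net A `coexpression_network`.
#' @return Data frame with columns gene_a, gene_b, clr, sign.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      clr = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  ends <- igraph::as_edgelist(g)
  data.frame(gene_a = ends[, 1], gene_b = ends[, 2],
             clr = igraph::edge_attr(g, "clr"),
             sign = igraph::edge_attr(g, "sign"),
             stringsAsFactors = FALSE)
}

#' Write a network as an edge-list TSV or as GraphML
#'
#' @param net A `coexpression_network`.
#' @param path Output file path.
#' @export
write_network_edges <- function(net, path) {
  write_tsv(network_edges(net), path)
  invisible(net)
}

#' @rdname write_network_edges
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(net)
}
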