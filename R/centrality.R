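#' Betweenness centrality of every gene in the network
#'
#' Unweighted shortest-path betweenness with fractional credit across
#' equal-length paths (Brandes accumulation), normalized by the number of
#' node pairs `(N-1)(N-2)/2` so values lie in \[0, 1\]. CLR edge weights are
#' ignored for path lengths; isolated nodes score 0.
#'
#' @param net A `coexpression_network` (or an `igraph` graph).
#' @return Named numeric vector, one value per gene.
#' @export
betweenness_centrality <- function(net) {
  g <- as_graph(net)
  if (igraph::vcount(g) < 3) stop("need at least 3 nodes")
  igraph::betweenness(g, directed = FALSE, normalized = TRUE,
                      weights = NA)
}

#' Closeness centrality with the reachable-set correction
#'
#' For node v with r reachable other nodes at total shortest-path distance
#' S, closeness is `(r / (N - 1)) * (r / S)`: the inverse mean distance to
#' the reachable set, scaled by the fraction of the network that is
#' reachable. On a connected graph this is the familiar normalized inverse
#' of the sum of distances; the correction keeps the score defined and
#' comparable on disconnected graphs. Isolated nodes score 0.
#'
#' @param net A `coexpression_network` (or an `igraph` graph).
#' @return Named numeric vector, one value per gene.
#' @export
closeness_centrality <- function(net) {
  g <- as_graph(net)
  N <- igraph::vcount(g)
  if (N < 2) stop("need at least 2 nodes")
  d <- igraph::distances(g, weights = NA)
  diag(d) <- Inf
  fin <- is.finite(d)
  r <- rowSums(fin)
  S <- rowSums(ifelse(fin, d, 0))
  cl <- ifelse(r > 0, (r / (N - 1)) * (r / S), 0)
  setNames(cl, igraph::V(g)$name)
}

#' Degree of every gene (incident edge count; signs ignored)
#'
#' @param net A `coexpression_network` (or an `igraph` graph).
#' @return Named integer vector.
#' @export
node_degree <- function(net) {
  g <- as_graph(net)
  igraph::degree(g)
}

as_graph <- function(net) {
  if (inherits(net, "coexpression_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected a coexpression_network or igraph object")
}

#' Rank values in descending order, ties sharing the minimum rank
#'
#' Rank 1 is the largest value; equal values all receive the smallest rank
#' applicable to the block.
#'
#' @param values Nonempty numeric vector.
#' @return Integer ranks, same length and names as `values`.
#' @export
rank_descending <- function(values) {
  if (!length(values)) stop("empty value vector")
  as.integer(rank(-values, ties.method = "min"))
}

#' Assemble the per-gene centrality table
#'
#' Computes betweenness, closeness and degree, ranks genes (rank 1 =
#' highest), flags hubs via [call_hubs()] and assigns node categories via
#' [categorize_nodes()].
#'
#' @param net A `coexpression_network`.
#' @param hub_fraction Fraction of top-betweenness genes called hubs
#'   (default 0.20).
#' @param high_quantile Quantile defining "high" for node categories.
#' @return Data frame with columns gene, btw, cl, degree, btw_rank,
#'   cl_rank, hub, category.
#' @export
centrality_table <- function(net, hub_fraction = 0.20,
                             high_quantile = 0.80) {
  btw <- betweenness_centrality(net)
  cl <- closeness_centrality(net)
  deg <- node_degree(net)
  tab <- data.frame(gene = names(btw), btw = unname(btw),
                    cl = unname(cl[names(btw)]),
                    degree = as.integer(deg[names(btw)]),
                    btw_rank = rank_descending(btw),
                    cl_rank = rank_descending(cl[names(btw)]),
                    stringsAsFactors = FALSE)
  tab$hub <- tab$gene %in% call_hubs(tab, fraction = hub_fraction)
  tab$category <- categorize_nodes(tab, high_quantile = high_quantile)
  tab
}

#' Call hub genes: the top fraction by betweenness rank
#'
#' Hubs are the genes whose betweenness rank is within the top `fraction`
#' of the network (`btw_rank <= ceiling(fraction * N)`). Because tied
#' values share the minimum rank, a tie spanning the cutoff is included in
#' full rather than split arbitrarily.
#'
#' @param table Centrality table with columns `gene` and `btw_rank` (or
#'   `btw`, from which ranks are computed).
#' @param fraction Fraction of genes to call (0 < fraction <= 1).
#' @return Character vector of hub gene ids.
#' @export
call_hubs <- function(table, fraction = 0.20) {
  if (!nrow(table)) stop("empty centrality table")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  rk <- if ("btw_rank" %in% names(table)) table$btw_rank
        else rank_descending(table$btw)
  cutoff <- ceiling(fraction * nrow(table))
  table$gene[rk <= cutoff]
}

#' Categorize network nodes by their centrality profile
#'
#' A metric is "high" for a node when its value reaches the
#' `high_quantile` quantile across all nodes. Categories follow a
#' betweenness-first cascade: center (high BTW, Cl and degree), connecting
#' (high BTW and Cl, low degree), monopole (high BTW, low Cl and degree),
#' edge (everything else, i.e. low BTW). Combinations not literally listed
#' resolve to the nearest category in that priority order.
#'
#' @param table Centrality table with columns btw, cl, degree.
#' @param high_quantile Quantile defining "high" (default 0.80).
#' @return Character vector of categories, one per row of `table`.
#' @export
categorize_nodes <- function(table, high_quantile = 0.80) {
  hb <- table$btw >= quantile(table$btw, high_quantile)
  hc <- table$cl >= quantile(table$cl, high_quantile)
  hd <- table$degree >= quantile(table$degree, high_quantile)
  ifelse(hb & hc & hd, "center",
         ifelse(hb & hc, "connecting",
                ifelse(hb, "monopole", "edge")))
}

#' Write the centrality table as TSV
#'
#' @param table Data frame from [centrality_table()].
#' @param path Output path.
#' @export
write_centrality_table <- function(table, path) {
  write_tsv(table, path)
  invisible(table)
}
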