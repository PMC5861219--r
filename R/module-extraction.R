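#' Extract the co-expression module around a seed gene
#'
#' The module is the seed plus its direct neighbors at edges with CLR
#' weight at least `threshold`, together with all induced edges (again at
#' or above `threshold`) among the members. Optional annotation tables add
#' per-member flags: hub status (from a centrality table), ethylene
#' responsiveness (from a response table) and TF family.
#'
#' @param net A `coexpression_network`.
#' @param seed Gene id present in the network.
#' @param threshold Edge weight cutoff; defaults to the network's own
#'   threshold. Raising it shrinks the module, it can never grow it.
#' @param centrality Optional data frame from [centrality_table()].
#' @param response Optional data frame from [response_table()].
#' @param tf_table Optional data frame (gene, family).
#' @return A `gene_module`: list with `seed`, `members`, `edges` (data
#'   frame a, b, weight, sign) and `flags` (data frame gene, hub,
#'   ethylene_responsive, tf_family).
#' @export
extract_module <- function(net, seed, threshold = net$threshold,
                           centrality = NULL, response = NULL,
                           tf_table = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!seed %in% net$genes) stop("unknown seed gene: ", seed)
  g <- net$graph
  keep <- igraph::E(g)[igraph::edge_attr(g, "clr") >= threshold]
  g <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
  nbr <- igraph::neighbors(g, seed)$name
  members <- union(seed, nbr)
  sub <- igraph::induced_subgraph(g, members)
  if (igraph::ecount(sub)) {
    ends <- igraph::as_edgelist(sub)
    edges <- data.frame(a = ends[, 1], b = ends[, 2],
                        weight = igraph::edge_attr(sub, "clr"),
                        sign = igraph::edge_attr(sub, "sign"),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(), b = character(),
                        weight = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  }
  flags <- data.frame(gene = members, hub = NA, ethylene_responsive = NA,
                      tf_family = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(centrality))
    flags$hub <- centrality$hub[match(members, centrality$gene)]
  if (!is.null(response))
    flags$ethylene_responsive <-
      response$responsive[match(members, response$gene)]
  if (!is.null(tf_table))
    flags$tf_family <- tf_table$family[match(members, tf_table$gene)]
  structure(list(seed = seed, members = members, edges = edges,
                 flags = flags),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat("gene_module: seed", x$seed, "with", length(x$members), "members and",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Shared non-seed members of two gene modules
#'
#' @param mA,mB Objects from [extract_module()].
#' @return Character vector of genes present in both modules after
#'   removing each module's own seed.
#' @export
module_overlap <- function(mA, mB) {
  intersect(setdiff(mA$members, mA$seed), setdiff(mB$members, mB$seed))
}

#' Summarize the composition of a gene module
#'
#' @param module A `gene_module`.
#' @return List of counts: members, TFs, hubs, responsive members,
#'   positive and negative edges.
#' @export
module_summary <- function(module) {
  fl <- module$flags
  list(n_members = length(module$members),
       n_tfs = sum(!is.na(fl$tf_family) & fl$tf_family != "none"),
       n_hubs = sum(fl$hub %in% TRUE),
       n_responsive = sum(fl$ethylene_responsive %in% TRUE),
       n_pos_edges = sum(module$edges$sign == "+"),
       n_neg_edges = sum(module$edges$sign == "-"))
}

#' Write / read a gene module as JSON
#'
#' @param module A `gene_module`.
#' @param path File path.
#' @return `read_module` returns a `gene_module`.
#' @export
write_module <- function(module, path) {
  jsonlite::write_json(
    list(seed = module$seed, members = module$members,
         edges = module$edges, flags = module$flags),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(module)
}

#' @rdname write_module
#' @export
read_module <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as.data.frame(x$edges, stringsAsFactors = FALSE)
  flags <- as.data.frame(x$flags, stringsAsFactors = FALSE)
  structure(list(seed = x$seed, members = x$members, edges = edges,
                 flags = flags),
            class = "gene_module")
}
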