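# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (Floyd-Warshall plus explicit shortest-path
# enumeration, two-pass loops, combinatorial enumeration) and share no code
# with the implementation paths they check.

# all-pairs betweenness and closeness by exhaustive shortest-path
# enumeration on an adjacency matrix (0/1, symmetric, zero diagonal)
oracle_centrality <- function(adj) {
  N <- nrow(adj)
  d <- matrix(Inf, N, N)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(N)) for (i in seq_len(N)) for (j in seq_len(N))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]

  # every shortest path from s to t, as a list of vertex vectors
  all_paths <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (u in which(adj[s, ] == 1)) {
      if (is.finite(d[u, t]) && d[u, t] == d[s, t] - 1) {
        for (p in all_paths(u, t)) out[[length(out) + 1]] <- c(s, p)
      }
    }
    out
  }

  btw <- numeric(N)
  for (s in seq_len(N - 1)) for (t in seq((s + 1), N)) {
    if (!is.finite(d[s, t])) next
    paths <- all_paths(s, t)
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(paths)
    }
  }
  btw <- btw / ((N - 1) * (N - 2) / 2)

  cl <- numeric(N)
  for (v in seq_len(N)) {
    dv <- d[v, -v]
    r <- sum(is.finite(dv))
    S <- sum(dv[is.finite(dv)])
    cl[v] <- if (r > 0) (r / (N - 1)) * (r / S) else 0
  }
  list(btw = btw, cl = cl)
}

# random connected-or-not test graph as a named igraph
random_test_graph <- function(n, p) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(n))
  list(graph = g, adj = adj)
}

# literal two-pass CLR implementation
clr_direct <- function(mi) {
  G <- nrow(mi)
  diag(mi) <- 0
  z <- matrix(0, G, G)
  for (i in seq_len(G)) {
    off <- mi[i, -i]
    m <- mean(off)
    s <- sd(off)
    for (j in seq_len(G)) {
      if (j != i && s > 0) z[i, j] <- max(0, (mi[i, j] - m) / s)
    }
  }
  Z <- matrix(0, G, G)
  for (i in seq_len(G)) for (j in seq_len(G))
    Z[i, j] <- sqrt(z[i, j]^2 + z[j, i]^2)
  diag(Z) <- 0
  Z
}

# hypergeometric upper tail by complete enumeration of all C(N, n) draws
hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(dr) sum(dr <= K) >= k))
}

# small section_series from a bare matrix (single tree unless given)
make_series <- function(values, trees = NULL, zones = NULL) {
  ns <- ncol(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(trees)) trees <- rep("T1", ns)
  pos <- stats::ave(seq_len(ns), trees, FUN = seq_along)
  if (is.null(zones)) zones <- rep(zone_levels(), length.out = ns)
  colnames(values) <- paste0(trees, "_s", pos)
  section_series(values, data.frame(
    section = colnames(values), tree = trees, zone = zones,
    position = pos, stringsAsFactors = FALSE))
}

# count_experiment with a full 3x2 design, one value matrix supplied
make_experiment <- function(counts, n_rep) {
  meta <- expand.grid(replicate = seq_len(n_rep),
                      treatment = c("mock", "ACC"),
                      genotype = c("WT", "etr1_LMX5", "etr1_35S"),
                      stringsAsFactors = FALSE)
  meta$library <- sprintf("%s_%s_r%d", meta$genotype, meta$treatment,
                          meta$replicate)
  meta <- meta[, c("library", "genotype", "treatment", "replicate")]
  colnames(counts) <- meta$library
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  count_experiment(counts, meta)
}

# network straight from a handcrafted score matrix (uncorrelated profiles
# replaced by deterministic ones so edge signs are well defined)
network_from_scores <- function(Z, threshold = 5, values = NULL) {
  genes <- rownames(Z)
  if (is.null(values)) {
    set.seed(42)
    values <- matrix(rnorm(length(genes) * 8), nrow = length(genes),
                     dimnames = list(genes, NULL))
  }
  series <- make_series(values)
  build_network(structure(Z, class = c("clr_matrix", "matrix")), series,
                threshold = threshold)
}
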