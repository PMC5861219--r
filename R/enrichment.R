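#' Hypergeometric over-representation test of a gene list
#'
#' Tests each term of a gene-set collection for over-representation in the
#' query list with the one-sided hypergeometric upper tail
#' `p = P(X >= k)` for X ~ Hypergeometric(N, K, n), where N is the
#' universe size, K the term size, n the query size and k the overlap.
#' Query genes outside the universe are dropped with a warning. The paper
#' convention is raw p-values at a reporting cutoff; an optional BH
#' adjustment is available but off by default.
#'
#' @param query Character vector of gene ids.
#' @param collection List with `sets` (named list of gene vectors) and
#'   `universe` (character vector); term sets are intersected with the
#'   universe.
#' @param p_cutoff Report terms with p below this cutoff (default 0.05).
#' @param adjust If `TRUE`, add a BH-adjusted column `q` and filter on it
#'   instead of raw p.
#' @return Data frame sorted by p with columns term, k, K, n, N, p (and q
#'   when `adjust` is `TRUE`).
#' @export
hypergeometric_enrichment <- function(query, collection, p_cutoff = 0.05,
                                      adjust = FALSE) {
  universe <- unique(collection$universe)
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (!length(query)) stop("no query genes left inside the universe")
  }
  query <- unique(query)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(term) {
    set <- intersect(unique(collection$sets[[term]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term), , drop = FALSE]
  if (adjust) {
    out$q <- bh_adjust(out$p)
    out <- out[out$q < p_cutoff, , drop = FALSE]
  } else {
    out <- out[out$p < p_cutoff, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' @param table Data frame from [hypergeometric_enrichment()].
#' @param path Output path.
#' @export
write_enrichment <- function(table, path) {
  write_tsv(table, path)
  invisible(table)
}
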