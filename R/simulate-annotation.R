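#' Simulate a gene-set collection and TF-family table with planted enrichment
#'
#' Produces a named gene-set collection over a gene universe. Background
#' membership is Bernoulli at `base_rate` per gene and term. For each entry
#' in `planted` (term id -> gene set, typically a planted module), the
#' membership probability of those genes in that term is raised to
#' `min(1, base_rate * odds_factor)`, so the term over-represents its module
#' by a configurable odds factor; `odds_factor = 1` gives a null collection.
#' A transcription-factor family table assigns a family label to a random
#' subset of genes.
#'
#' @param seed Integer RNG seed.
#' @param genes Character vector, the gene universe (nonempty).
#' @param n_terms Number of background terms (planted terms are additional).
#' @param planted Named list: term id -> gene ids to over-represent.
#' @param base_rate Background membership probability per gene and term.
#' @param odds_factor Multiplier on `base_rate` for planted term members;
#'   the default 20 with `base_rate = 0.05` gives full coverage.
#' @param tf_fraction Fraction of genes assigned a TF family.
#' @return A list with `collection` (list with `sets`, a named list of gene
#'   vectors, and `universe`) and `tf_table` (data frame gene, family;
#'   family `"none"` for non-TFs).
#' @export
generate_annotation <- function(seed = 1L, genes, n_terms = 20L,
                                planted = list(), base_rate = 0.05,
                                odds_factor = 20, tf_fraction = 0.1) {
  if (length(genes) == 0) stop("empty gene universe")
  stopifnot(base_rate > 0, base_rate <= 1, odds_factor > 0)
  if (length(planted) && !all(unlist(planted) %in% genes))
    stop("planted term genes must be in the universe")
  planted_rate <- min(1, base_rate * odds_factor)
  families <- c("NAC", "MYB", "ERF", "WRKY", "bZIP", "C2H2")

  withr::with_seed(seed, {
    sets <- list()
    for (i in seq_len(n_terms)) {
      keep <- runif(length(genes)) < base_rate
      sets[[sprintf("TERM%03d", i)]] <- genes[keep]
    }
    for (term in names(planted)) {
      pr <- ifelse(genes %in% planted[[term]], planted_rate, base_rate)
      sets[[term]] <- genes[runif(length(genes)) < pr]
    }
    tf <- rep("none", length(genes))
    is_tf <- runif(length(genes)) < tf_fraction
    tf[is_tf] <- sample(families, sum(is_tf), replace = TRUE)
    list(collection = list(sets = sets, universe = genes),
         tf_table = data.frame(gene = genes, family = tf,
                               stringsAsFactors = FALSE))
  })
}
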