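#' Configuration for the factorial count simulator
#'
#' Emulates the ACC application experiment: three genotypes (wild type and
#' two ethylene-insensitive etr1-1 receptor lines), two treatments (mock,
#' ACC), replicated libraries, negative-binomial counts with variance
#' `mu + dispersion * mu^2`. Planted responder genes receive a
#' `2^responder_log2fc` fold change in wild-type ACC libraries only; every
#' other genotype x treatment cell stays at baseline, mimicking a response
#' that requires an intact ethylene receptor.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes.
#' @param n_replicates Libraries per genotype x treatment cell (>= 1).
#' @param dispersion Negative-binomial dispersion phi >= 0 (0 = Poisson).
#' @param responder_genes Gene ids with the planted WT-only ACC effect;
#'   `NULL` plants none (a null experiment).
#' @param responder_log2fc Planted log2 fold change (default 2).
#' @param library_size_mean,library_size_cv Mean and coefficient of
#'   variation of the log-normal library sizes.
#' @param baseline_log_mean,baseline_log_sd Location/spread (log scale) of
#'   the per-gene relative expression used to split a library's reads.
#' @return A `count_sim_config` list.
#' @export
count_sim_config <- function(seed = 1L, n_genes = 2000L, n_replicates = 3L,
                             dispersion = 0.05, responder_genes = NULL,
                             responder_log2fc = 2,
                             library_size_mean = 1e6, library_size_cv = 0.1,
                             baseline_log_mean = log(300),
                             baseline_log_sd = 1) {
  stopifnot(n_genes >= 1, dispersion >= 0, library_size_mean > 0,
            library_size_cv > 0)
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 genotypes = GENOTYPES, treatments = TREATMENTS,
                 n_replicates = as.integer(n_replicates),
                 dispersion = dispersion,
                 responder_genes = responder_genes,
                 responder_log2fc = responder_log2fc,
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd),
            class = "count_sim_config")
}

#' Simulate the factorial ACC count experiment
#'
#' Draws library sizes log-normally, splits each library's expected reads
#' over genes by a log-normal relative-abundance profile shared across
#' libraries, applies the planted fold change to responder genes in the
#' WT x ACC cell, and samples negative-binomial counts (Poisson when
#' `dispersion = 0`).
#'
#' @param config A [count_sim_config()].
#' @return A list with `experiment` (a [count_experiment()]) and `truth`
#'   (responder gene ids and the planted log2 fold change).
#' @export
generate_count_experiment <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  genes <- default_gene_ids(config$n_genes)
  responders <- config$responder_genes
  if (!is.null(responders) && !all(responders %in% genes))
    stop("responder_genes must be among the generated gene ids")

  meta <- expand.grid(replicate = seq_len(config$n_replicates),
                      treatment = TREATMENTS, genotype = GENOTYPES,
                      stringsAsFactors = FALSE)
  meta <- meta[, c("genotype", "treatment", "replicate")]
  meta$library <- sprintf("%s_%s_r%d", meta$genotype, meta$treatment,
                          meta$replicate)
  meta <- meta[, c("library", "genotype", "treatment", "replicate")]

  counts <- withr::with_seed(config$seed, {
    n_lib <- nrow(meta)
    sdlog <- sqrt(log(1 + config$library_size_cv^2))
    lib_sizes <- exp(rnorm(n_lib, log(config$library_size_mean) -
                             sdlog^2 / 2, sdlog))
    w <- exp(rnorm(config$n_genes, config$baseline_log_mean,
                   config$baseline_log_sd))
    p <- w / sum(w)
    mu <- outer(p, lib_sizes)  # genes x libraries baseline means
    dimnames(mu) <- list(genes, meta$library)
    if (length(responders)) {
      wt_acc <- meta$genotype == "WT" & meta$treatment == "ACC"
      mu[responders, wt_acc] <- mu[responders, wt_acc] *
        2^config$responder_log2fc
    }
    draw <- if (config$dispersion == 0) {
      function(m) rpois(length(m), m)
    } else {
      function(m) rnbinom(length(m), mu = m, size = 1 / config$dispersion)
    }
    matrix(draw(mu), nrow = config$n_genes,
           dimnames = dimnames(mu))
  })

  truth <- list(responders = if (is.null(responders)) character() else
                  responders,
                log2fc = config$responder_log2fc)
  list(experiment = count_experiment(counts, meta), truth = truth)
}
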