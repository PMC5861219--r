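#' Filter genes on minimum library counts
#'
#' The default rule (`"all"`) drops a gene if any library has fewer than
#' `min_count` reads, i.e. only genes reaching the minimum in every
#' library are kept. The lenient alternative (`"any"`) keeps a gene if at
#' least one library reaches `min_count`.
#'
#' @param exp A [count_experiment()].
#' @param min_count Minimum read count (default 10).
#' @param rule `"all"` (default) or `"any"`, see above.
#' @return The filtered [count_experiment()].
#' @export
filter_low_counts <- function(exp, min_count = 10,
                              rule = c("all", "any")) {
  stopifnot(inherits(exp, "count_experiment"))
  rule <- match.arg(rule)
  keep <- switch(rule,
                 all = rowSums(exp$counts < min_count) == 0,
                 any = rowSums(exp$counts >= min_count) > 0)
  count_experiment(exp$counts[keep, , drop = FALSE], exp$library_meta)
}

#' TMM normalization factors for the libraries
#'
#' Trimmed-mean-of-M-values factors (30% M-trim, 5% A-trim, reference
#' library chosen by upper-quartile proximity to the mean), normalized to
#' geometric mean 1, as computed by `edgeR::calcNormFactors`.
#'
#' @param exp A [count_experiment()].
#' @return Named positive numeric vector, one factor per library.
#' @export
normalization_factors <- function(exp) {
  stopifnot(inherits(exp, "count_experiment"))
  if (ncol(exp$counts) < 2) stop("need at least 2 libraries")
  if (any(colSums(exp$counts) == 0)) stop("library with all-zero counts")
  f <- edgeR::calcNormFactors(exp$counts, method = "TMM")
  setNames(f, colnames(exp$counts))
}

#' Log2 counts per million with a pseudocount offset
#'
#' `log2((count + prior) / (libsize * factor + 2 * prior) * 1e6)` per gene
#' and library, so zero counts map to a finite value.
#'
#' @param exp A [count_experiment()].
#' @param factors Positive normalization factors, one per library
#'   (default: [normalization_factors()]).
#' @param prior Pseudocount (default 0.5).
#' @return Numeric genes x libraries matrix of log2-CPM values.
#' @export
log_cpm <- function(exp, factors = normalization_factors(exp),
                    prior = 0.5) {
  stopifnot(inherits(exp, "count_experiment"))
  if (any(factors <= 0)) stop("normalization factors must be positive")
  eff <- colSums(exp$counts) * factors
  t(log2(t(exp$counts + prior) / (eff + 2 * prior) * 1e6))
}

#' Fit the genewise cell-means model and ACC-vs-mock contrasts
#'
#' Ordinary least squares on the six genotype x treatment cell means of
#' the log2-CPM values (replicates treated as exchangeable within a cell),
#' with one ACC - mock contrast per genotype, in log2 units. Fitting goes
#' through `limma::lmFit`/`contrasts.fit`.
#'
#' @param logcpm Numeric genes x libraries matrix from [log_cpm()].
#' @param library_meta Library metadata (columns genotype, treatment) with
#'   rows matching the columns of `logcpm`.
#' @return List with `coefficients` (genes x 3 matrix of per-genotype log2
#'   fold changes, columns `WT`, `etr1_LMX5`, `etr1_35S`),
#'   `stdev_unscaled` (matching unscaled standard errors), `sigma2`
#'   (residual variances) and `df_residual`.
#' @export
fit_genewise_model <- function(logcpm, library_meta) {
  if (ncol(logcpm) != nrow(library_meta))
    stop("one metadata row per library is required")
  grp <- factor(paste(library_meta$genotype, library_meta$treatment,
                      sep = "."),
                levels = as.vector(outer(GENOTYPES, TREATMENTS,
                                         paste, sep = ".")))
  if (any(table(grp) == 0)) stop("empty genotype x treatment cell")
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- levels(grp)
  fit <- limma::lmFit(logcpm, design)
  contr <- vapply(GENOTYPES, function(g) {
    (colnames(design) == paste(g, "ACC", sep = ".")) -
      (colnames(design) == paste(g, "mock", sep = "."))
  }, numeric(ncol(design)))
  cf <- limma::contrasts.fit(fit, contr)
  list(coefficients = cf$coefficients,
       stdev_unscaled = cf$stdev.unscaled,
       sigma2 = cf$sigma^2,
       df_residual = cf$df.residual[1])
}

#' Empirical-Bayes moderation of genewise variances
#'
#' Fits a scaled inverse-chi-square prior to the genewise residual
#' variances by the method of moments on log variances (Smyth 2004, as in
#' `limma::squeezeVar`) and returns the posterior variances
#' `(d0 * s0^2 + d * s2) / (d0 + d)`. When all variances are equal the
#' prior degrees of freedom are infinite and the variances pass through
#' unchanged. Supplying `d0` (and optionally `s02`) overrides the fit;
#' `d0 = 0` reproduces the unmoderated variances exactly.
#'
#' @param s2 Genewise residual variances (length >= 2, not all zero).
#' @param df Residual degrees of freedom of each variance.
#' @param d0,s02 Optional prior degrees of freedom and prior variance.
#' @return List with `d0`, `s02` and `s2_post`.
#' @export
moderate_variances <- function(s2, df, d0 = NULL, s02 = NULL) {
  if (length(s2) < 2) stop("need at least 2 genes")
  if (all(s2 == 0)) stop("all residual variances are zero")
  if (is.null(d0)) {
    sq <- limma::squeezeVar(s2, df)
    d0 <- sq$df.prior
    s02 <- sq$var.prior
    s2_post <- sq$var.post
  } else {
    if (d0 == 0) {
      s02 <- if (is.null(s02)) NA_real_ else s02
      s2_post <- s2
    } else {
      if (is.null(s02)) s02 <- mean(s2)
      if (is.infinite(d0)) s2_post <- rep(s02, length(s2))
      else s2_post <- (d0 * s02 + df * s2) / (d0 + df)
    }
  }
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, via
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-gene ACC response table with moderated statistics
#'
#' Runs the full differential-expression path on a count experiment:
#' low-count filter, TMM normalization, log2-CPM, genewise cell-means fit,
#' empirical-Bayes variance moderation, moderated t, p and BH q per
#' genotype contrast (ACC vs mock), and the ethylene-responsive call.
#'
#' @param exp A [count_experiment()].
#' @param min_count,filter_rule Passed to [filter_low_counts()].
#' @param prior Log-CPM pseudocount.
#' @param d0 Optional override of the prior degrees of freedom (see
#'   [moderate_variances()]).
#' @param fc_threshold,q_threshold,delta_threshold Passed to
#'   [call_ethylene_responsive()].
#' @return Data frame with one row per retained gene: gene, per-genotype
#'   `log2fc_*`, `t_*`, `p_*`, `q_*` and the `responsive` flag.
#' @export
response_table <- function(exp, min_count = 10, filter_rule = "all",
                           prior = 0.5, d0 = NULL, fc_threshold = 1,
                           q_threshold = 0.01, delta_threshold = 1) {
  exp <- filter_low_counts(exp, min_count = min_count, rule = filter_rule)
  if (!nrow(exp$counts)) stop("no genes left after the low-count filter")
  factors <- normalization_factors(exp)
  lc <- log_cpm(exp, factors, prior = prior)
  fit <- fit_genewise_model(lc, exp$library_meta)
  mod <- moderate_variances(fit$sigma2, fit$df_residual, d0 = d0)
  df_total <- fit$df_residual + mod$d0
  tab <- data.frame(gene = rownames(fit$coefficients),
                    stringsAsFactors = FALSE)
  for (g in GENOTYPES) {
    lfc <- fit$coefficients[, g]
    tt <- lfc / (fit$stdev_unscaled[, g] * sqrt(mod$s2_post))
    pp <- 2 * pt(-abs(tt), df = df_total)
    tab[[paste0("log2fc_", g)]] <- unname(lfc)
    tab[[paste0("t_", g)]] <- unname(tt)
    tab[[paste0("p_", g)]] <- unname(pp)
    tab[[paste0("q_", g)]] <- bh_adjust(unname(pp))
  }
  tab$responsive <- tab$gene %in%
    call_ethylene_responsive(tab, fc_threshold = fc_threshold,
                             q_threshold = q_threshold,
                             delta_threshold = delta_threshold)
  tab
}

#' Call ethylene-responsive genes
#'
#' A gene is ethylene responsive when (i) it responds at least
#' `2^fc_threshold`-fold to ACC in wild type at `q < q_threshold`, and
#' (ii) its wild-type log2 response differs by at least `delta_threshold`
#' from the response of both ethylene-insensitive genotypes, so the
#' response requires an intact ethylene receptor.
#'
#' @param table Response table with columns `gene`, `log2fc_WT`, `q_WT`,
#'   `log2fc_etr1_LMX5` and `log2fc_etr1_35S`.
#' @param fc_threshold Minimum |log2 fold change| in WT (default 1).
#' @param q_threshold BH q cutoff in WT (default 0.01).
#' @param delta_threshold Minimum |log2fc_WT - log2fc_transgenic| required
#'   against both insensitive lines (default 1).
#' @return Character vector of responsive gene ids.
#' @export
call_ethylene_responsive <- function(table, fc_threshold = 1,
                                     q_threshold = 0.01,
                                     delta_threshold = 1) {
  req <- c("gene", "log2fc_WT", "q_WT", "log2fc_etr1_LMX5",
           "log2fc_etr1_35S")
  if (!all(req %in% names(table)))
    stop("missing genotype contrast column(s): ",
         paste(setdiff(req, names(table)), collapse = ", "))
  ok <- abs(table$log2fc_WT) >= fc_threshold &
    table$q_WT < q_threshold &
    abs(table$log2fc_WT - table$log2fc_etr1_LMX5) >= delta_threshold &
    abs(table$log2fc_WT - table$log2fc_etr1_35S) >= delta_threshold
  table$gene[ok]
}

#' Relative expression from qPCR cycle thresholds
#'
#' The 2^-dCt quantity: expression of a target gene relative to a
#' reference gene from their Ct values.
#'
#' @param ct_target,ct_reference Finite Ct values (vectors recycle).
#' @return `2^-(ct_target - ct_reference)`.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_reference)))
    stop("Ct values must be finite")
  2^-(ct_target - ct_reference)
}

#' Write the response table as TSV
#'
#' @param table Data frame from [response_table()].
#' @param path Output path.
#' @export
write_response_table <- function(table, path) {
  write_tsv(table, path)
  invisible(table)
}
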