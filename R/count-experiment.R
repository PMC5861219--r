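GENOTYPES <- c("WT", "etr1_LMX5", "etr1_35S")
TREATMENTS <- c("mock", "ACC")

#' Construct a factorial count experiment
#'
#' A `count_experiment` holds a genes x libraries matrix of nonnegative
#' integer RNA-Seq counts from the 3-genotype x 2-treatment ACC application
#' design: wild type plus two ethylene-insensitive etr1-1 receptor lines,
#' each treated with mock (water) or ACC.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   libraries in columns (colnames = library ids).
#' @param library_meta Data frame with columns `library`, `genotype`
#'   (`WT`, `etr1_LMX5` or `etr1_35S`), `treatment` (`mock` or `ACC`) and
#'   `replicate`; one row per column of `counts`, same order. Every
#'   genotype x treatment cell must contain at least one library.
#' @return An object of class `count_experiment`.
#' @export
count_experiment <- function(counts, library_meta) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs gene and library ids as dimnames")
  req <- c("library", "genotype", "treatment", "replicate")
  if (!all(req %in% names(library_meta)))
    stop("library_meta must have columns: ", paste(req, collapse = ", "))
  if (!identical(as.character(library_meta$library), colnames(counts)))
    stop("library_meta$library must match colnames(counts) in order")
  if (!all(library_meta$genotype %in% GENOTYPES))
    stop("genotype must be one of: ", paste(GENOTYPES, collapse = ", "))
  if (!all(library_meta$treatment %in% TREATMENTS))
    stop("treatment must be one of: ", paste(TREATMENTS, collapse = ", "))
  cells <- table(factor(library_meta$genotype, GENOTYPES),
                 factor(library_meta$treatment, TREATMENTS))
  if (any(cells == 0))
    stop("every genotype x treatment cell needs at least one library")
  structure(list(counts = counts, library_meta = library_meta),
            class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat("count_experiment:", nrow(x$counts), "genes x", ncol(x$counts),
      "libraries\n")
  print(table(x$library_meta$genotype, x$library_meta$treatment))
  invisible(x)
}

#' @export
dim.count_experiment <- function(x) dim(x$counts)

#' Write / read a count experiment as a pair of TSV files
#'
#' @param exp A [count_experiment()].
#' @param counts_path,meta_path Paths for the count and metadata TSVs.
#' @return `read_count_experiment` returns a `count_experiment`.
#' @export
write_count_experiment <- function(exp, counts_path, meta_path) {
  df <- data.frame(gene = rownames(exp$counts), exp$counts,
                   check.names = FALSE)
  write_tsv(df, counts_path)
  write_tsv(exp$library_meta, meta_path)
  invisible(exp)
}

#' @rdname write_count_experiment
#' @export
read_count_experiment <- function(counts_path, meta_path) {
  df <- read_tsv(counts_path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  meta <- read_tsv(meta_path)
  meta$library <- as.character(meta$library)
  count_experiment(counts, meta)
}
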