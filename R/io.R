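# TSV dialect used everywhere: single header row, tab separated, no quoting,
# gene/item ids in column 1. Missing values are forbidden and fail fast.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (anyNA(df)) stop("missing values in ", path)
  df
}

#' Read / write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set format: one term per line with term id,
#' description, then member genes. Reading uses the standard fgsea parser.
#'
#' @param sets Named list of character vectors (term id -> member genes).
#' @param path File path.
#' @param descriptions Optional character vector of term descriptions
#'   (defaults to the term ids).
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fgsea::gmtPathways(path)
}
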