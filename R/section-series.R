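#' Construct a stem section expression series
#'
#' A `section_series` holds a genes x sections matrix of variance-stabilized
#' (VST-like) expression values together with per-section metadata: the tree
#' the section came from, its developmental zone and its position index along
#' the stem within that tree.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   sections in columns (colnames = section ids). All values finite.
#' @param section_meta Data frame with columns `section`, `tree`, `zone`
#'   (one of [zone_levels()]) and `position` (integer index, strictly
#'   increasing within each tree). One row per column of `values`, same order.
#' @return An object of class `section_series`: a list with elements
#'   `values` and `section_meta`.
#' @export
section_series <- function(values, section_meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("'values' needs gene ids as rownames")
  if (is.null(colnames(values))) stop("'values' needs section ids as colnames")
  req <- c("section", "tree", "zone", "position")
  if (!all(req %in% names(section_meta)))
    stop("section_meta must have columns: ", paste(req, collapse = ", "))
  if (nrow(section_meta) != ncol(values))
    stop("one metadata row per section is required")
  if (!identical(as.character(section_meta$section), colnames(values)))
    stop("section_meta$section must match colnames(values) in order")
  bad <- setdiff(unique(as.character(section_meta$zone)), ZONES)
  if (length(bad)) stop("unknown zone label(s): ", paste(bad, collapse = ", "))
  for (tr in unique(section_meta$tree)) {
    pos <- section_meta$position[section_meta$tree == tr]
    if (any(diff(pos) <= 0))
      stop("positions must be strictly increasing within tree ", tr)
  }
  structure(list(values = values, section_meta = section_meta),
            class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  cat("section_series:", nrow(x$values), "genes x", ncol(x$values),
      "sections from", length(unique(x$section_meta$tree)), "tree(s)\n")
  invisible(x)
}

#' @export
dim.section_series <- function(x) dim(x$values)

#' Write / read a section series as a pair of TSV files
#'
#' The expression table has gene ids in column `gene` and one column per
#' section; the metadata table has columns section, tree, zone, position.
#'
#' @param series A [section_series()].
#' @param expr_path,meta_path Paths for the expression and metadata TSVs.
#' @return `write_section_series` returns the series invisibly;
#'   `read_section_series` returns a `section_series`.
#' @export
write_section_series <- function(series, expr_path, meta_path) {
  df <- data.frame(gene = rownames(series$values), series$values,
                   check.names = FALSE)
  write_tsv(df, expr_path)
  write_tsv(series$section_meta, meta_path)
  invisible(series)
}

#' @rdname write_section_series
#' @export
read_section_series <- function(expr_path, meta_path) {
  df <- read_tsv(expr_path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  meta <- read_tsv(meta_path)
  meta$section <- as.character(meta$section)
  meta$tree <- as.character(meta$tree)
  section_series(vals, meta)
}
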