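# equal-frequency (quantile) binning; ties broken by stable rank order so
# every gene's marginal bin counts depend only on (n, bins)
bin_equal_freq <- function(x, bins) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * bins / n) + 1L)
}

# marginal bin counts under equal-frequency binning of n values into B bins
marginal_counts <- function(n, bins) {
  tabulate(floor((seq_len(n) - 1) * bins / n) + 1L, nbins = bins)
}

default_bins <- function(n) min(10L, max(2L, floor(sqrt(n))))

#' Plug-in mutual information of two expression profiles
#'
#' Estimates MI (in nats) from the joint histogram of the two profiles under
#' equal-frequency marginal binning with `bins` bins. A zero-variance input
#' carries no information and returns 0.
#'
#' @param x,y Numeric vectors of equal length n >= 4.
#' @param bins Number of bins B >= 2; default `min(10, floor(sqrt(n)))`.
#' @return MI estimate in nats (nonnegative).
#' @export
mutual_information <- function(x, y, bins = default_bins(length(x))) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (bins < 2) stop("bins must be at least 2")
  if (sd(x) == 0 || sd(y) == 0) return(0)
  bx <- bin_equal_freq(x, bins)
  by <- bin_equal_freq(y, bins)
  joint <- tabulate(bx + bins * (by - 1L), nbins = bins * bins) / n
  px <- marginal_counts(n, bins) / n
  pxy_ind <- as.vector(outer(px, px))  # both marginals share the same counts
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / pxy_ind[pos]))
}

#' All-pairs mutual information matrix for a section series
#'
#' Computes the plug-in MI (equal-frequency binning, as in
#' [mutual_information()]) between every pair of gene profiles. The
#' computation is vectorized over bin pairs via indicator cross-products, so
#' it scales to hundreds of genes. The diagonal is 0 by convention and
#' zero-variance genes get 0 against everything.
#'
#' @param series A [section_series()] or a numeric genes x samples matrix.
#' @param bins Number of bins; default `min(10, floor(sqrt(n_samples)))`.
#' @return Symmetric nonnegative matrix (nats) with gene dimnames, class
#'   `mi_matrix`.
#' @export
mi_matrix <- function(series, bins = NULL) {
  v <- if (inherits(series, "section_series")) series$values else series
  stopifnot(is.matrix(v), is.numeric(v))
  n <- ncol(v)
  if (n < 4) stop("need at least 4 samples")
  if (is.null(bins)) bins <- default_bins(n)
  if (bins < 2) stop("bins must be at least 2")
  G <- nrow(v)
  b <- t(apply(v, 1, bin_equal_freq, bins = bins))  # genes x samples
  m <- marginal_counts(n, bins)
  mi <- matrix(0, G, G, dimnames = list(rownames(v), rownames(v)))
  for (a in seq_len(bins)) {
    Ia <- t(b == a)  # samples x genes indicator
    for (bb in seq_len(bins)) {
      Ib <- if (bb == a) Ia else t(b == bb)
      N <- crossprod(Ia, Ib)  # joint counts for bin pair (a, bb)
      term <- N / n * log(N * n / (m[a] * m[bb]))
      term[N == 0] <- 0
      mi <- mi + term
    }
  }
  mi <- (mi + t(mi)) / 2  # exact symmetry against rounding
  const <- apply(v, 1, sd) == 0
  mi[const, ] <- 0
  mi[, const] <- 0
  diag(mi) <- 0
  structure(mi, class = c("mi_matrix", "matrix"))
}
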