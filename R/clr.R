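#' Context likelihood of relatedness (CLR) background correction
#'
#' Corrects each MI value against the MI background of both genes: for gene
#' i, `z_i(j) = max(0, (MI_ij - mean_i) / sd_i)` where the mean and sample
#' standard deviation are taken over row i excluding the diagonal; the
#' combined score is `Z_ij = sqrt(z_i(j)^2 + z_j(i)^2)`. Rows with zero
#' background spread contribute z = 0.
#'
#' @param mi Symmetric nonnegative MI matrix (e.g. from [mi_matrix()]).
#' @return Symmetric nonnegative matrix of CLR z-composite scores with zero
#'   diagonal, class `clr_matrix`.
#' @export
clr_transform <- function(mi) {
  stopifnot(is.matrix(mi), is.numeric(mi))
  if (!isSymmetric(unclass(mi), tol = 1e-8)) stop("MI matrix must be symmetric")
  G <- nrow(mi)
  if (G < 3) stop("need at least 3 genes")
  mi <- unclass(mi)
  diag(mi) <- 0
  rmean <- rowSums(mi) / (G - 1)
  # sample sd of the G-1 off-diagonal row entries
  rvar <- (rowSums(mi^2) - (G - 1) * rmean^2) / (G - 2)
  rsd <- sqrt(pmax(rvar, 0))
  z <- (mi - rmean) / ifelse(rsd > 0, rsd, Inf)
  z[rsd == 0, ] <- 0
  z <- pmax(z, 0)
  diag(z) <- 0
  Z <- sqrt(z^2 + t(z)^2)
  diag(Z) <- 0
  dimnames(Z) <- dimnames(mi)
  structure(Z, class = c("clr_matrix", "matrix"))
}
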