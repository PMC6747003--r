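# Expression-matrix preprocessing: the pattern likelihoods assume traits on
# a standard-normal scale, so raw matrices are missingness-filtered, rank
# inverse-normal transformed per gene, and optionally residualized against
# top sample-space principal components.

#' Filter genes by non-missing fraction
#'
#' Keeps genes quantified in at least `min_fraction` of the samples
#' (default: half), preserving row order.
#'
#' @param mat Gene x sample numeric matrix (rownames = gene ids).
#' @param min_fraction Required non-missing fraction in `(0, 1]`.
#' @return The filtered matrix (possibly zero rows, with a warning).
#' @export
filter_by_missingness <- function(mat, min_fraction = 0.5) {
  stopifnot(is.matrix(mat), min_fraction > 0, min_fraction <= 1)
  frac <- rowMeans(!is.na(mat))
  keep <- frac >= min_fraction
  if (!any(keep)) warning("no genes pass the missingness filter")
  mat[keep, , drop = FALSE]
}

#' Rank-based inverse normal transform
#'
#' Maps non-missing values to `qnorm((rank - 0.5) / m)` where `m` is the
#' non-missing count and tied values receive average ranks. Missing entries
#' stay missing. The output depends on the input only through its ranks, so
#' any strictly monotone transform of the input yields identical output.
#'
#' @param x Numeric vector, possibly with missing values.
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  m <- sum(ok)
  if (m < 3L) stop("need at least 3 non-missing values")
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 0.5) / m)
  out
}

#' Remove top sample-space principal components
#'
#' Centers each gene, computes the top-`k` right singular vectors of the
#' gene-centered matrix (sample-space principal components), and returns the
#' residuals after projecting them out. `k = 0` returns the input unchanged.
#' Missing cells are mean-imputed for the decomposition only and restored to
#' missing in the output.
#'
#' @param mat Gene x sample numeric matrix.
#' @param k Number of components to remove; `0 <= k < ncol(mat)`.
#' @return Residual matrix (gene-centered for `k > 0`).
#' @export
remove_principal_components <- function(mat, k) {
  stopifnot(is.matrix(mat))
  if (k < 0 || k >= ncol(mat)) stop("k must satisfy 0 <= k < number of samples")
  if (k == 0) return(mat)
  na_mask <- is.na(mat)
  Xc <- mat - rowMeans(mat, na.rm = TRUE)
  Xc[na_mask] <- 0
  sv <- svd(Xc, nu = 0, nv = k)
  V <- sv$v[, seq_len(k), drop = FALSE]
  res <- Xc - (Xc %*% V) %*% t(V)
  res[na_mask] <- NA_real_
  dimnames(res) <- dimnames(mat)
  res
}

#' Standard preprocessing pipeline for one expression matrix
#'
#' Missingness filter, then per-gene rank inverse-normal transform, then
#' optional principal-component removal — in that order.
#'
#' @param mat Gene x sample numeric matrix.
#' @param min_fraction Missingness filter threshold (see
#'   [filter_by_missingness()]).
#' @param normalize Apply the inverse-normal transform per gene.
#' @param n_pcs Principal components to remove after normalization.
#' @return Preprocessed matrix.
#' @export
normalize_expression <- function(mat, min_fraction = 0.5, normalize = TRUE,
                                 n_pcs = 0L) {
  mat <- filter_by_missingness(mat, min_fraction)
  if (normalize && nrow(mat) > 0) {
    dn <- dimnames(mat)
    mat <- t(apply(mat, 1L, inverse_normal_transform))
    dimnames(mat) <- dn
  }
  remove_principal_components(mat, n_pcs)
}
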