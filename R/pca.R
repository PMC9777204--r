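# Principal component analysis via mean-centred SVD.

#' Fit a PCA model to a spectra matrix
#'
#' Mean-centres the rows-as-observations matrix and takes the thin
#' singular value decomposition. Loadings are returned as rows
#' (`n_pcs x n_wavenumbers`, orthonormal); scores are the centred data
#' projected on the loadings; explained variance fractions come from the
#' squared singular values. Loading signs are fixed so the largest-
#' magnitude element of each loading is positive (determinism only; PCA
#' is sign-indeterminate).
#'
#' @param X Numeric matrix (`n_spectra x n_wavenumbers`) or a
#'   `spectra_set`.
#' @param n_pcs Number of components, at most
#'   `min(n_spectra - 1, n_wavenumbers)`.
#' @return A `pca_model`: list with `mean_spectrum`, `loadings`,
#'   `scores`, `explained_variance`, `n_pcs`.
#' @export
fit_pca <- function(X, n_pcs) {
  if (inherits(X, "spectra_set")) X <- X$intensities
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n_pcs < 1L || n_pcs > min(n - 1L, p))
    stop("n_pcs must be between 1 and min(n_spectra - 1, n_wavenumbers) = ",
         min(n - 1L, p))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  if (all(abs(Xc) < 1e-12))
    stop("matrix is constant; PCA is undefined")
  sv <- svd(Xc)
  flip <- apply(sv$v[, seq_len(n_pcs), drop = FALSE], 2L,
                function(v) sign(v[which.max(abs(v))]))
  V <- sweep(sv$v[, seq_len(n_pcs), drop = FALSE], 2L, flip, `*`)
  structure(
    list(mean_spectrum = mu,
         loadings = t(V),
         scores = Xc %*% V,
         explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(n_pcs)],
         n_pcs = n_pcs),
    class = "pca_model")
}

#' Project new spectra into an existing PCA space
#'
#' @param pca A `pca_model`.
#' @param X Matrix of spectra (rows) on the model's axis, or a
#'   `spectra_set`.
#' @return Score matrix `n x n_pcs`.
#' @export
pca_project <- function(pca, X) {
  if (inherits(X, "spectra_set")) X <- X$intensities
  X <- rbind(X)  # promote a bare vector to a 1-row matrix
  if (ncol(X) != length(pca$mean_spectrum))
    stop("spectrum length (", ncol(X), ") does not match the model axis (",
         length(pca$mean_spectrum), ")")
  sweep(X, 2L, pca$mean_spectrum) %*% t(pca$loadings)
}
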