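# PCA-LDA: linear discriminant analysis in a truncated PCA score space.
#
# Classification uses the quadratic discriminant score
#   L_ik = (x_i - xbar_k)' S_pooled^{-1} (x_i - xbar_k) - 2 ln(pi_k),
# the squared Mahalanobis distance of a spectrum's PC scores to the
# class-k centroid under the pooled within-class covariance, penalised
# by the log prior; a spectrum is assigned to the class minimising L_ik.

#' Fit a PCA-LDA classifier
#'
#' @param x A `spectra_set`, or a numeric matrix of pre-processed
#'   spectra (rows = spectra).
#' @param labels Class labels when `x` is a matrix; ignored for a
#'   `spectra_set` (its `class_labels` are used).
#' @param n_pcs Number of principal components retained before LDA
#'   (study-size serum models conventionally use 10).
#' @param priors `"proportions"` (training class frequencies, default)
#'   or `"uniform"`.
#' @return A `pcalda_model`: the embedded `pca_model`, per-class mean
#'   score vectors (`class_means`, K x n_pcs), `pooled_covariance` and
#'   its inverse, `priors`, and `classes`.
#' @export
fit_pca_lda <- function(x, labels = NULL, n_pcs = 10,
                        priors = c("proportions", "uniform")) {
  priors <- match.arg(priors)
  if (inherits(x, "spectra_set")) {
    labels <- x$class_labels
    x <- x$intensities
  }
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  K <- nlevels(labels)
  if (K < 2L) stop("need at least 2 classes")
  nk <- tabulate(labels)
  if (any(nk < 2L))
    stop("every class needs at least 2 spectra; offending class: ",
         paste(levels(labels)[nk < 2L], collapse = ", "))
  pca <- fit_pca(x, n_pcs)
  S <- pca$scores
  n <- nrow(S)
  means <- t(sapply(levels(labels), function(k)
    colMeans(S[labels == k, , drop = FALSE])))
  pooled <- matrix(0, n_pcs, n_pcs)
  for (k in seq_len(K)) {
    D <- sweep(S[labels == levels(labels)[k], , drop = FALSE], 2L, means[k, ])
    pooled <- pooled + crossprod(D)
  }
  pooled <- pooled / (n - K)
  if (rcond(pooled) < 1e-12)
    stop("pooled covariance is (near-)singular; refit with fewer PCs")
  pk <- if (priors == "uniform") rep(1 / K, K) else nk / n
  structure(
    list(pca = pca,
         class_means = means,
         pooled_covariance = pooled,
         pooled_inverse = solve(pooled),
         priors = stats::setNames(pk, levels(labels)),
         n_per_class = stats::setNames(nk, levels(labels)),
         classes = levels(labels),
         n_pcs = n_pcs),
    class = "pcalda_model")
}

#' Quadratic PCA-LDA discriminant scores and class assignment
#'
#' Computes, for each spectrum and each class, the Mahalanobis-plus-
#' log-prior score (smaller = closer), and assigns the arg-min class.
#' Exact ties are broken in favour of the first class in the model's
#' class order, with a warning.
#'
#' @param model A `pcalda_model`.
#' @param x A pre-processed spectrum (vector), matrix of spectra, or
#'   `spectra_set` on the model's axis.
#' @return List with `scores` (n x K matrix of L_ik) and
#'   `assigned_class` (factor).
#' @export
pca_lda_score <- function(model, x) {
  S <- pca_project(model$pca, x)
  K <- length(model$classes)
  L <- matrix(NA_real_, nrow(S), K, dimnames = list(NULL, model$classes))
  for (k in seq_len(K)) {
    D <- sweep(S, 2L, model$class_means[k, ])
    L[, k] <- rowSums((D %*% model$pooled_inverse) * D) -
      2 * log(model$priors[k])
  }
  best <- apply(L, 1L, function(r) {
    w <- which(r == min(r))
    if (length(w) > 1L)
      warning("tied discriminant scores; assigning first class in order")
    w[1L]
  })
  list(scores = L,
       assigned_class = factor(model$classes[best], levels = model$classes))
}

#' @export
predict.pcalda_model <- function(object, newdata, ...) {
  pca_lda_score(object, newdata)$assigned_class
}

#' One-dimensional (or few-axis) LDA discriminant projection
#'
#' Projects PC scores onto the leading generalized eigenvectors of the
#' between-class vs pooled within-class scatter -- the canonical
#' discriminant axes used for score plots and box plots. A K-class
#' problem has at most K - 1 axes.
#'
#' @param model A `pcalda_model`.
#' @param x Optional new spectra (`spectra_set`, matrix or vector); the
#'   training scores are projected when omitted.
#' @param n_axes Number of discriminant axes to return (capped at K - 1).
#' @return Numeric matrix `n x n_axes` of discriminant scores.
#' @export
lda_projection <- function(model, x = NULL, n_axes = 1L) {
  K <- length(model$classes)
  n_axes <- min(n_axes, K - 1L)
  S <- model$pca$scores
  # between-class scatter of centroids about the grand mean
  nk <- model$n_per_class
  gm <- colMeans(S)
  B <- matrix(0, ncol(S), ncol(S))
  for (k in seq_len(K)) {
    d <- model$class_means[k, ] - gm
    B <- B + nk[k] * tcrossprod(d)
  }
  e <- eigen(model$pooled_inverse %*% B)
  A <- Re(e$vectors[, seq_len(n_axes), drop = FALSE])
  A <- apply(A, 2L, function(v) {
    v <- v / sqrt(sum(v^2))
    v * sign(v[which.max(abs(v))])
  })
  A <- matrix(A, ncol = n_axes)
  scores <- if (is.null(x)) S else pca_project(model$pca, x)
  scores %*% A
}
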