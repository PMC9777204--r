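# PLS-DA: latent-variable regression of class-indicator codes on the
# spectra, prediction yhat = X b. Two classes are coded as a single 0/1
# column (second class level = 1) with a 0.5 decision threshold; K > 2
# classes use one indicator column per class and arg-max assignment.
# X and Y are mean-centred inside the fit; the intercept implied by the
# centring is restored at prediction.

# NIPALS PLS2. Returns weights W, X-loadings P, Y-loadings Q (columns =
# components) computed on centred X, Y.
nipals_pls <- function(Xc, Yc, n_lvs, tol = 1e-10, max_iter = 500L) {
  W <- matrix(0, ncol(Xc), n_lvs)
  P <- matrix(0, ncol(Xc), n_lvs)
  Q <- matrix(0, ncol(Yc), n_lvs)
  for (a in seq_len(n_lvs)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    w <- t_ <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, u)
      w <- w / sqrt(sum(w^2))
      t_ <- Xc %*% w
      q <- crossprod(Yc, t_) / sum(t_^2)
      u_new <- Yc %*% q / sum(q^2)
      if (sqrt(sum((u_new - u)^2)) < tol * sqrt(sum(u_new^2)) || it == max_iter) {
        u <- u_new
        break
      }
      u <- u_new
    }
    tt <- sum(t_^2)
    if (tt < 1e-12)
      stop("latent variable ", a, " has no remaining X variance; ",
           "n_lvs exceeds the rank of the training matrix")
    p <- crossprod(Xc, t_) / tt
    q <- crossprod(Yc, t_) / tt
    Xc <- Xc - t_ %*% t(p)
    Yc <- Yc - t_ %*% t(q)
    W[, a] <- w; P[, a] <- p; Q[, a] <- q
  }
  list(W = W, P = P, Q = Q)
}

#' Fit a PLS-DA classifier
#'
#' @param X Numeric matrix of pre-processed spectra (rows), or a
#'   `spectra_set`.
#' @param labels Class labels (ignored for a `spectra_set`).
#' @param n_lvs Number of latent variables; must not exceed the rank of
#'   the centred training matrix. Serum two-class models here default to
#'   6 and four-group models to 8 in the worked analyses.
#' @return A `plsda_model` with the regression matrix `b`
#'   (`n_wavenumbers x n_codes`), centring terms, the class coding and
#'   the decision rule (`threshold-0.5` for 2 classes, `argmax`
#'   otherwise).
#' @export
fit_plsda <- function(X, labels = NULL, n_lvs) {
  if (inherits(X, "spectra_set")) {
    labels <- X$class_labels
    X <- X$intensities
  }
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  K <- nlevels(labels)
  if (K < 2L) stop("need at least 2 classes")
  if (n_lvs < 1L) stop("n_lvs must be >= 1")
  Y <- if (K == 2L) {
    matrix(as.numeric(labels == levels(labels)[2L]), ncol = 1L,
           dimnames = list(NULL, levels(labels)[2L]))
  } else {
    sapply(levels(labels), function(k) as.numeric(labels == k))
  }
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2L, x_mean)
  r <- qr(Xc)$rank
  if (n_lvs > r)
    stop("n_lvs (", n_lvs, ") exceeds the rank of the centred training ",
         "matrix (", r, ")")
  fit <- nipals_pls(Xc, sweep(Y, 2L, y_mean), n_lvs)
  # regression coefficients: b = W (P'W)^{-1} Q'
  b <- fit$W %*% solve(crossprod(fit$P, fit$W), t(fit$Q))
  colnames(b) <- colnames(Y)
  structure(
    list(b = b, x_mean = x_mean, y_mean = y_mean,
         classes = levels(labels), n_lvs = n_lvs,
         decision_rule = if (K == 2L) "threshold-0.5" else "argmax"),
    class = "plsda_model")
}

#' Predicted PLS-DA response and class assignment
#'
#' The response is `yhat = X b` on centred data with the intercept
#' restored. Two-class rule: assign the positive (second) class iff
#' `yhat >= 0.5`; a response of exactly 0.5 goes to the positive class
#' with a warning. Multiclass rule: arg-max over indicator columns,
#' ties to the first class in order with a warning.
#'
#' @param model A `plsda_model`.
#' @param x Spectrum vector, matrix of spectra, or `spectra_set` on the
#'   model's axis.
#' @return List with `response` (n x n_codes matrix of yhat) and
#'   `assigned_class` (factor).
#' @export
plsda_predict <- function(model, x) {
  if (inherits(x, "spectra_set")) x <- x$intensities
  x <- rbind(x)
  if (ncol(x) != length(model$x_mean))
    stop("spectrum length (", ncol(x), ") does not match the model axis (",
         length(model$x_mean), ")")
  yhat <- sweep(x, 2L, model$x_mean) %*% model$b
  yhat <- sweep(yhat, 2L, model$y_mean, `+`)
  if (model$decision_rule == "threshold-0.5") {
    if (any(yhat == 0.5))
      warning("predicted response exactly 0.5; assigning positive class")
    cls <- ifelse(yhat[, 1L] >= 0.5, model$classes[2L], model$classes[1L])
  } else {
    idx <- apply(yhat, 1L, function(r) {
      w <- which(r == max(r))
      if (length(w) > 1L)
        warning("tied predicted responses; assigning first class in order")
      w[1L]
    })
    cls <- model$classes[idx]
  }
  list(response = yhat,
       assigned_class = factor(cls, levels = model$classes))
}

#' @export
predict.plsda_model <- function(object, newdata, ...) {
  plsda_predict(object, newdata)$assigned_class
}
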