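test_that("PCA recovers rank-1 structure and reconstructs at full rank", {
  set.seed(7)
  v <- vector_normalise(rnorm(30))
  X1 <- outer(rnorm(12), v)                   # single direction
  p1 <- fit_pca(X1, 1)
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-10)
  X <- matrix(rnorm(20 * 50), 20, 50)
  r <- 19                                      # rank of centred 20 x 50
  p <- fit_pca(X, r)
  expect_equal(p$loadings %*% t(p$loadings), diag(r), tolerance = 1e-8)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(p$scores %*% p$loadings, Xc, tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_error(fit_pca(X, 25), "n_pcs")
  expect_error(fit_pca(matrix(1, 5, 4), 2), "constant")
})

test_that("PCA loadings match brute-force covariance eigenvectors up to sign", {
  set.seed(8)
  X <- matrix(rnorm(15 * 8), 15, 8)
  p <- fit_pca(X, 4)
  ev <- eigen(cov(X))$vectors[, 1:4]
  for (j in 1:4) {
    dot <- abs(sum(p$loadings[j, ] * ev[, j]))
    expect_equal(dot, 1, tolerance = 1e-8)
  }
})

test_that("PCA-LDA pooled covariance equals the direct-sum oracle", {
  s <- tiny_set(n_per_class = 6, seed = 9)
  m <- fit_pca_lda(s, n_pcs = 3)
  S <- m$pca$scores
  lab <- s$class_labels
  acc <- matrix(0, 3, 3)
  for (k in levels(lab)) {
    Sk <- S[lab == k, , drop = FALSE]
    mk <- colMeans(Sk)
    for (i in seq_len(nrow(Sk)))
      acc <- acc + tcrossprod(Sk[i, ] - mk)
  }
  expect_equal(m$pooled_covariance, acc / (nrow(S) - 2), tolerance = 1e-10)
  expect_equal(sum(m$priors), 1)
  # class means separate along the shifted-band structure
  expect_gt(sum((m$class_means[1, ] - m$class_means[2, ])^2), 0)
})

test_that("PCA-LDA refuses single-spectrum classes", {
  s <- tiny_set(n_per_class = 4)
  s$class_labels <- factor(c("A", rep("B", 7)))
  expect_error(fit_pca_lda(s, n_pcs = 2), "at least 2 spectra")
})

test_that("discriminant score at the class mean reduces to the prior term", {
  # hand-built 2-PC model: identity covariance, priors 0.5/0.5
  m <- structure(list(
    pca = structure(list(mean_spectrum = c(0, 0),
                         loadings = diag(2), scores = NULL, n_pcs = 2),
                    class = "pca_model"),
    class_means = rbind(A = c(1, 2), B = c(-1, 0)),
    pooled_covariance = diag(2), pooled_inverse = diag(2),
    priors = c(A = 0.5, B = 0.5), n_per_class = c(A = 5, B = 5),
    classes = c("A", "B"), n_pcs = 2), class = "pcalda_model")
  sc <- pca_lda_score(m, c(1, 2))
  expect_equal(unname(sc$scores[1, "A"]), -2 * log(0.5),
               tolerance = 1e-12)
  expect_equal(as.character(sc$assigned_class), "A")
})

test_that("Eq.-1 scores match hand arithmetic with a 2x2 inverse", {
  # pooled covariance [[2, 0.5], [0.5, 1]], inverted analytically
  S <- rbind(c(2, 0.5), c(0.5, 1))
  det_s <- 2 * 1 - 0.5 * 0.5
  Sinv <- rbind(c(1, -0.5), c(-0.5, 2)) / det_s
  m <- structure(list(
    pca = structure(list(mean_spectrum = c(0, 0), loadings = diag(2),
                         scores = NULL, n_pcs = 2), class = "pca_model"),
    class_means = rbind(A = c(0, 0), B = c(3, 1)),
    pooled_covariance = S, pooled_inverse = solve(S),
    priors = c(A = 0.25, B = 0.75), n_per_class = c(A = 2, B = 6),
    classes = c("A", "B"), n_pcs = 2), class = "pcalda_model")
  x <- c(1, -1)
  sc <- pca_lda_score(m, x)
  manual_A <- drop(t(x - c(0, 0)) %*% Sinv %*% (x - c(0, 0))) -
    2 * log(0.25)
  manual_B <- drop(t(x - c(3, 1)) %*% Sinv %*% (x - c(3, 1))) -
    2 * log(0.75)
  expect_equal(unname(sc$scores[1, ]), c(manual_A, manual_B),
               tolerance = 1e-10)
})

test_that("equal priors and spherical covariance give nearest-centroid rule", {
  set.seed(15)
  for (i in 1:5) {
    mu <- matrix(rnorm(6, sd = 3), 2, 3)
    m <- structure(list(
      pca = structure(list(mean_spectrum = rep(0, 3), loadings = diag(3),
                           scores = NULL, n_pcs = 3), class = "pca_model"),
      class_means = mu, pooled_covariance = diag(3),
      pooled_inverse = diag(3), priors = c(0.5, 0.5),
      n_per_class = c(4, 4), classes = c("c1", "c2"), n_pcs = 3),
      class = "pcalda_model")
    x <- matrix(rnorm(30, sd = 3), 10, 3)
    got <- pca_lda_score(m, x)$assigned_class
    nearest <- apply(x, 1, function(z)
      c("c1", "c2")[which.min(c(sum((z - mu[1, ])^2),
                                sum((z - mu[2, ])^2)))])
    expect_identical(as.character(got), nearest)
  }
})

test_that("Eq.-1 scores are invariant under linear re-parameterisation", {
  set.seed(16)
  S <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  mu <- rbind(rnorm(3), rnorm(3))
  mk_model <- function(means, cov_) structure(list(
    pca = structure(list(mean_spectrum = rep(0, 3), loadings = diag(3),
                         scores = NULL, n_pcs = 3), class = "pca_model"),
    class_means = means, pooled_covariance = cov_,
    pooled_inverse = solve(cov_), priors = c(0.3, 0.7),
    n_per_class = c(3, 7), classes = c("a", "b"), n_pcs = 3),
    class = "pcalda_model")
  x <- matrix(rnorm(15), 5, 3)
  base <- pca_lda_score(mk_model(mu, S), x)$scores
  A <- matrix(rnorm(9), 3, 3) + diag(3) * 2     # invertible w.h.p.
  trans <- pca_lda_score(mk_model(mu %*% t(A), A %*% S %*% t(A)),
                         x %*% t(A))$scores
  expect_equal(base, trans, tolerance = 1e-8)
})

test_that("LDA projection yields K-1 axes and beats any single PC", {
  s <- small_cohort(seed = 21)
  pp <- preprocess(s)
  m <- fit_pca_lda(pp, n_pcs = 5)
  pr <- lda_projection(m)
  expect_equal(ncol(pr), 1L)                     # 2 classes -> 1 axis
  fisher_1d <- function(v, lab) {
    ms <- tapply(v, lab, mean)
    vs <- tapply(v, lab, var)
    (ms[1] - ms[2])^2 / sum(vs)
  }
  lab <- pp$class_labels
  f_lda <- fisher_1d(pr[, 1], lab)
  for (j in 1:5)
    expect_gte(f_lda, fisher_1d(m$pca$scores[, j], lab) - 1e-8)
  # 4 groups -> up to 3 axes
  s4 <- default_four_group(seed = 3)
  m4 <- fit_pca_lda(preprocess(s4), n_pcs = 6)
  expect_equal(ncol(lda_projection(m4, n_axes = 5)), 3L)
})

test_that("full-rank PLS-DA reproduces least squares", {
  set.seed(23)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rep(c(0, 1), each = 10)
  m <- fit_plsda(X, factor(rep(c("n", "p"), each = 10)), n_lvs = 10)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  pred_pls <- plsda_predict(m, X)$response[, 1]
  pred_ols <- drop(cbind(1, X) %*% ols)
  expect_equal(pred_pls, pred_ols, tolerance = 1e-8)
})

test_that("single-LV regression vector is proportional to cov(X, y)", {
  set.seed(24)
  X <- matrix(rnorm(30 * 6), 30, 6)
  lab <- factor(rep(c("n", "p"), 15))
  y <- as.numeric(lab == "p")
  m <- fit_plsda(X, lab, n_lvs = 1)
  cv <- drop(crossprod(sweep(X, 2, colMeans(X)), y - mean(y)))
  # b = w * q with w = cov direction: collinearity check
  cosang <- sum(m$b[, 1] * cv) / sqrt(sum(m$b^2) * sum(cv^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-10)
})

test_that("PLS-DA rejects rank-deficient requests and zero matrices", {
  X0 <- matrix(0, 8, 5)
  expect_error(fit_plsda(X0, factor(rep(c("a", "b"), 4)), n_lvs = 1),
               "rank")
  set.seed(25)
  X <- matrix(rnorm(6 * 10), 6, 10)
  expect_error(fit_plsda(X, factor(rep(c("a", "b"), 3)), n_lvs = 6),
               "rank")
})

test_that("binary threshold rule and multiclass argmax behave at the edges", {
  set.seed(26)
  X <- rbind(matrix(rnorm(20, mean = 0, sd = 0.1), 10, 2),
             matrix(rnorm(20, mean = 3, sd = 0.1), 10, 2))
  lab <- factor(rep(c("lo", "hi"), each = 10), levels = c("lo", "hi"))
  m <- fit_plsda(X, lab, n_lvs = 2)
  # a spectrum at a training class mean predicts near that indicator
  r_hi <- plsda_predict(m, colMeans(X[11:20, ]))$response[1, 1]
  expect_equal(r_hi, 1, tolerance = 0.05)
  expect_equal(as.character(plsda_predict(m, colMeans(X[1:10, ]))$assigned_class),
               "lo")
  # exact 0.5 goes to the positive class with a warning
  m2 <- m; m2$b[] <- 0; m2$y_mean <- 0.5
  expect_warning(p0 <- plsda_predict(m2, c(1, 1)), "0.5")
  expect_equal(as.character(p0$assigned_class), "hi")
  # four groups assign by argmax column
  s4 <- preprocess(default_four_group(seed = 6))
  m4 <- fit_plsda(s4, n_lvs = 8)
  pr4 <- plsda_predict(m4, s4)
  idx <- apply(pr4$response, 1, which.max)
  expect_identical(as.character(pr4$assigned_class),
                   m4$classes[idx])
})
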