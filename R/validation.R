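# Model validation: confusion tables, accuracy/sensitivity/specificity,
# Monte Carlo cross-validation, and ANOVA/MANOVA on discriminant scores.

#' Build a K x K confusion table
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param truth,predicted Factors (or vectors) on the same class set.
#' @param classes Optional explicit class ordering.
#' @return Integer matrix with row sums equal to the true class counts.
#' @export
confusion_table <- function(truth, predicted, classes = NULL) {
  if (is.null(classes))
    classes <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  truth <- factor(truth, levels = classes)
  predicted <- factor(predicted, levels = classes)
  unclass(table(truth = truth, predicted = predicted))
}

one_vs_rest_counts <- function(tab, k) {
  tp <- tab[k, k]
  fn <- sum(tab[k, ]) - tp
  fp <- sum(tab[, k]) - tp
  tn <- sum(tab) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

ratio_pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Accuracy, sensitivity and specificity of a confusion table
#'
#' For a K x K table the accuracy is the trace over the total (micro
#' accuracy); sensitivity and specificity are computed per class
#' one-vs-rest as `TP/(TP+FN)` and `TN/(TN+FP)` (in percent), with the
#' unweighted class means reported as `mean_sensitivity` /
#' `mean_specificity`. Ratios with a zero denominator are reported as
#' `NA`, never as 0.
#'
#' @param tab Confusion matrix from [confusion_table] (or any K x K
#'   numeric matrix, rows = truth).
#' @return List with `accuracy`, per-class `sensitivity` and
#'   `specificity` (named vectors), and their unweighted means, all in
#'   percent.
#' @export
classification_metrics <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) stop("all-zero confusion table")
  classes <- rownames(tab)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(tab)))
  sens <- spec <- stats::setNames(numeric(length(classes)), classes)
  for (k in seq_along(classes)) {
    cnt <- one_vs_rest_counts(tab, k)
    sens[k] <- ratio_pct(cnt["TP"], cnt["TP"] + cnt["FN"])
    spec[k] <- ratio_pct(cnt["TN"], cnt["TN"] + cnt["FP"])
  }
  list(accuracy = 100 * sum(diag(tab)) / sum(tab),
       sensitivity = sens,
       specificity = spec,
       mean_sensitivity = mean(sens),
       mean_specificity = mean(spec))
}

fit_and_predict <- function(train_X, train_labels, test_X,
                            model = c("plsda", "pcalda"), n_components) {
  model <- match.arg(model)
  if (model == "plsda") {
    m <- fit_plsda(train_X, train_labels, n_lvs = n_components)
    plsda_predict(m, test_X)$assigned_class
  } else {
    m <- fit_pca_lda(train_X, train_labels, n_pcs = n_components)
    pca_lda_score(m, test_X)$assigned_class
  }
}

stratified_holdout <- function(labels, subject_ids, test_fraction,
                               split_level) {
  test <- logical(length(labels))
  for (k in levels(labels)) {
    in_k <- which(labels == k)
    if (split_level == "spectrum") {
      n_test <- max(1L, round(test_fraction * length(in_k)))
      test[sample(in_k, n_test)] <- TRUE
    } else {
      subj <- unique(subject_ids[in_k])
      n_test <- max(1L, round(test_fraction * length(subj)))
      if (n_test >= length(subj))
        stop("class ", k, " has too few subjects for a subject-level split")
      hold <- sample(subj, n_test)
      test[in_k[subject_ids[in_k] %in% hold]] <- TRUE
    }
  }
  test
}

#' Monte Carlo cross-validation of a spectral classifier
#'
#' Repeats, `n_iter` times: draw a stratified random hold-out of
#' `test_fraction` of the data (per class, so no class can vanish from
#' either side), fit the chosen classifier on the remainder, predict
#' the hold-out, and accumulate the confusion table. Means of the
#' per-iteration accuracy, per-class sensitivity/specificity and of the
#' confusion tables are reported. `split_level = "spectrum"` draws
#' individual spectra (replicates of one subject may straddle the
#' split, which is optimistic when replicates are highly correlated);
#' `"subject"` holds out whole subjects.
#'
#' @param set A pre-processed `spectra_set`.
#' @param model `"plsda"` or `"pcalda"`.
#' @param n_components Latent variables (PLS-DA) or principal
#'   components (PCA-LDA).
#' @param n_iter Number of Monte Carlo iterations (default 1000).
#' @param test_fraction Fraction held out per iteration (default 0.2).
#' @param split_level `"spectrum"` (default) or `"subject"`.
#' @param seed Optional integer seed; the run is reproducible given it.
#' @return A `cv_result`: mean metrics (percent), mean confusion table,
#'   and the per-iteration metric matrix.
#' @export
monte_carlo_cv <- function(set, model = c("plsda", "pcalda"), n_components,
                           n_iter = 1000L, test_fraction = 0.2,
                           split_level = c("spectrum", "subject"),
                           seed = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  model <- match.arg(model)
  split_level <- match.arg(split_level)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  labels <- droplevels(set$class_labels)
  K <- nlevels(labels)
  classes <- levels(labels)
  X <- set$intensities
  acc <- numeric(n_iter)
  sens <- spec <- matrix(NA_real_, n_iter, K, dimnames = list(NULL, classes))
  tab_sum <- matrix(0, K, K, dimnames = list(classes, classes))
  for (it in seq_len(n_iter)) {
    test <- stratified_holdout(labels, set$subject_ids, test_fraction,
                               split_level)
    pred <- fit_and_predict(X[!test, , drop = FALSE],
                            labels[!test],
                            X[test, , drop = FALSE],
                            model, n_components)
    tab <- confusion_table(labels[test], pred, classes)
    m <- classification_metrics(tab)
    acc[it] <- m$accuracy
    sens[it, ] <- m$sensitivity
    spec[it, ] <- m$specificity
    tab_sum <- tab_sum + tab
  }
  structure(
    list(model = model, n_components = n_components,
         n_iter = n_iter, test_fraction = test_fraction,
         split_level = split_level,
         accuracy = mean(acc),
         sensitivity = colMeans(sens, na.rm = TRUE),
         specificity = colMeans(spec, na.rm = TRUE),
         mean_sensitivity = mean(colMeans(sens, na.rm = TRUE)),
         mean_specificity = mean(colMeans(spec, na.rm = TRUE)),
         mean_confusion = tab_sum / n_iter,
         per_iteration = list(accuracy = acc, sensitivity = sens,
                              specificity = spec)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Monte Carlo CV: %s (%d components), %d iterations, %.0f%% out (%s-level)\n",
              x$model, x$n_components, x$n_iter, 100 * x$test_fraction,
              x$split_level))
  cat(sprintf("mean accuracy: %.2f%%\n", x$accuracy))
  for (k in names(x$sensitivity))
    cat(sprintf("  %s: sensitivity %.2f%%, specificity %.2f%%\n",
                k, x$sensitivity[k], x$specificity[k]))
  cat("mean confusion table (rows = truth):\n")
  print(round(x$mean_confusion, 2))
  invisible(x)
}

#' One-way ANOVA on 1-D discriminant scores
#'
#' @param scores Numeric vector of per-spectrum discriminant scores.
#' @param labels Group labels (>= 2 groups of >= 2).
#' @return List with `F` and `p`.
#' @export
score_anova <- function(scores, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L || any(tabulate(labels) < 2L))
    stop("score_anova needs >= 2 groups with >= 2 scores each")
  a <- stats::anova(stats::lm(scores ~ labels))
  list(F = a[["F value"]][1L], p = a[["Pr(>F)"]][1L])
}

#' Wilks-lambda MANOVA on multi-axis discriminant scores
#'
#' With a single axis this reduces to the one-way ANOVA F test.
#'
#' @param scores Numeric matrix (n x n_axes) of discriminant scores.
#' @param labels Group labels.
#' @return List with `statistic` (Wilks lambda; for 1 axis the ANOVA F),
#'   `F` approximation and `p`.
#' @export
score_manova <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- droplevels(as.factor(labels))
  if (ncol(scores) == 1L) {
    a <- score_anova(scores[, 1L], labels)
    return(list(statistic = a$F, F = a$F, p = a$p))
  }
  fit <- stats::manova(scores ~ labels)
  s <- summary(fit, test = "Wilks")$stats
  list(statistic = s["labels", "Wilks"],
       F = s["labels", "approx F"],
       p = s["labels", "Pr(>F)"])
}
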