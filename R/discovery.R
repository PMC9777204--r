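# Cluster-vector discovery of discriminatory wavenumbers.
#
# The cluster vector of a class is the sum of three PCA loading vectors
# weighted by that class's median scores on those PCs -- a
# "loadings-like" spectrum pointing from the PCA origin through the
# class cluster. The disease-minus-control difference of cluster
# vectors concentrates its extrema at the wavenumbers that drive class
# separation; ranking those extrema yields candidate spectral markers.

fisher_criterion <- function(S, labels) {
  # trace(Sw^-1 Sb) of the projected scores S (columns = chosen PCs)
  classes <- levels(labels)
  gm <- colMeans(S)
  Sw <- matrix(0, ncol(S), ncol(S))
  Sb <- matrix(0, ncol(S), ncol(S))
  for (k in classes) {
    Sk <- S[labels == k, , drop = FALSE]
    mk <- colMeans(Sk)
    Sw <- Sw + crossprod(sweep(Sk, 2L, mk))
    Sb <- Sb + nrow(Sk) * tcrossprod(mk - gm)
  }
  if (rcond(Sw) < 1e-12) return(Inf)
  sum(diag(solve(Sw, Sb)))
}

#' Select the PC triplet with the best class separation
#'
#' Exhaustively scores every 3-combination of the model's PCs with a
#' Fisher criterion (trace of within-scatter-inverse times
#' between-scatter of the 3-D score projection) and returns the arg-max.
#' Ties go to the lexicographically first triplet.
#'
#' @param pca A `pca_model` with >= 3 PCs.
#' @param labels Class labels, one per training spectrum.
#' @return Integer vector of 3 distinct PC indices (ascending).
#' @export
select_pc_triplet <- function(pca, labels) {
  labels <- droplevels(as.factor(labels))
  if (pca$n_pcs < 3L) stop("need at least 3 PCs to pick a triplet")
  combos <- utils::combn(pca$n_pcs, 3L)
  crit <- apply(combos, 2L, function(ix)
    fisher_criterion(pca$scores[, ix, drop = FALSE], labels))
  combos[, which.max(crit)]
}

#' Cluster vectors and their disease-minus-control contrast
#'
#' @param pca A `pca_model` fitted to the pre-processed spectra.
#' @param labels Class labels for the training spectra.
#' @param triplet Three distinct PC indices (e.g. from
#'   [select_pc_triplet]).
#' @param control Label of the control class (default first factor
#'   level).
#' @param disease Label of the disease class; defaults to the only
#'   other class and must be given when there are more than two.
#' @return A `cluster_vector_result`: `per_class_vectors` (one row per
#'   class over wavenumbers), `contrast_vector` (disease minus
#'   control), `pc_triplet`, and the class roles.
#' @export
cluster_vectors <- function(pca, labels, triplet, control = NULL,
                            disease = NULL) {
  labels <- droplevels(as.factor(labels))
  stopifnot(length(triplet) == 3L, !anyDuplicated(triplet),
            all(triplet >= 1L & triplet <= pca$n_pcs))
  classes <- levels(labels)
  if (is.null(control)) control <- classes[1L]
  if (!control %in% classes) stop("unknown control class: ", control)
  if (is.null(disease)) {
    rest <- setdiff(classes, control)
    if (length(rest) != 1L)
      stop("disease class must be named when there are > 2 classes")
    disease <- rest
  }
  if (!disease %in% classes) stop("unknown disease class: ", disease)
  V <- t(sapply(classes, function(k) {
    med <- apply(pca$scores[labels == k, triplet, drop = FALSE], 2L,
                 stats::median)
    colSums(med * pca$loadings[triplet, , drop = FALSE])
  }))
  structure(
    list(per_class_vectors = V,
         contrast_vector = V[disease, ] - V[control, ],
         pc_triplet = as.integer(triplet),
         control = control, disease = disease),
    class = "cluster_vector_result")
}

#' Top discriminatory peaks of a cluster-vector contrast
#'
#' Local extrema of the absolute contrast vector, ranked by magnitude,
#' greedily thinned so that retained peaks are at least `min_separation`
#' apart (a broad band then occupies one slot, not several).
#'
#' @param result A `cluster_vector_result`, or a numeric contrast
#'   vector (then `wavenumbers` is required).
#' @param wavenumbers Axis for the contrast vector.
#' @param n Maximum number of peaks to return (default 12).
#' @param min_separation Minimum pairwise distance in cm^-1 (default
#'   10).
#' @return Data frame with `wavenumber`, `magnitude` (signed contrast
#'   value), `direction` (`"up"` if the disease class is higher), sorted
#'   by `abs(magnitude)` descending. Zero rows for a flat contrast.
#' @export
top_peaks <- function(result, wavenumbers, n = 12L, min_separation = 10) {
  v <- if (inherits(result, "cluster_vector_result"))
    result$contrast_vector else as.numeric(result)
  if (n < 1L) stop("n must be >= 1")
  stopifnot(length(v) == length(wavenumbers))
  a <- abs(v)
  m <- length(a)
  # local maxima: strictly above the left neighbour (endpoints: strictly
  # above the only neighbour), at least level to the right -- so a flat
  # vector has no peaks and a plateau contributes its first point
  left <- c(a[2L], a[-m])
  right <- c(a[-1L], a[m - 1L])
  cand <- which(a > left & a >= right & a > 0)
  empty <- data.frame(wavenumber = numeric(0), magnitude = numeric(0),
                      direction = character(0))
  if (length(cand) == 0L) return(empty)
  cand <- cand[order(a[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(wavenumbers[i] - wavenumbers[keep]) >= min_separation))
      keep <- c(keep, i)
    if (length(keep) == n) break
  }
  data.frame(wavenumber = wavenumbers[keep],
             magnitude = v[keep],
             direction = ifelse(v[keep] > 0, "up", "down"))
}

#' Per-peak intensity statistics across classes
#'
#' One-way ANOVA of the pre-processed intensity at each requested
#' wavenumber (nearest axis point) across the class labels, with the
#' disease-vs-control direction of the mean difference.
#'
#' @param set A pre-processed `spectra_set` (every class >= 2 spectra).
#' @param peaks Wavenumbers of interest (cm^-1).
#' @param control Control class label (default first factor level).
#' @param disease Disease class label (default: remaining class for two
#'   classes; otherwise required for directions).
#' @param p_adjust Multiplicity correction passed to
#'   [stats::p.adjust()]; default `"none"` (raw per-peak p values).
#' @return Data frame with one row per peak: `wavenumber` (nearest axis
#'   point), per-class means and SDs, `F`, `p`, `direction`.
#' @export
peak_stats <- function(set, peaks, control = NULL, disease = NULL,
                       p_adjust = "none") {
  stopifnot(inherits(set, "spectra_set"))
  labels <- droplevels(set$class_labels)
  if (any(tabulate(labels) < 2L))
    stop("every class needs >= 2 spectra for the ANOVA")
  classes <- levels(labels)
  if (is.null(control)) control <- classes[1L]
  if (is.null(disease) && length(classes) == 2L)
    disease <- setdiff(classes, control)
  rows <- lapply(peaks, function(w) {
    i <- which.min(abs(set$wavenumbers - w))
    y <- set$intensities[, i]
    a <- stats::anova(stats::lm(y ~ labels))
    mns <- tapply(y, labels, mean)
    sds <- tapply(y, labels, stats::sd)
    out <- data.frame(wavenumber = set$wavenumbers[i],
                      F = a[["F value"]][1L],
                      p = a[["Pr(>F)"]][1L])
    for (k in classes) {
      out[[paste0("mean_", k)]] <- mns[[k]]
      out[[paste0("sd_", k)]] <- sds[[k]]
    }
    out$direction <- if (!is.null(disease))
      ifelse(mns[[disease]] > mns[[control]], "up", "down") else NA_character_
    out
  })
  res <- do.call(rbind, rows)
  res$p <- stats::p.adjust(res$p, method = p_adjust)
  res
}
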