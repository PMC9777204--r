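# Shared fixtures and independent oracles, all built in code.

# A tiny deterministic spectra set: n spectra of pure Gaussian bands on
# a short axis, two classes, two subjects per class.
tiny_set <- function(n_per_class = 4, seed = 1, axis = seq(900, 1100, by = 4)) {
  set.seed(seed)
  n <- 2 * n_per_class
  bands <- function(shift) {
    1 + 0.5 * exp(-(axis - 950)^2 / 200) +
      (0.8 + shift) * exp(-(axis - 1050)^2 / 300)
  }
  X <- t(sapply(seq_len(n), function(i) {
    shift <- if (i > n_per_class) 0.3 else 0
    bands(shift) + rnorm(length(axis), 0, 0.01)
  }))
  spectra_set(axis, X,
              spectrum_ids = sprintf("s%02d", seq_len(n)),
              subject_ids = rep(sprintf("subj%d", 1:4),
                                each = n_per_class / 2)[seq_len(n)],
              class_labels = rep(c("A", "B"), each = n_per_class))
}

# Small two-class cohort from the package generator (fast preprocessed
# version for CV tests).
small_cohort <- function(seed = 3, reps = 8L, shift_multiple = 3) {
  lib <- serum_band_library()
  r <- ramanclass:::disease_shifts(shift_multiple * 0.02, lib)
  shifts <- rbind(HC = rep(0, nrow(lib)), SLE = r)
  design <- cohort_design(list(
    list(label = "HC", subjects = paste0("H", 1:3),
         replicates = rep(reps, 3)),
    list(label = "SLE", subjects = paste0("S", 1:3),
         replicates = rep(reps, 3))))
  generate_cohort(design, effect_spec(lib, shifts, base_bands = lib[0, ]),
                  seed = seed)
}

# O(n^2)-per-point chord oracle for the lower convex-hull envelope:
# the greatest convex minorant at x_i is the minimum over all chords
# (j <= i <= k) of the interpolated chord value at x_i.
chord_oracle_baseline <- function(x, y) {
  n <- length(x)
  sapply(seq_len(n), function(i) {
    best <- y[i]
    for (j in seq_len(i)) {
      for (k in i:n) {
        if (j == k) next
        v <- y[j] + (y[k] - y[j]) * (x[i] - x[j]) / (x[k] - x[j])
        if (v < best) best <- v
      }
    }
    best
  })
}

# Independent Fisher criterion for a fixed PC triplet, written with
# explicit loops (oracle for select_pc_triplet).
oracle_triplet_criterion <- function(scores, labels, idx) {
  S <- scores[, idx, drop = FALSE]
  gm <- colMeans(S)
  Sw <- matrix(0, 3, 3); Sb <- matrix(0, 3, 3)
  for (k in levels(labels)) {
    Sk <- S[labels == k, , drop = FALSE]
    mk <- colMeans(Sk)
    for (i in seq_len(nrow(Sk)))
      Sw <- Sw + tcrossprod(Sk[i, ] - mk)
    Sb <- Sb + nrow(Sk) * tcrossprod(mk - gm)
  }
  sum(diag(solve(Sw) %*% Sb))
}

# Exact two-sided Mann-Whitney p value by enumeration of all
# choose(nA + nB, nA) group assignments.
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  u_stat <- function(ia) {
    ra <- rank(pooled)[ia]
    sum(ra) - nA * (nA + 1) / 2
  }
  obs <- u_stat(seq_len(nA))
  combos <- utils::combn(length(pooled), nA)
  us <- apply(combos, 2, u_stat)
  mu <- nA * (length(b)) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}
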