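# Spectral pre-processing: fingerprint cut, rubber-band baseline
# correction, vector normalisation.

#' Pre-processing configuration
#'
#' @param cut_low,cut_high Fingerprint window in cm^-1 (defaults
#'   900-1800, the biological fingerprint region of serum).
#' @param baseline_method Only `"rubberband"` (lower convex hull) is
#'   implemented.
#' @param normalisation Only `"vector"` (unit Euclidean norm).
#' @param baseline_before_cut If `TRUE`, baseline-correct on the full
#'   axis before cutting. Default `FALSE`: cutting first keeps the hull
#'   from anchoring on spectral regions that are discarded anyway.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(cut_low = 900, cut_high = 1800,
                              baseline_method = "rubberband",
                              normalisation = "vector",
                              baseline_before_cut = FALSE) {
  baseline_method <- match.arg(baseline_method, "rubberband")
  normalisation <- match.arg(normalisation, "vector")
  if (!(is.numeric(cut_low) && is.numeric(cut_high) && cut_low < cut_high))
    stop("cut_low must be smaller than cut_high")
  structure(list(cut_low = cut_low, cut_high = cut_high,
                 baseline_method = baseline_method,
                 normalisation = normalisation,
                 baseline_before_cut = baseline_before_cut),
            class = "preprocess_config")
}

#' Cut a spectra set to a wavenumber window
#'
#' Retains the closed interval `[low, high]` of the axis; the number of
#' spectra is unchanged.
#'
#' @param set A `spectra_set`.
#' @param low,high Window bounds in cm^-1 with `low < high`.
#' @return A `spectra_set` restricted to the window.
#' @export
cut_region <- function(set, low = 900, high = 1800) {
  stopifnot(inherits(set, "spectra_set"))
  if (low >= high) stop("invalid cut window: low (", low,
                        ") must be below high (", high, ")")
  keep <- set$wavenumbers >= low & set$wavenumbers <= high
  if (!any(keep))
    stop("cut window [", low, ", ", high, "] does not overlap the axis [",
         min(set$wavenumbers), ", ", max(set$wavenumbers), "]")
  spectra_set(set$wavenumbers[keep],
              set$intensities[, keep, drop = FALSE],
              set$spectrum_ids, set$subject_ids, set$class_labels,
              set$subgroup)
}

# Indices of the lower convex hull of (x, y), x strictly ascending
# (Andrew monotone chain, lower chain only).
lower_hull_indices <- function(x, y) {
  n <- length(x)
  idx <- integer(0)
  for (i in seq_len(n)) {
    while (length(idx) >= 2L) {
      k <- idx[length(idx) - 1L]; j <- idx[length(idx)]
      # drop j when it is on or above the chord k -> i
      if ((x[j] - x[k]) * (y[i] - y[k]) -
          (y[j] - y[k]) * (x[i] - x[k]) <= 0)
        idx <- idx[-length(idx)]
      else break
    }
    idx <- c(idx, i)
  }
  idx
}

#' Rubber-band baseline correction of one spectrum
#'
#' The baseline is the lower convex-hull envelope of the
#' (wavenumber, intensity) points, linearly interpolated between hull
#' vertices -- the "rubber band" stretched under the spectrum. The
#' corrected spectrum is nonnegative and exactly zero at hull vertices,
#' including both endpoints; broad smooth backgrounds (fluorescence) are
#' removed while band structure is preserved.
#'
#' @param wavenumbers Ascending numeric axis (>= 3 points).
#' @param intensities Finite numeric vector on that axis.
#' @return List with `baseline` and `corrected` (`intensities - baseline`).
#' @export
rubberband_baseline <- function(wavenumbers, intensities) {
  if (length(wavenumbers) < 3L)
    stop("rubber-band baseline needs at least 3 points")
  if (length(intensities) != length(wavenumbers))
    stop("axis and intensity lengths differ")
  if (any(!is.finite(intensities)))
    stop("non-finite intensity values")
  hull <- lower_hull_indices(wavenumbers, intensities)
  baseline <- stats::approx(wavenumbers[hull], intensities[hull],
                            xout = wavenumbers)$y
  list(baseline = baseline, corrected = intensities - baseline)
}

#' Scale a spectrum to unit Euclidean norm
#'
#' @param x Nonzero numeric vector.
#' @return `x / ||x||_2`, with norm 1; direction preserved.
#' @export
vector_normalise <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("cannot vector-normalise an all-zero (or non-finite) spectrum")
  x / nrm
}

#' Pre-process a spectra set
#'
#' Applies, per spectrum: cut to the fingerprint window, rubber-band
#' baseline correction, vector normalisation (order of the first two
#' steps configurable). Metadata is untouched.
#'
#' @param set A `spectra_set`.
#' @param cfg A [preprocess_config].
#' @return A `spectra_set` of unit-norm, baseline-corrected spectra on
#'   the cut axis.
#' @export
preprocess <- function(set, cfg = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"), inherits(cfg, "preprocess_config"))
  correct_all <- function(s) {
    s$intensities <- t(apply(s$intensities, 1L, function(y)
      rubberband_baseline(s$wavenumbers, y)$corrected))
    s
  }
  if (cfg$baseline_before_cut) {
    set <- correct_all(set)
    set <- cut_region(set, cfg$cut_low, cfg$cut_high)
  } else {
    set <- cut_region(set, cfg$cut_low, cfg$cut_high)
    set <- correct_all(set)
  }
  set$intensities <- t(apply(set$intensities, 1L, vector_normalise))
  set
}
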