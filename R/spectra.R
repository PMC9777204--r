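#' Construct a set of Raman spectra with per-spectrum metadata
#'
#' A `spectra_set` bundles a shared wavenumber axis, an intensity matrix
#' (one row per spectrum) and the metadata the downstream analysis needs:
#' a unique spectrum id, the subject each replicate came from, and a class
#' label. The axis is always stored in ascending wavenumber order; inputs
#' on a descending axis are flipped, and the intensity columns with them.
#'
#' @param wavenumbers Numeric vector of Raman shifts in cm^-1, strictly
#'   monotonic (ascending or descending; stored ascending).
#' @param intensities Numeric matrix, `n_spectra x length(wavenumbers)`,
#'   arbitrary intensity units.
#' @param spectrum_ids Character vector of unique spectrum identifiers.
#' @param subject_ids Character vector grouping replicate spectra by
#'   subject.
#' @param class_labels Factor (or vector coercible to factor) of class
#'   labels, one per spectrum.
#' @param subgroup Optional per-spectrum subgroup annotation.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, intensities, spectrum_ids,
                        subject_ids, class_labels, subgroup = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) == 0L || ncol(intensities) == 0L)
    stop("spectra_set needs at least one spectrum and one wavenumber")
  n <- nrow(intensities)
  if (length(wavenumbers) != ncol(intensities))
    stop("length of wavenumber axis (", length(wavenumbers),
         ") does not match intensity columns (", ncol(intensities), ")")
  d <- diff(wavenumbers)
  if (any(d == 0))
    stop("duplicate wavenumber values in axis")
  if (all(d < 0)) {           # descending instrument axis: flip
    wavenumbers <- rev(wavenumbers)
    intensities <- intensities[, rev(seq_along(wavenumbers)), drop = FALSE]
  } else if (any(d < 0)) {
    stop("wavenumber axis is not monotonic")
  }
  spectrum_ids <- as.character(spectrum_ids)
  if (length(spectrum_ids) != n)
    stop("need one spectrum_id per spectrum")
  if (anyDuplicated(spectrum_ids))
    stop("spectrum_ids are not unique: ",
         paste(unique(spectrum_ids[duplicated(spectrum_ids)]), collapse = ", "))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n || anyNA(subject_ids))
    stop("need one non-missing subject_id per spectrum")
  class_labels <- as.factor(class_labels)
  if (length(class_labels) != n || anyNA(class_labels))
    stop("need one non-missing class label per spectrum")
  if (!is.null(subgroup) && length(subgroup) != n)
    stop("subgroup must have one entry per spectrum")
  rownames(intensities) <- spectrum_ids
  colnames(intensities) <- NULL
  structure(
    list(wavenumbers = wavenumbers,
         intensities = intensities,
         spectrum_ids = spectrum_ids,
         subject_ids = subject_ids,
         class_labels = class_labels,
         subgroup = subgroup),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set:", n_spectra(x), "spectra x", length(x$wavenumbers),
      "wavenumbers (", min(x$wavenumbers), "-", max(x$wavenumbers), "cm^-1 )\n")
  cat("classes:",
      paste(sprintf("%s=%d", levels(x$class_labels),
                    tabulate(x$class_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `spectra_set`.
#' @return Integer count.
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' Subset a spectra set by spectrum index
#' @param set A `spectra_set`.
#' @param i Integer or logical index over spectra.
#' @return A `spectra_set` with the selected spectra.
#' @export
subset_spectra <- function(set, i) {
  spectra_set(set$wavenumbers,
              set$intensities[i, , drop = FALSE],
              set$spectrum_ids[i],
              set$subject_ids[i],
              droplevels(set$class_labels[i]),
              if (!is.null(set$subgroup)) set$subgroup[i])
}

#' Summarise the design of a spectra set
#'
#' Tabulates per-class spectrum counts and per-subject replicate counts
#' into a manifest, the record of the cohort design actually present in
#' the data.
#'
#' @param set A `spectra_set`.
#' @param provenance Optional free-text provenance string.
#' @return A `dataset_manifest`: list with `n_spectra`, `class_counts`
#'   (named integer vector), `subject_counts` (named integer vector of
#'   replicates per subject) and `provenance`.
#' @export
summarise_spectra <- function(set, provenance = "") {
  stopifnot(inherits(set, "spectra_set"))
  cls <- table(set$class_labels)
  subj <- table(set$subject_ids)
  m <- structure(
    list(n_spectra = n_spectra(set),
         class_counts = stats::setNames(as.integer(cls), names(cls)),
         subject_counts = stats::setNames(as.integer(subj), names(subj)),
         provenance = provenance),
    class = "dataset_manifest")
  stopifnot(sum(m$class_counts) == m$n_spectra,
            sum(m$subject_counts) == m$n_spectra,
            all(m$subject_counts >= 1L))
  m
}

#' @export
summary.spectra_set <- function(object, ...) summarise_spectra(object)

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("dataset_manifest:", x$n_spectra, "spectra\n")
  cat("per class: ",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
            collapse = ", "), "\n")
  cat("subjects:", length(x$subject_counts),
      "(replicates", min(x$subject_counts), "-", max(x$subject_counts), ")\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}
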