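# Plain-text spectral input/output.
#
# Two layouts are supported:
#   * a wide delimited matrix: column 1 is the wavenumber axis
#     (`wavenumber_cm1`), every further column one spectrum, header row
#     carries the spectrum ids;
#   * a directory of two-column (wavenumber, intensity) text files,
#     whitespace- or comma-delimited, file name (sans extension) = id.
# Metadata travels in a separate CSV keyed by spectrum id with columns
# `spectrum_id, subject_id, class[, subgroup]`.

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.table(path, header = FALSE, sep = sep,
                    stringsAsFactors = FALSE, comment.char = "#")
}

check_numeric_cols <- function(df, path, first_col = 1L) {
  for (j in seq(first_col, ncol(df))) {
    v <- df[[j]]
    if (is.numeric(v)) next
    bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
    if (length(bad) == 0) bad <- which(is.na(v))
    stop("non-numeric cell in ", path, " at row ", bad[1] + 1L,
         ", column ", j, call. = FALSE)
  }
}

read_wide_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("wide matrix in ", path, " has no spectrum columns")
  check_numeric_cols(df, path)
  list(wavenumbers = as.numeric(df[[1]]),
       # spectra are columns on disk, rows in memory
       intensities = t(as.matrix(df[, -1, drop = FALSE])),
       ids = colnames(df)[-1])
}

read_spectrum_dir <- function(path) {
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no spectrum files found in ", path)
  axis <- NULL
  rows <- list()
  for (f in files) {
    df <- read_delim_auto(f)
    if (ncol(df) != 2L)
      stop("expected two columns (wavenumber, intensity) in ", f)
    check_numeric_cols(df, f)
    w <- as.numeric(df[[1]]); y <- as.numeric(df[[2]])
    o <- order(w)
    w <- w[o]; y <- y[o]
    if (anyDuplicated(w))
      stop("duplicate wavenumber values in ", f)
    if (is.null(axis)) axis <- w
    else if (length(w) != length(axis) || any(w != axis))
      stop("wavenumber axis in ", f, " differs from the other files")
    id <- sub("\\.[^.]*$", "", basename(f))
    rows[[id]] <- y
  }
  list(wavenumbers = axis,
       intensities = do.call(rbind, rows),
       ids = names(rows))
}

read_metadata <- function(metadata_path) {
  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "subject_id", "class")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata ", metadata_path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  md
}

#' Read a spectra set from plain-text files
#'
#' @param path Either a wide delimited matrix file (first column
#'   `wavenumber_cm1`, one column per spectrum) or a directory of
#'   two-column (wavenumber, intensity) text files named by spectrum id.
#' @param metadata_path CSV with columns
#'   `spectrum_id, subject_id, class[, subgroup]`; its ids must match the
#'   spectra exactly (any mismatch is an error).
#' @return A [spectra_set] with the axis sorted ascending.
#' @export
read_spectra <- function(path, metadata_path) {
  raw <- if (dir.exists(path)) read_spectrum_dir(path) else read_wide_matrix(path)
  md <- read_metadata(metadata_path)
  extra <- setdiff(raw$ids, md$spectrum_id)
  orphan <- setdiff(md$spectrum_id, raw$ids)
  if (length(extra) || length(orphan))
    stop("metadata/spectrum id mismatch; missing from metadata: [",
         paste(extra, collapse = ", "), "], missing from spectra: [",
         paste(orphan, collapse = ", "), "]")
  md <- md[match(raw$ids, md$spectrum_id), ]
  o <- order(raw$wavenumbers)
  w <- raw$wavenumbers[o]
  if (anyDuplicated(w)) stop("duplicate wavenumber values in axis of ", path)
  spectra_set(w, raw$intensities[, o, drop = FALSE],
              raw$ids, md$subject_id, md$class,
              if ("subgroup" %in% names(md)) md$subgroup)
}

#' Write a spectra set to a wide CSV plus a metadata CSV
#'
#' Values round-trip through [read_spectra] to better than 1e-9.
#'
#' @param set A `spectra_set` with all-finite intensities.
#' @param path Output CSV path for the wide matrix.
#' @param metadata_path Output CSV path for the metadata; defaults to
#'   `path` with a `_metadata.csv` suffix.
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(set, path,
                          metadata_path = sub("(\\.[^.]+)?$", "_metadata.csv",
                                              path)) {
  stopifnot(inherits(set, "spectra_set"))
  if (n_spectra(set) == 0L) stop("refusing to write an empty spectra set")
  bad <- which(apply(set$intensities, 1L, function(r) any(!is.finite(r))))
  if (length(bad))
    stop("non-finite intensities in spectrum: ",
         paste(set$spectrum_ids[bad], collapse = ", "))
  out <- data.frame(wavenumber_cm1 = set$wavenumbers, check.names = FALSE)
  for (i in seq_len(n_spectra(set)))
    out[[set$spectrum_ids[i]]] <- set$intensities[i, ]
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  md <- data.frame(spectrum_id = set$spectrum_ids,
                   subject_id = set$subject_ids,
                   class = as.character(set$class_labels))
  if (!is.null(set$subgroup)) md$subgroup <- set$subgroup
  utils::write.csv(md, metadata_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
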