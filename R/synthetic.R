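# Synthetic serum-like Raman cohorts.
#
# A spectrum is built as
#   [ background + sum(base bands) + sum(planted, group-shifted bands) ]
#     x subject band effects x replicate gain  +  additive noise,
# on a 400-1800 cm^-1 axis (2 cm^-1 step). Bands are Gaussians; the
# background is a broad decaying fluorescence curve. Class effects are
# multiplicative band-amplitude shifts applied before normalisation, so
# vector normalisation later redistributes part of the effect across
# the spectrum, as it does for real relative-intensity data.

#' Fixed serum band library
#'
#' Gaussian bands spanning the fingerprint region, with strong bands
#' near 1002 (phenylalanine ring breathing), 1450 (CH2 deformation) and
#' 1655 cm^-1 (amide I), plus a very broad underlying protein envelope
#' (serum spectra do not fall to zero between bands), qualitatively
#' matching the shape of pre-processed serum spectra. Amplitudes are in
#' units of the strongest narrow band.
#'
#' @return Data frame with `center` (cm^-1), `width` (Gaussian SD,
#'   cm^-1) and `amplitude`.
#' @export
serum_band_library <- function() {
  data.frame(
    center    = c(940, 965, 1002, 1032, 1070, 1113, 1126, 1155, 1175,
                  1208, 1244, 1260, 1286, 1305, 1319, 1335, 1346, 1365,
                  1380, 1408, 1425, 1452, 1480, 1505, 1527, 1550, 1575,
                  1596, 1615, 1639, 1655, 1680, 1700, 1727, 1745, 1400),
    width     = c(9, 7, 4, 6, 7, 7, 6, 6, 7,
                  6, 9, 7, 8, 7, 7, 6, 8, 6,
                  7, 8, 7, 8, 7, 7, 6, 7, 7,
                  7, 7, 8, 9, 7, 7, 7, 8, 230),
    amplitude = c(0.25, 0.20, 1.00, 0.35, 0.30, 0.25, 0.30, 0.25, 0.30,
                  0.25, 0.40, 0.30, 0.30, 0.35, 0.25, 0.30, 0.30, 0.35,
                  0.30, 0.25, 0.30, 0.75, 0.35, 0.30, 0.20, 0.35, 0.30,
                  0.25, 0.35, 0.40, 0.90, 0.40, 0.30, 0.20, 0.15, 1.20))
}

#' Cohort design
#'
#' @param groups List of groups, each a list with `label`, `subjects`
#'   (character vector of subject ids) and `replicates` (integer vector,
#'   one count per subject).
#' @param axis_start,axis_stop,axis_step Wavenumber axis in cm^-1
#'   (defaults 400-1800 by 2).
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(groups, axis_start = 400, axis_stop = 1800,
                          axis_step = 2) {
  if (axis_step <= 0) stop("axis_step must be positive")
  for (g in groups) {
    stopifnot(length(g$subjects) >= 1L,
              length(g$replicates) == length(g$subjects),
              all(g$replicates >= 1L))
  }
  structure(list(groups = groups,
                 axis = seq(axis_start, axis_stop, by = axis_step)),
            class = "cohort_design")
}

#' Effect and noise specification for the generator
#'
#' @param planted_bands Data frame with `center`, `width`, `amplitude`:
#'   bands whose amplitude differs between groups.
#' @param planted_shifts Numeric matrix, one row per group label (row
#'   names) and one column per planted band: signed relative amplitude
#'   shift of that band in that group (0 = reference level).
#' @param base_bands Band library shared by all groups (default
#'   [serum_band_library] minus any centers that are planted).
#' @param background_amplitude Fluorescence background scale (default
#'   1.5).
#' @param subject_sd Between-subject SD of per-band relative amplitude
#'   (default 0.01).
#' @param replicate_sd Additive per-point noise SD, in units of the
#'   strongest band (default 0.02).
#' @param gain_sd SD of the log-normal whole-spectrum replicate gain
#'   (default 0.05).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(planted_bands, planted_shifts,
                        base_bands = NULL,
                        background_amplitude = 1.5,
                        subject_sd = 0.01,
                        replicate_sd = 0.02,
                        gain_sd = 0.05) {
  stopifnot(nrow(planted_shifts) >= 1L,
            ncol(planted_shifts) == nrow(planted_bands),
            all(planted_bands$width > 0),
            subject_sd >= 0, replicate_sd >= 0, gain_sd >= 0)
  if (is.null(base_bands)) {
    base_bands <- serum_band_library()
    base_bands <- base_bands[!base_bands$center %in% planted_bands$center, ]
  }
  stopifnot(is.data.frame(base_bands))
  structure(list(planted_bands = planted_bands,
                 planted_shifts = planted_shifts,
                 base_bands = base_bands,
                 background_amplitude = background_amplitude,
                 subject_sd = subject_sd,
                 replicate_sd = replicate_sd,
                 gain_sd = gain_sd),
            class = "effect_spec")
}

gaussian_bands <- function(axis, centers, widths, amplitudes) {
  # rows = bands, cols = axis points
  if (length(centers) == 0L) return(matrix(0, 0L, length(axis)))
  t(sapply(seq_along(centers), function(j)
    amplitudes[j] * exp(-(axis - centers[j])^2 / (2 * widths[j]^2))))
}

#' Generate a synthetic Raman cohort
#'
#' Fully reproducible given `seed`; the output passes `spectra_set`
#' validation for any valid design.
#'
#' @param design A [cohort_design].
#' @param effects An [effect_spec]; its `planted_shifts` rows must cover
#'   every group label in the design.
#' @param seed Integer seed.
#' @return A raw (un-pre-processed) `spectra_set`; subjects and classes
#'   in the metadata. The planted band table (with the reference-vs-
#'   group directions) is attached as attribute `"planted"`.
#' @export
generate_cohort <- function(design, effects, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"), inherits(effects, "effect_spec"))
  labels <- vapply(design$groups, `[[`, "", "label")
  missing_rows <- setdiff(labels, rownames(effects$planted_shifts))
  if (length(missing_rows))
    stop("planted_shifts has no row for group(s): ",
         paste(missing_rows, collapse = ", "))
  set.seed(seed)
  axis <- design$axis
  bg <- effects$background_amplitude *
    (exp(-(axis - min(axis)) / 600) + 0.3)
  Gb <- gaussian_bands(axis, effects$base_bands$center,
                       effects$base_bands$width,
                       effects$base_bands$amplitude)
  Gp <- gaussian_bands(axis, effects$planted_bands$center,
                       effects$planted_bands$width,
                       effects$planted_bands$amplitude)
  nb <- nrow(Gb); np <- nrow(Gp)
  rows <- list(); subj <- character(0); cls <- character(0); ids <- character(0)
  for (g in design$groups) {
    shifts <- effects$planted_shifts[g$label, ]
    for (s in seq_along(g$subjects)) {
      base_mult <- 1 + stats::rnorm(nb, 0, effects$subject_sd)
      planted_mult <- (1 + stats::rnorm(np, 0, effects$subject_sd)) *
        (1 + shifts)
      clean <- bg + colSums(base_mult * Gb) + colSums(planted_mult * Gp)
      for (r in seq_len(g$replicates[s])) {
        gain <- exp(stats::rnorm(1, 0, effects$gain_sd))
        y <- clean * gain + stats::rnorm(length(axis), 0, effects$replicate_sd)
        id <- sprintf("%s_rep%02d", g$subjects[s], r)
        rows[[id]] <- y
        subj <- c(subj, g$subjects[s])
        cls <- c(cls, g$label)
        ids <- c(ids, id)
      }
    }
  }
  out <- spectra_set(axis, do.call(rbind, rows), ids, subj,
                     factor(cls, levels = labels))
  attr(out, "planted") <- effects$planted_bands
  attr(out, "planted_shifts") <- effects$planted_shifts
  out
}

table2_wavenumbers <- c(1002, 1070, 1113, 1155, 1286, 1346, 1408, 1452,
                        1527, 1596, 1639, 1727)

#' The twelve discriminatory serum wavenumbers
#'
#' Band centers (cm^-1) whose intensity separates disease from control
#' serum in the reference analysis, and which the default synthetic
#' cohorts plant as class effects: 1002, 1070, 1113, 1155, 1286, 1346,
#' 1408, 1452, 1527, 1596, 1639, 1727. All are raised in disease
#' except 1155 cm^-1.
#'
#' @return Data frame with `wavenumber` and `direction` (+1 raised in
#'   disease, -1 lowered).
#' @export
discriminatory_wavenumbers <- function() {
  data.frame(wavenumber = table2_wavenumbers,
             direction = default_direction())
}

# direction pattern of the 12 discriminatory bands: all raised in
# disease except 1155 cm^-1, which is reduced
default_direction <- function() ifelse(table2_wavenumbers == 1155, -1, 1)

# Relative band-amplitude shifts implementing the disease effect: each
# discriminatory band changes by an absolute intensity of `shift_abs`
# in its planted direction, while the broad underlying envelope is
# fractionally reduced so that total scattering intensity over the
# fingerprint region is conserved. Disease then redistributes relative
# intensity -- the regime in which vector-normalised analysis is
# well-posed -- and the compensation, being featureless, adds no sharp
# extrema of its own to the class contrast.
disease_shifts <- function(shift_abs, lib = serum_band_library()) {
  planted <- lib$center %in% table2_wavenumbers
  envelope <- which.max(lib$width)  # the broad envelope band
  dirv <- default_direction()[match(lib$center[planted],
                                    table2_wavenumbers)]
  axis <- seq(900, 1800, by = 2)
  G <- gaussian_bands(axis, lib$center, lib$width, rep(1, nrow(lib)))
  sbar <- colSums(lib$amplitude * G)
  gain <- sum(colSums((shift_abs * dirv) * G[planted, , drop = FALSE]) * sbar)
  eps <- gain / (lib$amplitude[envelope] * sum(G[envelope, ] * sbar))
  r <- numeric(nrow(lib))
  r[planted] <- shift_abs * dirv / lib$amplitude[planted]
  r[envelope] <- -eps
  r
}

subject_plan <- function() {
  list(hc = list(label = "HC",
                 subjects = sprintf("HC%02d", 1:4),
                 replicates = rep(20L, 4)),
       g1 = list(label = "CLIFT-N/A",
                 subjects = c("P1", "P2"), replicates = c(20L, 20L)),
       g2 = list(label = "CLIFT-Neg",
                 subjects = c("P3", "P4"), replicates = c(18L, 19L)),
       g3 = list(label = "CLIFT-Pos",
                 subjects = c("P5", "P6", "P7", "P8"),
                 replicates = c(20L, 20L, 20L, 17L)))
}

#' Default two-class synthetic cohort
#'
#' Emulates the reference design: 4 control subjects with 20 replicates
#' each (80 spectra) and 8 disease subjects with 20, 20, 18, 19, 20,
#' 20, 20 and 17 replicates (154 spectra; 234 in total). Twelve
#' discriminatory bands (1002, 1070, 1113, 1155, 1286, 1346, 1408,
#' 1452, 1527, 1596, 1639, 1727 cm^-1) are shifted in the disease class
#' by an absolute band-intensity change of `shift_multiple` times the
#' replicate noise SD -- raised for 11 of them and lowered at
#' 1155 cm^-1.
#'
#' @param seed Integer seed.
#' @param shift_multiple Planted shift as a multiple of the replicate
#'   noise SD (default 3).
#' @param replicate_sd Additive noise SD (default 0.02).
#' @return A raw `spectra_set` with classes `HC` and `SLE` (`SLE` is
#'   the positive level) and the planted-truth attributes of
#'   [generate_cohort].
#' @export
default_two_class <- function(seed = 42L, shift_multiple = 3,
                              replicate_sd = 0.02) {
  plan <- subject_plan()
  sle <- list(label = "SLE",
              subjects = unlist(lapply(plan[c("g1", "g2", "g3")],
                                       `[[`, "subjects"), use.names = FALSE),
              replicates = unlist(lapply(plan[c("g1", "g2", "g3")],
                                         `[[`, "replicates"),
                                  use.names = FALSE))
  design <- cohort_design(list(plan$hc, sle))
  lib <- serum_band_library()
  r <- disease_shifts(shift_multiple * replicate_sd, lib)
  shifts <- rbind(HC = rep(0, nrow(lib)), SLE = r)
  generate_cohort(design,
                  effect_spec(lib, shifts,
                              base_bands = lib[0, ],
                              replicate_sd = replicate_sd),
                  seed = seed)
}

#' Default four-group synthetic cohort
#'
#' The same 234-spectrum design split into healthy controls (80) and
#' three disease serology subgroups (40 / 37 / 77 spectra). All
#' disease subgroups share the two-class band shifts; each subgroup
#' additionally modulates two of its own bands by an absolute
#' intensity change of `subgroup_multiple` x the replicate noise SD,
#' giving weaker subgroup-vs-subgroup separation than
#' disease-vs-control.
#'
#' @param seed Integer seed.
#' @param shift_multiple Shared disease shift multiple (default 3).
#' @param subgroup_multiple Subgroup-specific shift multiple (default 2).
#' @param replicate_sd Additive noise SD (default 0.02).
#' @return A raw `spectra_set` with classes `HC`, `CLIFT-N/A`,
#'   `CLIFT-Neg`, `CLIFT-Pos`.
#' @export
default_four_group <- function(seed = 42L, shift_multiple = 3,
                               subgroup_multiple = 2,
                               replicate_sd = 0.02) {
  plan <- subject_plan()
  design <- cohort_design(plan)
  lib <- serum_band_library()
  disease <- disease_shifts(shift_multiple * replicate_sd, lib)
  # subgroup-specific modulations on two distinct non-discriminatory
  # bands each, as absolute intensity shifts converted to relative
  sub_bands <- list("CLIFT-N/A" = c(1032, 1244),
                    "CLIFT-Neg" = c(1208, 1319),
                    "CLIFT-Pos" = c(965, 1745))
  shifts <- rbind("HC" = rep(0, nrow(lib)),
                  "CLIFT-N/A" = disease,
                  "CLIFT-Neg" = disease,
                  "CLIFT-Pos" = disease)
  for (g in names(sub_bands)) {
    i <- match(sub_bands[[g]], lib$center)
    shifts[g, i] <- shifts[g, i] +
      subgroup_multiple * replicate_sd / lib$amplitude[i]
  }
  generate_cohort(design,
                  effect_spec(lib, shifts,
                              base_bands = lib[0, ],
                              replicate_sd = replicate_sd),
                  seed = seed)
}

#' Generate a synthetic anti-dsDNA audit table
#'
#' One row per test request: a quantitative ELIA value in IU/mL
#' (log-normal, with positivity defined by value > 10), a CLIFT
#' category (0 = negative .. 3 = strong positive) recorded only for
#' ELIA-positive requests (the reflex-testing cascade), and a clinical
#' diagnosis flag. Marginal rates hold in expectation.
#'
#' @param n_requests Number of requests (default 600).
#' @param params List of rates: `elia_pos` (P(ELIA positive)),
#'   `clift_pos_given_elia` (P(CLIFT positive | ELIA positive)),
#'   `category_mix` (weak/positive/strong split among CLIFT positives),
#'   `diagnosis_mix` (named list of `c(SLE, SLE-overlap, other)`
#'   probabilities per stratum `dual_pos`, `elia_only`, `elia_neg`).
#' @param seed Integer seed.
#' @return An `audit_table` data frame with `request_id`, `elia_iuml`,
#'   `clift_category` (NA when not performed) and `diagnosis`.
#' @export
generate_audit <- function(n_requests = 600L,
                           params = list(),
                           seed = 7L) {
  p <- utils::modifyList(list(
    elia_pos = 128 / 600,
    clift_pos_given_elia = 27 / 128,
    category_mix = c(weak = 7, positive = 16, strong = 4) / 27,
    diagnosis_mix = list(
      dual_pos  = c(0.85, 0.04, 0.11),
      elia_only = c(0.23, 0.075, 0.695),
      elia_neg  = c(0.023, 0.007, 0.97))), params)
  probs <- c(p$elia_pos, p$clift_pos_given_elia, p$category_mix,
             unlist(p$diagnosis_mix))
  if (any(probs < 0 | probs > 1)) stop("rates must lie in [0, 1]")
  set.seed(seed)
  elia_pos <- stats::runif(n_requests) < p$elia_pos
  rtrunc_lnorm <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
    lo <- stats::plnorm(lower, meanlog, sdlog)
    hi <- stats::plnorm(upper, meanlog, sdlog)
    stats::qlnorm(lo + stats::runif(n) * (hi - lo), meanlog, sdlog)
  }
  elia <- numeric(n_requests)
  elia[!elia_pos] <- rtrunc_lnorm(sum(!elia_pos), log(3), 0.7, upper = 10)
  npos <- sum(elia_pos)
  if (npos > 0) {
    # three positive clusters: low (just above 10), mid (100-170), high (>379)
    comp <- sample.int(3L, npos, replace = TRUE, prob = c(0.6, 0.25, 0.15))
    vals <- numeric(npos)
    vals[comp == 1] <- rtrunc_lnorm(sum(comp == 1), log(25), 0.6, lower = 10)
    vals[comp == 2] <- rtrunc_lnorm(sum(comp == 2), log(130), 0.12)
    vals[comp == 3] <- rtrunc_lnorm(sum(comp == 3), log(450), 0.15,
                                    lower = 379)
    elia[elia_pos] <- vals
  }
  clift <- rep(NA_integer_, n_requests)
  if (npos > 0) {
    cp <- stats::runif(npos) < p$clift_pos_given_elia
    cat_pos <- sample.int(3L, sum(cp), replace = TRUE, prob = p$category_mix)
    clift[elia_pos] <- 0L
    clift[which(elia_pos)[cp]] <- cat_pos
  }
  stratum <- ifelse(!elia_pos, "elia_neg",
                    ifelse(!is.na(clift) & clift >= 1L, "dual_pos",
                           "elia_only"))
  dx_levels <- c("SLE", "SLE-overlap", "other")
  diagnosis <- vapply(stratum, function(s)
    sample(dx_levels, 1L, prob = p$diagnosis_mix[[s]]), "")
  structure(
    data.frame(request_id = sprintf("R%04d", seq_len(n_requests)),
               elia_iuml = elia,
               clift_category = clift,
               diagnosis = factor(diagnosis, levels = dx_levels)),
    class = c("audit_table", "data.frame"))
}
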