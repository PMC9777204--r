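# Anti-dsDNA clinical audit statistics: ELIA/CLIFT reflex-testing
# cascade summary, diagnostic 2x2 metrics, and nonparametric group
# comparisons of ELIA titres across CLIFT categories.

round_half_up <- function(x) floor(x + 0.5)

as_audit_table <- function(table) {
  need <- c("elia_iuml", "clift_category", "diagnosis")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("audit table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(table$elia_iuml < 0, na.rm = TRUE))
    stop("negative ELIA values")
  table
}

#' Summarise the ELIA -> CLIFT testing cascade
#'
#' Counts requests through the reflex cascade: ELIA positivity
#' (strictly above `elia_threshold` IU/mL), CLIFT negativity/positivity
#' among ELIA positives, the weak/positive/strong category split among
#' CLIFT positives, and dual positivity as a fraction of all requests.
#' Report percentages are rounded half-up to integers; the exact
#' fractions are kept alongside.
#'
#' @param table Audit data frame with columns `elia_iuml`,
#'   `clift_category` (0-3, NA = not performed), `diagnosis`.
#' @param elia_threshold Positivity cut-off in IU/mL (default 10,
#'   strict `>`).
#' @return A `cascade_summary` list of counts and percentages.
#' @export
summarise_cascade <- function(table, elia_threshold = 10) {
  table <- as_audit_table(table)
  n <- nrow(table)
  if (n == 0L) stop("empty audit table")
  pos <- !is.na(table$elia_iuml) & table$elia_iuml > elia_threshold
  n_pos <- sum(pos)
  cl <- table$clift_category[pos]
  n_clift_done <- sum(!is.na(cl))
  n_clift_neg <- sum(cl == 0L, na.rm = TRUE)
  n_clift_pos <- sum(cl >= 1L, na.rm = TRUE)
  cat_counts <- vapply(1:3, function(k) sum(cl == k, na.rm = TRUE), 0L)
  names(cat_counts) <- c("weak_positive", "positive", "strong_positive")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- list(
    n_requests = n,
    elia_threshold = elia_threshold,
    n_elia_pos = n_pos,
    pct_elia_pos = pct(n_pos, n),
    n_clift_done = n_clift_done,
    n_clift_neg = n_clift_neg,
    pct_clift_neg = pct(n_clift_neg, n_clift_done),
    n_clift_pos = n_clift_pos,
    pct_clift_pos = pct(n_clift_pos, n_clift_done),
    category_counts = cat_counts,
    category_pct = vapply(cat_counts, pct, 0, den = n_clift_pos),
    n_dual_pos = n_clift_pos,
    pct_dual_pos = pct(n_clift_pos, n))
  stopifnot(sum(cat_counts) == n_clift_pos)
  out$report <- lapply(out[grep("^pct_|category_pct", names(out))],
                       round_half_up)
  structure(out, class = "cascade_summary")
}

#' @export
print.cascade_summary <- function(x, ...) {
  r <- x$report
  cat(sprintf("%d requests; %d (%d%%) ELIA-positive (> %g IU/mL)\n",
              x$n_requests, x$n_elia_pos, r$pct_elia_pos, x$elia_threshold))
  cat(sprintf("of %d CLIFT-tested: %d (%d%%) negative, %d (%d%%) positive\n",
              x$n_clift_done, x$n_clift_neg, r$pct_clift_neg,
              x$n_clift_pos, r$pct_clift_pos))
  if (x$n_clift_pos > 0)
    cat(sprintf("CLIFT positives: %d weak (%d%%), %d positive (%d%%), %d strong (%d%%)\n",
                x$category_counts[1], r$category_pct[1],
                x$category_counts[2], r$category_pct[2],
                x$category_counts[3], r$category_pct[3]))
  cat(sprintf("dual ELIA+CLIFT positive: %d of %d (%d%%)\n",
              x$n_dual_pos, x$n_requests, r$pct_dual_pos))
  invisible(x)
}

#' Diagnostic performance of ELIA or CLIFT against clinical diagnosis
#'
#' Builds the 2x2 table of test positivity (ELIA: value strictly above
#' the threshold; CLIFT: category >= 1, with not-performed counted
#' negative) against `diagnosis == "SLE"`, and reports sensitivity,
#' specificity, PPV and NPV in percent. Overlap syndromes
#' (`"SLE-overlap"`) count as non-SLE unless `include_overlap = TRUE`.
#' Zero-denominator ratios are returned as `NA` with a warning.
#'
#' @param table Audit data frame (see [summarise_cascade]).
#' @param method `"ELIA"` or `"CLIFT"`.
#' @param elia_threshold ELIA positivity cut-off (default 10 IU/mL).
#' @param include_overlap Count SLE overlap syndromes as SLE.
#' @return List with the 2x2 `counts` (TP, FP, TN, FN) and
#'   `sensitivity`, `specificity`, `ppv`, `npv` in percent.
#' @export
diagnostic_metrics <- function(table, method = c("ELIA", "CLIFT"),
                               elia_threshold = 10,
                               include_overlap = FALSE) {
  table <- as_audit_table(table)
  method <- match.arg(method)
  test_pos <- if (method == "ELIA")
    !is.na(table$elia_iuml) & table$elia_iuml > elia_threshold
  else
    !is.na(table$clift_category) & table$clift_category >= 1L
  dx <- table$diagnosis == "SLE" |
    (include_overlap & table$diagnosis == "SLE-overlap")
  tp <- sum(test_pos & dx); fp <- sum(test_pos & !dx)
  fn <- sum(!test_pos & dx); tn <- sum(!test_pos & !dx)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting NA")
      return(NA_real_)
    }
    100 * num / den
  }
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       sensitivity = safe(tp, tp + fn, "sensitivity"),
       specificity = safe(tn, tn + fp, "specificity"),
       ppv = safe(tp, tp + fp, "PPV"),
       npv = safe(tn, tn + fn, "NPV"))
}

#' Kruskal-Wallis test of ELIA titres across CLIFT categories
#'
#' Rank-based H statistic (tie-corrected) comparing the ELIA values of
#' the CLIFT interpretation categories present in the table.
#'
#' @param table Audit data frame; rows without a CLIFT category are
#'   dropped.
#' @return List with `H`, `df` and `p`.
#' @export
clift_kruskal_wallis <- function(table) {
  table <- as_audit_table(table)
  keep <- !is.na(table$clift_category) & !is.na(table$elia_iuml)
  g <- factor(table$clift_category[keep], levels = 0:3)
  g <- droplevels(g)
  if (nlevels(g) < 2L)
    stop("need ELIA values in at least 2 CLIFT categories")
  x <- table$elia_iuml[keep]
  if (length(unique(x)) == 1L)     # total ties: no rank information
    return(list(H = 0, df = nlevels(g) - 1L, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Mann-Whitney U test between two groups of ELIA values
#'
#' Exact two-sided p value for small samples without ties (both groups
#' <= 8), normal approximation with tie/continuity correction
#' otherwise.
#'
#' @param group_a,group_b Non-empty numeric vectors of ELIA values.
#' @return List with `U` (statistic for `group_a`) and `p`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  exact <- length(group_a) <= 8L && length(group_b) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}
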