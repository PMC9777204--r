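# Deterministic audit table mirroring the printed cascade counts:
# 600 requests, 128 ELIA-positive, of which 101 CLIFT-negative and 27
# positive (7 weak / 16 positive / 4 strong).
printed_cascade_table <- function() {
  n <- 600
  elia <- c(runif(472, 0, 10),          # negatives at/below threshold
            runif(128, 11, 400))
  clift <- rep(NA_integer_, n)
  clift[473:600] <- c(rep(0L, 101), rep(1L, 7), rep(2L, 16), rep(3L, 4))
  data.frame(request_id = sprintf("R%03d", 1:n),
             elia_iuml = elia,
             clift_category = clift,
             diagnosis = factor(rep("other", n),
                                levels = c("SLE", "SLE-overlap", "other")))
}

test_that("cascade summary reproduces the printed audit percentages", {
  set.seed(51)
  cs <- summarise_cascade(printed_cascade_table())
  expect_equal(cs$n_elia_pos, 128L)
  expect_equal(cs$report$pct_elia_pos, 21)
  expect_equal(cs$n_clift_neg, 101L)
  expect_equal(cs$report$pct_clift_neg, 79)
  expect_equal(unname(cs$category_counts), c(7L, 16L, 4L))
  expect_equal(unname(cs$report$category_pct), c(26, 59, 15))
  expect_equal(cs$n_dual_pos, 27L)
  expect_equal(cs$report$pct_dual_pos, 5)
})

test_that("cascade summary handles an all-negative table", {
  t0 <- data.frame(request_id = "a", elia_iuml = c(1, 5, 9),
                   clift_category = NA_integer_,
                   diagnosis = "other")
  cs <- summarise_cascade(t0)
  expect_equal(cs$n_elia_pos, 0L)
  expect_equal(cs$n_clift_pos, 0L)
  expect_true(is.na(cs$pct_clift_neg))
  expect_error(summarise_cascade(t0[0, ]), "empty")
})

test_that("cascade percentages are self-consistent on random fixtures", {
  for (i in 1:5) {
    a <- generate_audit(400, seed = 60 + i)
    cs <- summarise_cascade(a)
    expect_equal(cs$pct_elia_pos, 100 * cs$n_elia_pos / cs$n_requests)
    if (cs$n_clift_done > 0)
      expect_equal(cs$n_clift_neg + cs$n_clift_pos, cs$n_clift_done)
    expect_equal(sum(cs$category_counts), cs$n_clift_pos)
  }
})

test_that("diagnostic metrics follow the 2x2 arithmetic", {
  # TP 20, FN 5, FP 10, TN 65 by construction via ELIA values
  tab <- data.frame(
    request_id = sprintf("r%03d", 1:100),
    elia_iuml = c(rep(50, 30), rep(1, 70)),
    clift_category = NA_integer_,
    diagnosis = factor(c(rep("SLE", 20), rep("other", 10),
                         rep("SLE", 5), rep("other", 65)),
                       levels = c("SLE", "SLE-overlap", "other")))
  m <- diagnostic_metrics(tab, "ELIA")
  expect_equal(m$counts, c(TP = 20L, FP = 10L, TN = 65L, FN = 5L))
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 100 * 65 / 75, tolerance = 1e-10)
  expect_equal(m$ppv, 100 * 20 / 30, tolerance = 1e-10)
  expect_equal(m$npv, 100 * 65 / 70, tolerance = 1e-10)
  # a perfect test scores 100 everywhere
  perfect <- tab
  perfect$diagnosis <- factor(ifelse(perfect$elia_iuml > 10, "SLE", "other"),
                              levels = levels(tab$diagnosis))
  mp <- diagnostic_metrics(perfect, "ELIA")
  expect_equal(c(mp$sensitivity, mp$specificity, mp$ppv, mp$npv),
               rep(100, 4))
})

test_that("diagnostic metrics match a row-scan oracle and ignore row order", {
  a <- generate_audit(500, seed = 71)
  for (method in c("ELIA", "CLIFT")) {
    m <- diagnostic_metrics(a, method)
    tp <- fp <- tn <- fn <- 0L
    for (i in seq_len(nrow(a))) {
      pos <- if (method == "ELIA") a$elia_iuml[i] > 10 else
        !is.na(a$clift_category[i]) && a$clift_category[i] >= 1
      dx <- a$diagnosis[i] == "SLE"
      if (pos && dx) tp <- tp + 1L
      else if (pos) fp <- fp + 1L
      else if (dx) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_equal(m$counts, c(TP = tp, FP = fp, TN = tn, FN = fn))
    m_shuf <- diagnostic_metrics(a[sample(nrow(a)), ], method)
    expect_equal(m_shuf, m)
  }
})

test_that("overlap handling switches SLE-overlap rows between sides", {
  tab <- data.frame(request_id = c("a", "b"),
                    elia_iuml = c(50, 50),
                    clift_category = c(2L, 2L),
                    diagnosis = factor(c("SLE-overlap", "SLE"),
                                       levels = c("SLE", "SLE-overlap",
                                                  "other")))
  strict <- suppressWarnings(diagnostic_metrics(tab, "CLIFT"))
  lax <- suppressWarnings(diagnostic_metrics(tab, "CLIFT",
                                             include_overlap = TRUE))
  expect_equal(unname(strict$counts["TP"]), 1L)
  expect_equal(unname(lax$counts["TP"]), 2L)
})

test_that("Kruskal-Wallis across CLIFT categories behaves at the extremes", {
  tab <- data.frame(request_id = letters[1:8],
                    elia_iuml = rep(5, 8),
                    clift_category = rep(0:1, each = 4),
                    diagnosis = "other")
  kw <- clift_kruskal_wallis(tab)
  expect_equal(kw$H, 0, tolerance = 1e-12)       # total ties
  # manual tie-corrected H on an n = 8 toy with ties
  tab2 <- tab
  tab2$elia_iuml <- c(1, 2, 2, 3, 4, 5, 5, 6)
  kw2 <- clift_kruskal_wallis(tab2)
  r <- rank(tab2$elia_iuml)
  n <- 8; g <- tab2$clift_category
  h_raw <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(z) length(z) * mean(z)^2)) - 3 * (n + 1)
  ties <- table(tab2$elia_iuml)
  h_corr <- h_raw / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kw2$H, h_corr, tolerance = 1e-10)
  expect_error(clift_kruskal_wallis(
    data.frame(request_id = "x", elia_iuml = 1,
               clift_category = 0L, diagnosis = "other")),
    "2 CLIFT categories")
})

test_that("two-category Kruskal-Wallis orders with Mann-Whitney", {
  # without ties the two tests must agree in significance ordering
  set.seed(52)
  ps <- replicate(10, {
    a <- rnorm(6, 20, 3); b <- rnorm(6, 20 + sample(c(0, 6), 1), 3)
    tab <- data.frame(request_id = as.character(1:12),
                      elia_iuml = c(a, b),
                      clift_category = rep(0:1, each = 6),
                      diagnosis = "other")
    c(kw = clift_kruskal_wallis(tab)$p, mw = mann_whitney(a, b)$p)
  })
  expect_equal(order(ps["kw", ]), order(ps["mw", ]))
})

test_that("Mann-Whitney U matches exact enumeration for small groups", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  mw <- mann_whitney(a, b)
  expect_equal(unname(mw$U), 0)
  expect_equal(mw$p, 0.1, tolerance = 1e-10)
  set.seed(53)
  for (i in 1:5) {
    x <- round(rnorm(4), 2); y <- round(rnorm(4, 0.5), 2)
    expect_equal(mann_whitney(x, y)$p, enumerate_mw_p(x, y),
                 tolerance = 1e-8)
  }
  # U_A + U_B = nA * nB
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(7)
    expect_equal(unname(mann_whitney(x, y)$U + mann_whitney(y, x)$U),
                 5 * 7)
  }
  # identical groups: p near 1
  z <- c(1.4, 2.2, 3.1, 4.5)
  expect_gt(mann_whitney(z, z)$p, 0.5)
  expect_error(mann_whitney(numeric(0), z), "non-empty")
})
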