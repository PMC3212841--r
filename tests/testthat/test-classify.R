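test_that("the flag pair maps onto the four LGT classes", {
  expect_equal(classify_gene_set(TRUE, TRUE), "within_gene_lateral")
  expect_equal(classify_gene_set(TRUE, FALSE), "whole_gene_lateral")
  expect_equal(classify_gene_set(FALSE, TRUE), "within_gene_lateral")
  expect_equal(classify_gene_set(FALSE, FALSE), "vertical")
  expect_equal(classify_gene_set(NA, TRUE), "unclassified")
  expect_equal(classify_gene_set(TRUE, NA), "unclassified")
  expect_equal(classify_gene_set(c(TRUE, FALSE), c(FALSE, FALSE)),
               c("whole_gene_lateral", "vertical"))
})

mk_records <- function(tt, tf, ft, ff, category = NULL) {
  r <- data.frame(
    discordant = rep(c(TRUE, TRUE, FALSE, FALSE), c(tt, tf, ft, ff)),
    orb = rep(c(TRUE, FALSE, TRUE, FALSE), c(tt, tf, ft, ff)))
  if (!is.null(category)) r$regulator_category <- category
  r$lgt_class <- classify_gene_set(r$discordant, r$orb)
  r
}

test_that("summary cells, totals and proportions reconcile", {
  tab <- summarize_classification(mk_records(12, 37, 7, 34))
  expect_equal(unname(tab$cells["discordant", ]), c(12, 37))
  expect_equal(unname(tab$cells["concordant", ]), c(7, 34))
  expect_equal(unname(tab$row_totals), c(49, 41))
  expect_equal(unname(tab$col_totals), c(19, 71))
  expect_equal(tab$total, 90)
  expect_equal(tab$lateral, 56)
  expect_equal(tab$vertical, 34)
  expect_equal(tab$lateral + tab$vertical, tab$total)
})

test_that("an all-vertical cohort has zero lateral families", {
  tab <- summarize_classification(mk_records(0, 0, 0, 25))
  expect_equal(tab$lateral, 0)
  expect_equal(tab$lateral_prop, 0)
})

test_that("category filters restrict the table and empty selections warn", {
  r <- mk_records(2, 3, 1, 4, category = rep(c("neighbour", "other"), 5))
  tab <- summarize_classification(r, "neighbour")
  expect_equal(tab$total, 5)
  expect_warning(z <- summarize_classification(r, "global"), "empty")
  expect_equal(z$total, 0)
})

test_that("NA flags are excluded from denominators, never counted vertical", {
  r <- mk_records(1, 1, 1, 5)
  r$orb[2] <- NA
  tab <- summarize_classification(r)
  expect_equal(tab$total, 7)
  expect_equal(tab$n_unclassified, 1)
})

test_that("Fisher association matches direct enumeration on small tables", {
  for (tab in list(c(3, 5, 2, 8), c(1, 9, 7, 2), c(6, 0, 3, 4),
                   c(10, 0, 0, 10), c(2, 2, 2, 2))) {
    got <- fisher_association(tab[1:2], tab[3:4])$p
    expect_equal(got, enum_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
  }
})

test_that("the neighbour ORB+ enrichment reproduces the reported p", {
  res <- fisher_association(c(19, 71), c(659, 4533))
  expect_lt(abs(res$p - 0.02), 0.005)
  expect_gt(res$odds_ratio, 1)
})

test_that("identical proportions give p = 1 and zero margins fail", {
  expect_equal(fisher_association(c(5, 5), c(50, 50))$p, 1)
  expect_error(fisher_association(c(0, 0), c(3, 4)), "zero margin")
  expect_error(fisher_association(c(-1, 2), c(3, 4)), "non-negative")
})

test_that("zero cells flag the continuity-corrected odds ratio", {
  res <- fisher_association(c(10, 0), c(0, 10))
  expect_true(res$continuity)
  expect_equal(res$p, enum_fisher_p(10, 0, 0, 10), tolerance = 1e-10)
})

test_that("rank-sum comparisons match assignment enumeration", {
  set.seed(12)
  for (r in 1:25) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    a <- sample(1:15, n1, replace = TRUE)
    b <- sample(1:15, n2, replace = TRUE)
    expect_equal(rank_sum_compare(a, b), enum_ranksum_p(a, b),
                 tolerance = 1e-9)
  }
})

test_that("extreme separation at n = 3 attains the minimal two-sided p", {
  expect_equal(rank_sum_compare(c(1, 1, 1), c(9, 9, 9)), 0.1)
  expect_equal(enum_ranksum_p(c(1, 1, 1), c(9, 9, 9)), 0.1)
})

test_that("identical samples give p = 1 and empty samples fail", {
  expect_equal(rank_sum_compare(c(2, 4, 6), c(2, 4, 6)), 1)
  expect_error(rank_sum_compare(numeric(0), 1:3), "empty sample")
})

test_that("regulator-count comparison is calibrated under the null", {
  # same in-degree distribution for both groups: p should be uniform
  set.seed(99)
  ps <- replicate(120, {
    a <- rpois(40, 2); b <- rpois(35, 2)
    rank_sum_compare(a, b)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_gt(mean(ps), 0.35)
})
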