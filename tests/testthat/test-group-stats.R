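mk_groups_table <- function(values, groups) {
  as_chem_table(data.frame(region = groups, country = "X", x = values,
                           stringsAsFactors = FALSE))
}

test_that("one-way ANOVA reproduces the hand decomposition", {
  tbl <- mk_groups_table(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                         rep(c("A", "B", "C"), each = 3))
  res <- one_way_anova(tbl, "x")
  expect_equal(res$F, 3)                      # SSB = 6, SSW = 6, df 2/6
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  expect_equal(unname(res$group_means), c(2, 3, 4))
})

test_that("identical groups yield F = 0, p = 1", {
  tbl <- mk_groups_table(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  res <- one_way_anova(tbl, "x")
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_equal(res$category, "ns")
})

test_that("zero within-variance with unequal means is flagged degenerate", {
  tbl <- mk_groups_table(c(1, 1, 2, 2), rep(c("A", "B"), each = 2))
  res <- one_way_anova(tbl, "x")
  expect_true(res$degenerate)
  expect_equal(res$F, Inf)
  expect_equal(res$p, 0)
})

test_that("undersized groups are rejected by name", {
  tbl <- mk_groups_table(c(1, 2, 3), c("A", "A", "Solo"))
  expect_error(one_way_anova(tbl, "x"), "Solo")
  one_group <- mk_groups_table(c(1, 2), c("A", "A"))
  expect_error(one_way_anova(one_group, "x"), "two groups")
})

test_that("ANOVA F agrees with the brute-force oracle on random tables", {
  set.seed(101)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    n <- sample(4:8, k, replace = TRUE)
    groups <- rep(LETTERS[1:k], n)
    values <- rnorm(sum(n), mean = rep(runif(k, 0, 3), n))
    res <- one_way_anova(mk_groups_table(values, groups), "x")
    expect_equal(res$F, bf_anova_F(values, groups), tolerance = 1e-10)
  }
})

test_that("Tukey HSD matrix is symmetric with a FALSE diagonal", {
  set.seed(7)
  tbl <- mk_groups_table(rnorm(60), rep(c("A", "B", "C"), each = 20))
  hsd <- tukey_hsd(tbl, "x")
  expect_true(all(hsd$significant == t(hsd$significant)))
  expect_false(any(diag(hsd$significant)))
  # identically drawn groups: no pair significant at this seed
  expect_false(any(hsd$significant))
})

test_that("extreme separation is detected by Tukey HSD", {
  set.seed(8)
  tbl <- mk_groups_table(c(rnorm(50), rnorm(50, 20)),
                         rep(c("A", "B"), each = 50))
  hsd <- tukey_hsd(tbl, "x")
  expect_true(hsd$significant["A", "B"])
})

test_that("compact letter display handles canonical cases", {
  nm <- function(k) LETTERS[1:k]
  none <- matrix(FALSE, 4, 4, dimnames = list(nm(4), nm(4)))
  expect_equal(unname(compact_letter_display(none)), rep("a", 4))
  all5 <- matrix(TRUE, 5, 5, dimnames = list(nm(5), nm(5)))
  diag(all5) <- FALSE
  expect_equal(unname(compact_letter_display(all5)),
               c("a", "b", "c", "d", "e"))
  chain <- matrix(FALSE, 3, 3, dimnames = list(nm(3), nm(3)))
  chain["A", "C"] <- chain["C", "A"] <- TRUE
  expect_equal(unname(compact_letter_display(chain)), c("a", "ab", "b"))
  asym <- chain; asym["A", "C"] <- FALSE
  expect_error(compact_letter_display(asym), "symmetric")
})

test_that("letter sharing equals non-significance on all small instances", {
  # exhaustive for 3 and 4 groups, random for 5 and 6
  for (k in 3:4) {
    npairs <- k * (k - 1) / 2
    for (code in 0:(2^npairs - 1)) {
      bits <- as.logical(bitwAnd(code, 2^(0:(npairs - 1))))
      m <- matrix(FALSE, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
      m[lower.tri(m)] <- bits
      m <- m | t(m)
      letters_vec <- compact_letter_display(m)
      expect_true(cld_consistent(letters_vec, m))
    }
  }
  set.seed(33)
  for (rep in 1:100) {
    k <- sample(5:6, 1)
    m <- random_sig_matrix(k)
    expect_true(cld_consistent(compact_letter_display(m), m))
  }
})

test_that("significance categories use right-closed bins", {
  expect_equal(significance_category(c(0.0004, 0.03, 0.2)),
               c("***", "*", "ns"))
  expect_equal(significance_category(0.001), "***")
  expect_equal(significance_category(0.01), "**")
  expect_equal(significance_category(0.05), "*")
  expect_equal(significance_category(0.0500001), "ns")
  expect_error(significance_category(1.2), "0, 1")
  expect_error(significance_category(-0.1), "0, 1")
})

test_that("the screening table mirrors the published layout", {
  set.seed(21)
  tbl <- blob_table(10)
  out <- anova_screen(tbl, group_by = "region")
  expect_equal(out$component, c("f1", "f2", "f3"))
  expect_true(all(c("A", "B", "C", "F", "p", "category") %in% names(out)))
  expect_match(out$A[1], "^-?[0-9.]+ ± [0-9.]+[a-z]+$")
  path <- withr::local_tempfile(fileext = ".csv")
  anova_screen(tbl, group_by = "region", path = path)
  expect_true(file.exists(path))
})
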