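test_that("chemotaxis index follows its formula, bounds, and antisymmetry", {
  expect_equal(chemotaxis_index(15, 5), 0.5)
  expect_equal(chemotaxis_index(7, 7), 0)
  expect_equal(chemotaxis_index(0, 20), -1)
  expect_equal(chemotaxis_index(20, 0), 1)
  set.seed(4)
  for (i in 1:50) {
    a <- sample(0:50, 1); b <- sample(0:50, 1)
    if (a + b == 0) next
    ci <- chemotaxis_index(a, b)
    expect_gte(ci, -1); expect_lte(ci, 1)
    expect_equal(chemotaxis_index(b, a), -ci)
  }
  expect_error(chemotaxis_index(0, 0), class = "invalid_argument")
})

test_that("two-group tests give symmetric, sensible p-values", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(compare_two(x, x, "mann_whitney")$p_value, 1)
  expect_gt(compare_two(x, x + 1e-9, "welch_t")$p_value, 0.99)
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(10.3, 12.1, 9.8, 11.5)
  for (m in c("welch_t", "mann_whitney")) {
    r1 <- compare_two(a, b, m)
    r2 <- compare_two(b, a, m)
    expect_equal(r1$p_value, r2$p_value)
  }
  expect_error(compare_two(1, c(1, 2), "welch_t"), class = "invalid_argument")
  expect_error(compare_two(c(2, 2, 2), c(2, 2), "welch_t"),
               class = "invalid_argument")
})

test_that("exact Mann-Whitney p matches full enumeration of rank assignments", {
  expect_equal(compare_two(c(1, 2, 3), c(101, 102, 103),
                           "mann_whitney")$p_value,
               oracle_mann_whitney_p(c(1, 2, 3), c(101, 102, 103)))
  set.seed(11)
  for (i in 1:40) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    v <- sample(1000, n1 + n2)  # distinct values: exact test applies
    a <- v[1:n1]; b <- v[-(1:n1)]
    expect_equal(compare_two(a, b, "mann_whitney")$p_value,
                 oracle_mann_whitney_p(a, b))
  }
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  expect_equal(compare_categorical(matrix(c(5, 0, 0, 5), 2))$p_value,
               2 / 252, tolerance = 1e-12)
  # identical rows: no association
  expect_equal(compare_categorical(matrix(c(4, 4, 7, 7), 2))$p_value, 1)
  set.seed(12)
  for (i in 1:40) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(compare_categorical(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
    expect_equal(compare_categorical(t(tab))$p_value,
                 compare_categorical(tab)$p_value)
  }
  expect_error(compare_categorical(matrix(c(0, 0, 3, 4), 2)),
               class = "invalid_argument")
})

test_that("Kruskal-Wallis with Dunn posttest adjusts p upward", {
  set.seed(5)
  v <- stats::rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  res <- compare_multi(v, g, "kruskal_dunn")
  expect_equal(res$test_name, "kruskal_dunn")
  expect_true(all(res$comparisons$p_adj >= res$comparisons$p_raw - 1e-12))
  expect_true(all(res$comparisons$p_adj <= 1))
  # vs-reference mode restricts the comparison set
  res_ref <- compare_multi(v, g, "kruskal_dunn", ref = "a")
  expect_equal(nrow(res_ref$comparisons), 2)
  # observation order is irrelevant
  perm <- sample(30)
  expect_equal(compare_multi(v[perm], g[perm], "kruskal_dunn")$p_value,
               res$p_value)
})

test_that("Dunnett posttest compares each group to the reference", {
  set.seed(6)
  v <- c(stats::rnorm(10), stats::rnorm(10) + 3, stats::rnorm(10))
  g <- rep(c("ctrl", "hi", "same"), each = 10)
  res <- compare_multi(v, g, "anova_dunnett", ref = "ctrl")
  expect_equal(nrow(res$comparisons), 2)
  hi <- res$comparisons[grepl("hi", res$comparisons$pair), ]
  same <- res$comparisons[grepl("same", res$comparisons$pair), ]
  expect_lt(hi$p_adj, 0.01)
  expect_gt(same$p_adj, 0.1)
  expect_true(all(res$comparisons$p_adj >= res$comparisons$p_raw - 1e-9))
})

test_that("two-way ANOVA Sidak posttest matches the closed-form adjustment", {
  set.seed(8)
  d <- data.frame(group = rep(c("g1", "g2", "g3"), each = 12),
                  condition = rep(rep(c("air", "CO2"), each = 6), 3))
  v <- stats::rnorm(36) + ifelse(d$group == "g2" & d$condition == "CO2", 2, 0)
  res <- compare_multi(v, method = "anova2_sidak", design = d)
  expect_equal(nrow(res$comparisons), 3)
  expect_equal(res$comparisons$p_adj,
               1 - (1 - res$comparisons$p_raw)^3, tolerance = 1e-12)
  expect_true(all(res$comparisons$p_adj >= res$comparisons$p_raw - 1e-12))
  expect_error(
    compare_multi(v, method = "anova2_sidak",
                  design = data.frame(group = d$group,
                                      condition = "only_one")),
    class = "invalid_argument"
  )
})
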