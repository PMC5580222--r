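# Rank tests, ANOVA, correlation and p-value adjustment against brute-force
# oracles and their invariance properties.

test_that("paired_wilcoxon matches exhaustive sign enumeration", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_equal(paired_wilcoxon(a, a)$p_value, 1)
  # extreme one-direction shift: p equals enumeration over all 2^6 signs
  b <- a + 10
  expect_equal(paired_wilcoxon(b, a)$p_value,
               oracle_signed_rank_p(b - a), tolerance = 1e-12)
  # non-degenerate mixed-sign case
  set.seed(3)
  x <- rnorm(8); y <- x + rnorm(8, 0.8)
  expect_equal(paired_wilcoxon(y, x)$p_value,
               oracle_signed_rank_p(y - x), tolerance = 1e-12)
  # 13-24 pairs, no ties: exact signed-rank distribution path
  set.seed(4)
  x <- rnorm(15); y <- x + rnorm(15, 0.5)
  d <- y - x
  v <- sum(rank(abs(d))[d > 0])
  p_ref <- 2 * min(psignrank(v, 15), psignrank(v - 1, 15, lower.tail = FALSE))
  expect_equal(paired_wilcoxon(y, x)$p_value, min(1, p_ref), tolerance = 1e-12)
})

test_that("large-sample wilcoxon approximation tracks the exact distribution", {
  # moderate-p regime: approximation within 10% relative of the exact
  # signed-rank distribution
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30)
  d <- a - b
  v <- sum(rank(abs(d))[d > 0]); n <- length(d)
  p_exact <- 2 * min(psignrank(v, n), psignrank(v - 1, n, lower.tail = FALSE))
  p_impl <- paired_wilcoxon(a, b)$p_value
  expect_lt(abs(p_impl - p_exact) / p_exact, 0.10)
  # stated design point (shift 1, sd 1, n = 30): the p lands deep in the
  # tail, where the normal approximation is accurate on the log scale; the
  # test decision agrees exactly
  set.seed(1)
  a <- rnorm(30, 1); b <- rnorm(30, 0)
  d <- a - b
  v <- sum(rank(abs(d))[d > 0])
  p_exact <- 2 * min(psignrank(v, 30), psignrank(v - 1, 30, lower.tail = FALSE))
  p_impl <- paired_wilcoxon(a, b)$p_value
  expect_lt(abs(log10(p_impl) - log10(p_exact)) / abs(log10(p_exact)), 0.15)
  expect_identical(p_impl < 0.05, p_exact < 0.05)
})

test_that("paired_wilcoxon handles degenerate and missing input", {
  expect_equal(paired_wilcoxon(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(paired_wilcoxon(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  r <- paired_wilcoxon(c(1, NA, 3, 5), c(0, 7, NA, 4))
  expect_equal(r$n, 2)
  expect_error(paired_wilcoxon(1, c(1, 2)), "length")
})

test_that("mann_whitney matches exhaustive arrangement enumeration", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, oracle_mw_p(c(1, 2), c(3, 4)), tolerance = 1e-12)
  set.seed(7)
  a <- rnorm(5); b <- rnorm(6, 1)
  expect_equal(mann_whitney(a, b)$p_value, oracle_mw_p(a, b),
               tolerance = 1e-12)
  # symmetry and degenerate cases
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_error(mann_whitney(numeric(), c(1, 2)), "at least 2")
})

test_that("kruskal_wallis matches the rank-sum formula and reduces to MW", {
  g <- list(c(1, 1, 1), c(1, 1), c(1, 1, 1))
  expect_equal(kruskal_wallis(g)$statistic, 0)
  expect_equal(kruskal_wallis(g)$p_value, 1)
  set.seed(9)
  groups <- list(rnorm(4), rnorm(5, 1), rnorm(4, 2))
  expect_equal(kruskal_wallis(groups)$statistic, oracle_kw_h(groups),
               tolerance = 1e-10)
  # two groups: approximately the MW p (both chi-square/normal approximations)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  expect_lt(abs(kruskal_wallis(list(a, b))$p_value -
                  mann_whitney(a, b)$p_value), 0.05)
  expect_error(kruskal_wallis(list(1:5)), "at least 2 groups")
})

test_that("anova_group_effect matches explicit sums of squares", {
  # balanced 2x3 design, n = 4 per cell, planted group and block shifts
  set.seed(13)
  group <- rep(c("rr", "rs"), each = 12)
  block <- rep(rep(c("t0", "t2h", "t6h"), each = 4), 2)
  y <- rnorm(24) + 2.0 * (group == "rr") + 0.5 * (block == "t2h")
  r <- anova_group_effect(y, group, block)
  expect_equal(r$statistic, oracle_anova_f(y, group, block), tolerance = 1e-10)
  # identical values -> degenerate
  expect_equal(anova_group_effect(rep(1, 24), group, block)$p_value, 1)
  # balanced design: permuting block labels within blocks leaves F unchanged
  perm <- sample(levels(factor(block)))
  block2 <- perm[as.integer(factor(block))]
  expect_equal(anova_group_effect(y, group, block2)$statistic, r$statistic)
  # constant group -> degenerate
  expect_equal(anova_group_effect(y, rep("rr", 24), block)$p_value, 1)
  # single block level falls back to one-way
  r1 <- anova_group_effect(y[1:8], group[c(1:4, 13:16)], rep("t0", 8))
  expect_true(r1$p_value <= 1 && r1$statistic >= 0)
})

test_that("pearson_cor matches the direct formula and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_cor(x, -x)$statistic, -1)
  set.seed(17)
  a <- rnorm(10); b <- rnorm(10)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  r <- pearson_cor(a, b)
  expect_equal(r$statistic, r_direct, tolerance = 1e-12)
  t_stat <- r_direct * sqrt(8 / (1 - r_direct^2))
  expect_equal(r$p_value, 2 * pt(-abs(t_stat), 8), tolerance = 1e-12)
  d <- pearson_cor(rep(1, 5), a[1:5])
  expect_true(d$degenerate)
  expect_true(is.na(d$statistic))
})

test_that("adjust_pvalues implements step-down Holm and BH per hand computation", {
  expect_equal(adjust_pvalues(0.03, "holm"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "holm"), c(0.03, 0.04, 0.04))
  expect_equal(adjust_pvalues(rep(1, 4), "holm"), rep(1, 4))
  # BH hand computation: p*(m/rank), cumulative-min from the largest
  p <- c(0.01, 0.04, 0.03, 0.005)
  expect_equal(adjust_pvalues(p, "bh"), c(0.02, 0.04, 0.04, 0.02))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0,1\\]")
  # dominance properties at random p
  set.seed(19)
  for (i in 1:20) {
    p <- runif(15)
    for (m in c("holm", "bh")) {
      q <- adjust_pvalues(p, m)
      expect_true(all(q >= p - 1e-15))
      expect_true(all(q <= 1))
    }
  }
})

test_that("rank tests are invariant under strictly increasing transforms", {
  set.seed(23)
  transforms <- list(function(x) exp(x), function(x) 3 * x + 7,
                     function(x) x^3, function(x) atan(x))
  for (i in 1:25) {
    a <- rnorm(10); b <- rnorm(12, 0.5)
    f <- transforms[[1 + (i %% 4)]]
    expect_equal(mann_whitney(f(a), f(b))$p_value, mann_whitney(a, b)$p_value)
    expect_equal(kruskal_wallis(list(f(a), f(b)))$statistic,
                 kruskal_wallis(list(a, b))$statistic)
  }
})
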