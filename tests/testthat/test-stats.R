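# Statistical procedures, cross-checked against hand computations,
# brute-force/permutation oracles, and (independently) base R.

test_that("Spearman correlation handles the canonical cases", {
  expect_equal(spearman_rank(1:5, 5:1)$r_s, -1)
  expect_equal(spearman_rank(1:4, 1:4)$r_s, 1)

  # tied data against an explicit rank-then-Pearson oracle
  x <- c(1, 2, 2, 3); y <- c(10, 20, 20, 40)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 2.5, 2.5, 4)  # hand-computed midranks
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rank(x, y)$r_s, oracle, tolerance = 1e-15)

  expect_error(spearman_rank(rep(1, 5), 1:5),
               class = "icasflow_undefined_correlation_error")
  expect_error(spearman_rank(1:3, 1:4), class = "icasflow_stats_error")
})

test_that("Spearman agrees with base R and is monotone-invariant", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- x + rnorm(n)
    if (rep %% 2 == 0) { x <- round(x); y <- round(y, 1) }  # force ties
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    ours <- spearman_rank(x, y)
    expect_equal(ours$r_s,
                 suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
    # p cross-check against cor.test's asymptotic t (untied data only)
    if (rep %% 2 == 1) {
      ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
      expect_equal(ours$r_s, unname(ct$estimate), tolerance = 1e-12)
    }
    # invariance under strictly monotone transforms
    expect_equal(spearman_rank(exp(x), y)$r_s, ours$r_s, tolerance = 1e-12)
    expect_equal(spearman_rank(x, 3 * y - 7)$r_s, ours$r_s,
                 tolerance = 1e-12)
  }
})

test_that("partial Spearman reduces correctly in the limiting cases", {
  set.seed(3)
  x <- rnorm(20); y <- x + rnorm(20)
  covs <- data.frame(z = rep(1, 20))
  plain <- spearman_rank(x, y)
  adj <- partial_spearman(x, y, covs)
  expect_equal(adj$r_s, plain$r_s, tolerance = 1e-12)
  expect_equal(adj$p_value, plain$p_value, tolerance = 1e-12)

  # y fully explained by the covariate
  z <- rnorm(20)
  res <- partial_spearman(x, z, data.frame(z = z))
  expect_lt(abs(res$r_s), 1e-8)

  expect_error(
    partial_spearman(x, y, data.frame(a = 1:20, b = 2 * (1:20))),
    class = "icasflow_degenerate_adjustment_error")
})

test_that("partial Spearman matches an explicit projection oracle", {
  # 6-row worked set, residualised with the hat-matrix formula
  x <- c(3, 1, 4, 1, 5, 9)
  y <- c(2, 7, 1, 8, 2, 8)
  age <- c(61, 72, 65, 58, 70, 66)
  sex <- c(0, 1, 1, 0, 1, 0)
  rx <- rank(x); ry <- rank(y)
  X <- cbind(1, rank(age), rank(sex))
  P <- X %*% solve(t(X) %*% X) %*% t(X)
  ex <- rx - P %*% rx; ey <- ry - P %*% ry
  oracle <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  ours <- partial_spearman(x, y, data.frame(age_years = age, sex = sex))
  expect_equal(ours$r_s, oracle, tolerance = 1e-12)
  expect_equal(ours$df, 6 - 2 - 2)
})

test_that("Friedman statistic matches hand computation and base R", {
  # identical columns: null case
  m0 <- matrix(rep(1:6, 3), ncol = 3)
  f0 <- friedman_test(m0)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)

  # every block ranked (1, 2, 3): Q = 10, p = P(chisq_2 > 10)
  m1 <- matrix(rep(c(1, 2, 3), each = 5) + rep(0:4, 3) * 0.01, ncol = 3)
  f1 <- friedman_test(m1)
  expect_equal(f1$statistic, 10, tolerance = 1e-12)
  expect_equal(f1$p_value, pchisq(10, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  set.seed(12)
  for (rep in 1:10) {
    n <- sample(3:10, 1); k <- sample(3:5, 1)
    m <- matrix(rnorm(n * k), n, k)    # continuous: no ties
    ours <- friedman_test(m)
    base <- friedman.test(m)
    expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, base$p.value, tolerance = 1e-12)
    # invariance under within-block strictly monotone transforms
    m2 <- t(apply(m, 1, function(r) exp(2 * r) - min(r)))
    expect_equal(friedman_test(m2)$statistic, ours$statistic,
                 tolerance = 1e-12)
  }
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2)),
               class = "icasflow_stats_error")
})

test_that("Friedman p is consistent with an exact permutation null", {
  # 4 blocks x 3 locations: enumerate all 6^4 within-block permutations
  set.seed(5)
  m <- matrix(rnorm(12), 4, 3)
  q_obs <- friedman_test(m)$statistic
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  grid <- expand.grid(1:6, 1:6, 1:6, 1:6)
  qs <- apply(grid, 1, function(idx) {
    mm <- m
    for (b in 1:4) mm[b, ] <- mm[b, perms[[idx[b]]]]
    friedman_test(mm)$statistic
  })
  p_exact <- mean(qs >= q_obs - 1e-12)
  p_asym <- friedman_test(m)$p_value
  # chi-square approximation within 3 SE of the exact null at this size
  se <- sqrt(p_exact * (1 - p_exact) / length(qs)) + 0.05
  expect_lt(abs(p_asym - p_exact), max(3 * se, 0.06))
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(c(0.9, 0.9)), c(1, 1))
  expect_equal(bonferroni_adjust(0.3), 0.3)
  expect_equal(bonferroni_adjust(rep(0.004, 10)), rep(0.04, 10))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), class = "icasflow_stats_error")
})

test_that("Wilcoxon signed-rank matches exact enumeration and base R", {
  # large constant shift, n = 10: all signs positive, p = 2 / 2^10
  a <- rnorm(10); b <- a + 100
  res <- wilcoxon_signed_rank(b, a)
  expect_equal(res$statistic, 55)
  expect_equal(res$p_value, 2 / 1024, tolerance = 1e-12)

  # identical vectors: degenerate pair
  expect_equal(wilcoxon_signed_rank(a, a)$p_value, 1)

  set.seed(21)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)
    base <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$statistic, unname(base$statistic))
    expect_equal(ours$p_value, base$p.value, tolerance = 1e-12)
  }
  # normal approximation branch agrees with base R's corrected variance
  set.seed(22)
  x <- round(rnorm(40), 1); y <- round(rnorm(40), 1)
  ours <- wilcoxon_signed_rank(x, y)
  base <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                       correct = FALSE))
  expect_equal(ours$p_value, base$p.value, tolerance = 1e-10)
})

test_that("post-hoc pipeline adjusts pairwise Wilcoxon p-values", {
  set.seed(9)
  base_col <- rnorm(12)
  m <- cbind(a = base_col, b = base_col + 2 + rnorm(12, sd = 0.1),
             c = base_col + 4 + rnorm(12, sd = 0.1))
  ph <- pairwise_posthoc(m)
  expect_equal(nrow(ph$pairwise), 3)
  expect_equal(ph$pairwise$p_adjusted,
               bonferroni_adjust(ph$pairwise$p_value, 3))
  expect_true(all(ph$pairwise$p_adjusted >= ph$pairwise$p_value))

  # identical-column pair comes back with p = 1 (forced run)
  m2 <- cbind(a = base_col, b = base_col)
  ph2 <- pairwise_posthoc(m2, force = TRUE)
  expect_equal(ph2$pairwise$p_value, 1)

  # non-significant Friedman refuses the post-hoc unless forced
  set.seed(10)
  m3 <- matrix(rnorm(30), 10, 3)
  if (friedman_test(m3)$p_value > 0.05) {
    expect_error(pairwise_posthoc(m3), class = "icasflow_stats_error")
  }

  # Conover variant produces valid, symmetric results
  phc <- pairwise_posthoc(m, method = "conover")
  expect_true(all(phc$pairwise$p_value >= 0 & phc$pairwise$p_value <= 1))
  expect_lt(phc$pairwise$p_value[2], 0.05)  # a vs c strongly separated
})

test_that("chi-square independence matches hand computation and base R", {
  res <- chi_square_independence(matrix(c(10, 20, 20, 10), 2))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)

  # proportional rows: exact independence
  res0 <- chi_square_independence(matrix(c(10, 20, 30, 60), 2))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)

  res4 <- chi_square_independence(matrix(c(5, 6, 7, 8, 9, 10, 11, 12), 4))
  expect_equal(res4$df, 3)

  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(rpois(6, 20) + 1, 2, 3)
    ours <- chi_square_independence(m)
    base <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, base$p.value, tolerance = 1e-12)
  }
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)),
               class = "icasflow_stats_error")
  expect_error(chi_square_independence(matrix(c(1.5, 2, 1, 2), 2)),
               class = "icasflow_stats_error")
})

test_that("Cohen's kappa matches its definition", {
  expect_equal(cohen_kappa(diag(c(12, 18)))$statistic, 1)
  # hand computation: p_o = 0.7, p_e = 0.5
  expect_equal(cohen_kappa(matrix(c(20, 10, 5, 15), 2))$statistic, 0.4,
               tolerance = 1e-12)
  # observed agreement at chance level
  expect_equal(cohen_kappa(matrix(c(9, 21, 21, 49), 2))$statistic, 0,
               tolerance = 1e-12)
  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2)),
               class = "icasflow_undefined_kappa_error")
})

test_that("threshold-split correlation separates the severity subgroups", {
  tab <- data.frame(percent_stenosis = c(seq(20, 45, length.out = 8),
                                         seq(52, 80, length.out = 8)))
  tab$index <- tab$percent_stenosis^2   # strictly monotone in both groups
  res <- threshold_split_correlation(tab, "index", adjust = NULL)
  expect_equal(res$below$r_s, 1)
  expect_equal(res$at_or_above$r_s, 1)
  expect_equal(res$below$n, 8)

  tab_small <- tab[tab$percent_stenosis < 50, , drop = FALSE]
  expect_error(threshold_split_correlation(tab_small, "index", adjust = NULL),
               class = "icasflow_subgroup_size_error")
  expect_error(threshold_split_correlation(tab, "missing", adjust = NULL),
               class = "icasflow_stats_error")
})
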