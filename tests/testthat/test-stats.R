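test_that("normality routing accepts Gaussians and flags bimodal samples", {
  set.seed(81)
  hits <- mean(replicate(400, normality_check(rnorm(50))$normal))
  expect_lt(abs(hits - 0.95), 0.05)
  bimodal <- mean(replicate(200, {
    x <- c(rnorm(50, -4), rnorm(50, 4))
    normality_check(x)$normal
  }))
  expect_lt(bimodal, 0.01)
  expect_warning(res <- normality_check(rep(1, 10)), "constant")
  expect_false(res$normal)
  expect_error(normality_check(c(1, 2)), "n >= 3")
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  res <- oneway_anova(groups)
  expect_equal(res$statistic, anova_f_oracle(groups))
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
  # identical groups: F = 0, p = 1
  same <- oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # two groups: F equals the square of the pooled t statistic
  set.seed(82)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  f2 <- oneway_anova(list(a, b))$statistic
  t2 <- unname(t.test(a, b, var.equal = TRUE)$statistic)^2
  expect_equal(f2, t2, tolerance = 1e-10)
  expect_warning(deg <- oneway_anova(list(c(1, 1), c(1, 1))), "zero variance")
  expect_equal(deg$statistic, 0)
})

test_that("Friedman statistic matches the rank formula", {
  # identical ranking across 10 subjects, 3 conditions: maximal statistic 20
  m <- matrix(rep(c(1, 5, 9), each = 10), 10, 3) + runif(30, 0, 0.1)
  res <- friedman_test(m)
  expect_equal(res$statistic, 20, tolerance = 1e-9)
  expect_equal(res$statistic, friedman_oracle(m), tolerance = 1e-9)
  expect_equal(res$df1, 2)
  # random (no-tie) matrices agree with the brute-force rank formula
  set.seed(83)
  for (i in 1:20) {
    m2 <- matrix(rnorm(8 * 4), 8, 4)
    expect_equal(friedman_test(m2)$statistic, friedman_oracle(m2), tolerance = 1e-9)
  }
  # two conditions: statistic reduces to the sign-test form (2k - n)^2 / n
  for (i in 1:10) {
    m3 <- matrix(rnorm(12), 6, 2)
    k <- sum(m3[, 1] > m3[, 2])
    expect_equal(friedman_test(m3)$statistic, (2 * k - 6)^2 / 6, tolerance = 1e-9)
  }
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
  # invariance under a strictly monotone transform
  m4 <- matrix(rnorm(24), 6, 4)
  expect_equal(friedman_test(m4)$statistic, friedman_test(exp(m4))$statistic)
})

test_that("Mann-Whitney exact enumeration matches brute force at small n", {
  # spec example: x = {1,2}, y = {3,4} -> U = 0, two-sided p = 1/3
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3)
  # identical multisets -> U = nx ny / 2
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 4.5)
  # all arrangements of distinct values at n_x = n_y in {2, ..., 6}
  for (n in 2:6) {
    vals <- seq_len(2 * n)
    sel <- utils::combn(2 * n, n)
    for (j in seq_len(ncol(sel))) {
      x <- vals[sel[, j]]; y <- vals[-sel[, j]]
      ours <- mann_whitney_u(x, y)
      expect_equal(ours$statistic, u_statistic(x, y))
      expect_equal(ours$p_value, mw_brute_force_p(x, y), tolerance = 1e-12)
    }
  }
  # rank-test invariance under monotone transforms
  set.seed(84)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(mann_whitney_u(x, y)$p_value,
               mann_whitney_u(exp(x), exp(y))$p_value)
  # approximation close to exact at the crossover size
  x12 <- rnorm(6); y12 <- rnorm(6, 0.8)
  pe <- mann_whitney_u(x12, y12, exact = TRUE)$p_value
  pa <- mann_whitney_u(x12, y12, exact = FALSE)$p_value
  expect_lt(abs(pe - pa), 0.03)
})

test_that("vs-control comparisons are family-wise adjusted", {
  set.seed(85)
  # identical groups: all adjusted p = 1
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  res <- control_comparisons(g, 1, "holm_t")
  expect_true(all(res$p_value == 1))
  expect_true(all(res$adjusted))
  # adjusted p >= unadjusted p
  groups <- lapply(1:5, function(i) rnorm(10, mean = i / 4))
  adj <- control_comparisons(groups, 1, "holm_t")
  raw <- vapply(2:5, function(i)
    t.test(groups[[i]], groups[[1]])$p.value, 1)
  expect_true(all(adj$p_value >= raw - 1e-12))
  adj2 <- control_comparisons(groups, 1, "dunn_bonferroni")
  raw2 <- vapply(2:5, function(i)
    suppressWarnings(wilcox.test(groups[[i]], groups[[1]])$p.value), 1)
  expect_true(all(adj2$p_value >= raw2 - 1e-12))
  expect_error(control_comparisons(groups, 9), "control index")
  # power: a single 2 SD shifted group among 5 is the one detected
  hits <- replicate(60, {
    gs <- c(lapply(1:4, function(i) rnorm(20)), list(rnorm(20, 2)))
    res <- control_comparisons(gs, 1, "holm_t")
    sig <- res$p_value < 0.05
    sig[4] && sum(sig[1:3]) == 0
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Pearson correlation matches the hand-computed oracle", {
  exact <- pearson_correlation(1:5, 2 * (1:5) + 1)
  expect_equal(exact$r, 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  # hand oracle: S_xy = 8, S_xx = S_yy = 10 -> r = 0.8
  res <- pearson_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(res$r, 0.8)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
  expect_error(pearson_correlation(1:2, 2:3), "n >= 3")
})

test_that("behavior-signal correlation recovers a constructed dependency", {
  set.seed(86)
  keys <- expand.grid(animal_id = paste0("a", 1:8), group = "motor-parietal",
                      day = 1:3, phase = "post", stringsAsFactors = FALSE)
  behavior <- cbind(keys, mean_score = runif(nrow(keys), 0, 4))
  signal <- cbind(keys[rep(seq_len(nrow(keys)), each = 2), ],
                  band = rep(c("beta", "delta"), nrow(keys)))
  # beta coherence decreasing in score; delta independent
  signal$msc <- ifelse(signal$band == "beta",
                       0.8 - 0.15 * behavior$mean_score[rep(seq_len(nrow(keys)), each = 2)] +
                         rnorm(nrow(signal), 0, 0.02),
                       runif(nrow(signal), 0.2, 0.4))
  out <- correlate_behavior_signal(signal, behavior, value_col = "msc")
  expect_lt(out$r[out$band == "beta"], -0.9)
  expect_lt(out$p_value[out$band == "beta"], 1e-6)
  expect_gt(out$p_value[out$band == "delta"], 1e-4)
  # zero score variance -> undefined, not dropped
  behavior2 <- behavior; behavior2$mean_score <- 4
  out2 <- correlate_behavior_signal(signal, behavior2, value_col = "msc")
  expect_true(all(is.na(out2$r)))
  expect_true(all(out2$note == "zero variance"))
  # empty join warns and returns empty
  behavior3 <- behavior; behavior3$day <- behavior3$day + 100
  expect_warning(out3 <- correlate_behavior_signal(signal, behavior3, "msc"),
                 "empty join")
  expect_identical(nrow(out3), 0L)
})
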