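test_that("pearson_r matches the closed form and the stats oracle", {
  set.seed(101)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    ours <- pearson_r(x, y)
    ref <- cor.test(x, y)
    expect_equal(unname(ours$estimate), unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(unname(pearson_r(1:10, 1:10)$estimate), 1)
  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:3, 1:4), "equal length")

  set.seed(7)
  x <- rnorm(10000); y <- rnorm(10000)
  expect_lt(abs(unname(pearson_r(x, y)$estimate)), 0.05)
})

test_that("pearson_r is invariant to positive affine transforms", {
  set.seed(5)
  x <- rnorm(20); y <- rnorm(20)
  a <- pearson_r(x, y)
  b <- pearson_r(3 * x + 7, 0.5 * y - 2)
  expect_equal(unname(a$estimate), unname(b$estimate), tolerance = 1e-12)
  expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
})

test_that("kendall tau-b matches O(n^2) pair counting with heavy ties", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    ours <- kendall_tau_b(x, y)
    # oracle: explicit pair loop
    C <- 0; D <- 0
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      s <- sign(x[p] - x[q]) * sign(y[p] - y[q])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
    n0 <- n * (n - 1) / 2
    tx <- table(x); ty <- table(y)
    tau_oracle <- (C - D) / sqrt((n0 - sum(tx * (tx - 1) / 2)) *
                                 (n0 - sum(ty * (ty - 1) / 2)))
    expect_equal(unname(ours$estimate), tau_oracle, tolerance = 1e-12)
    # and against the stats implementation of the estimate
    expect_equal(unname(ours$estimate),
                 unname(suppressWarnings(cor.test(x, y, method = "kendall")$estimate)),
                 tolerance = 1e-12)
  }
})

test_that("kendall tau-b has the expected symmetries and edge behavior", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  expect_equal(unname(kendall_tau_b(x, y)$estimate), 1)
  expect_equal(unname(kendall_tau_b(x, rev(y))$estimate), -1)
  set.seed(9)
  a <- sample(1:3, 15, replace = TRUE); b <- sample(1:3, 15, replace = TRUE)
  expect_equal(unname(kendall_tau_b(a, b)$estimate),
               -unname(kendall_tau_b(a, -b)$estimate), tolerance = 1e-12)
  # invariance to strictly monotone transforms
  expect_equal(unname(kendall_tau_b(a, b)$estimate),
               unname(kendall_tau_b(exp(a), b^3)$estimate), tolerance = 1e-12)
  expect_error(kendall_tau_b(rep(1, 5), 1:5), "all x values tied")
})

test_that("kruskal_wallis matches the stats oracle including ties", {
  set.seed(303)
  for (i in 1:5) {
    g <- list(round(rnorm(8), 1), round(rnorm(12), 1), round(rnorm(6), 1))
    ours <- kruskal_wallis(g)
    ref <- kruskal.test(g)
    expect_equal(unname(ours$statistic), unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
  allsame <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(unname(allsame$statistic), 0)
  expect_equal(allsame$p.value, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric())), "empty group")
})

test_that("two-group kruskal_wallis agrees with the rank-sum test", {
  set.seed(404)
  a <- rnorm(25); b <- rnorm(25, 0.4)
  p_kw <- kruskal_wallis(list(a, b))$p.value
  p_w <- wilcoxon_rank_sum(a, b)$p.value
  expect_lt(abs(p_kw - p_w), 0.01)
})

test_that("wilcoxon_rank_sum matches stats and the exact permutation law", {
  set.seed(505)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  ours <- wilcoxon_rank_sum(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(unname(ours$statistic), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)

  # exact permutation oracle at small n
  for (i in 1:3) {
    a <- rnorm(6); b <- rnorm(7)
    approx_p <- wilcoxon_rank_sum(a, b)$p.value
    exact_p <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_lt(abs(approx_p - exact_p), 0.02)
  }

  same <- wilcoxon_rank_sum(c(1, 2, 3), c(3, 1, 2))
  expect_gt(same$p.value, 0.9)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "empty")
})

test_that("two_sample_t is the Welch test", {
  a <- c(1.1, 2.3, 0.7); b <- c(2.0, 2.5, 3.1)
  ours <- two_sample_t(a, b)
  ref <- t.test(a, b)
  expect_equal(unname(ours$statistic), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(unname(ours$parameter), unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero variance")
})

test_that("holm_adjust is the step-down rule, order-preserving and capped", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  set.seed(606)
  for (i in 1:10) {
    p <- runif(sample(1:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, method = "holm"), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order-consistent
  }
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("null simulations are calibrated at the nominal level", {
  set.seed(707)
  rej_t <- mean(replicate(400, two_sample_t(rnorm(15), rnorm(15))$p.value < 0.05))
  expect_gt(rej_t, 0.02); expect_lt(rej_t, 0.08)
  ps <- replicate(300, {
    d <- data.frame(subtype = sample(rep(c("basal", "luminal_A"), 15)),
                    v = rnorm(30))
    kruskal_wallis(split(d$v, d$subtype))$p.value
  })
  # permuted labels: p approximately uniform
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.08)
})

test_that("wilcoxon power grows with the location shift", {
  set.seed(808)
  mean_p <- vapply(c(0, 0.5, 1.5), function(shift) {
    mean(replicate(150, wilcoxon_rank_sum(rnorm(12), rnorm(12, shift))$p.value))
  }, numeric(1))
  expect_true(all(diff(mean_p) < 0))
})

test_that("cn_expression_report integrates correlation, group and pairwise tests", {
  d <- simulate_cn_expression(
    600, target_r = 0.4,
    subtype_effects = list(basal = c(0.5, 1.5), luminal_A = c(0, 0),
                           HER2 = c(0, 0)),
    proportions = c(basal = 0.4, luminal_A = 0.3, HER2 = 0.3), seed = 13)
  rep <- cn_expression_report(d)
  expect_s3_class(rep, "cn_expression_report")
  expect_gt(unname(rep$correlation$estimate), 0.3)
  expect_lt(rep$group_tests$log2_expr$p.value, 1e-6)
  pw <- rep$pairwise
  expect_setequal(pw$subtype, c("luminal_A", "HER2"))
  # the injected basal shift makes expression the most significant variable
  expect_lt(min(pw$p_holm[pw$variable == "log2_expr"]),
            min(pw$p_holm[pw$variable == "log2_cn"]) + 1e-12)
  expect_true(all(pw$p_holm >= pw$p_value))
  expect_match(rep$note, "Holm")
  expect_output(print(rep), "Pearson")

  single <- d[d$subtype == "basal", ]
  expect_error(cn_expression_report(single), ">= 2 subtypes")
  expect_error(cn_expression_report(d, reference_subtype = "normal_like"),
               "not present")
})
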