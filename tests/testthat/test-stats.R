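test_that("normality gate passes Gaussian and rejects heavy-tailed samples", {
  set.seed(101)
  x <- rnorm(50)
  expect_identical(normality_gate(x)$verdict, "normal")
  y <- c(rep(0, 40), rep(100, 10))
  expect_identical(normality_gate(y)$verdict, "non_normal")
  expect_identical(normality_gate(rep(3, 10))$verdict, "non_normal")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("exact Mann-Whitney matches hand enumeration and symmetry", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$method, "exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)               # 2 * 1/20
  same <- mann_whitney(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p, 1)
})

test_that("exact Mann-Whitney agrees with wilcox.test on tie-free samples", {
  set.seed(7)
  for (i in 1:30) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    vals <- sample(1:1000, na + nb)          # distinct: tie-free
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    mine <- mann_whitney(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
  }
})

test_that("exact Mann-Whitney equals a brute-force permutation oracle with ties", {
  set.seed(8)
  for (i in 1:15) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    vals <- sample(1:6, na + nb, replace = TRUE)  # plenty of ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    mine <- mann_whitney(a, b)
    # oracle: enumerate all label assignments independently
    r <- rank(c(a, b))
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2, function(s) sum(r[s])) - na * (na + 1) / 2
    u0 <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    p_oracle <- min(1, 2 * min(mean(us <= u0 + 1e-9), mean(us >= u0 - 1e-9)))
    expect_equal(mine$p, p_oracle, tolerance = 1e-12)
  }
})

test_that("three identical groups give a null omnibus result", {
  # heavy-tailed values fail the normality gate, forcing the KW path
  v <- c(rep(0, 8), 50, 100)
  res <- compare_three_groups(list(a = v, b = v, c = v))
  expect_identical(res$test, "kruskal_wallis")
  expect_equal(res$statistic, 0, tolerance = 1e-9)
  expect_gt(res$p, 0.99)
  # near-uniform identical groups pass the gate; the ANOVA F is 0, p = 1
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res2 <- compare_three_groups(g)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-9)
})

test_that("clearly separated normal groups take the ANOVA path with tiny p", {
  g <- list(a = c(1, 2, 3), b = c(11, 12, 13), c = c(21, 22, 23))
  res <- compare_three_groups(g)
  expect_identical(res$test, "anova")
  expect_equal(res$statistic, 300, tolerance = 1e-9)  # closed-form F
  expect_lt(res$p, 0.001)
  expect_identical(nrow(res$pairwise), 3L)
})

test_that("Bonferroni adjustment is min(1, m p) and never decreases", {
  expect_equal(bonferroni(0.02, m = 3), 0.06)
  expect_equal(bonferroni(0.5, m = 3), 1)
  p <- runif(10)
  expect_true(all(bonferroni(p, 4) >= p))
  expect_true(all(bonferroni(p, 4) <= 1))
})

test_that("correlation strength labels follow the r cutoffs", {
  x <- 1:20
  r1 <- correlate(x, 2 * x + 1, method = "pearson")
  expect_equal(r1$r, 1)
  expect_identical(r1$label, "strong")
  # construct moderate correlation deterministically
  set.seed(5)
  repeat {
    y <- x + rnorm(20, 0, 12)
    r <- abs(cor(x, y))
    if (r > 0.42 && r < 0.68) break
  }
  expect_identical(correlate(x, y, method = "pearson")$label, "moderate")
  # monotone nonlinear transform: Spearman sees a perfect association
  r3 <- correlate(x, exp(x / 3), method = "spearman")
  expect_equal(r3$r, 1)
  expect_error(correlate(x, rep(1, 20)), "zero variance")
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(9)
  x <- rnorm(30); y <- rnorm(30)
  r0 <- correlate(x, y, method = "spearman")$r
  expect_equal(correlate(exp(x), y, method = "spearman")$r, r0)
  expect_equal(correlate(x, y^3, method = "spearman")$r, r0)
})

test_that("auto mode picks Pearson for normal data and Spearman otherwise", {
  set.seed(10)
  x <- rnorm(40); y <- x + rnorm(40, 0, 0.5)
  expect_identical(correlate(x, y)$method, "pearson")
  xh <- c(rnorm(35), 50, 60, 70, 80, 90)  # heavy outliers
  expect_identical(correlate(xh, seq_along(xh))$method, "spearman")
})

test_that("null rejection rates sit near the nominal level", {
  set.seed(42)
  n_rep <- 600
  rej_mw <- rej_kw <- 0
  for (i in seq_len(n_rep)) {
    a <- rnorm(6); b <- rnorm(6); c <- rnorm(6)
    if (mann_whitney(a, b)$p <= 0.05) rej_mw <- rej_mw + 1
    if (stats::kruskal.test(list(a, b, c))$p.value <= 0.05) rej_kw <- rej_kw + 1
  }
  expect_gt(rej_mw / n_rep, 0.02); expect_lt(rej_mw / n_rep, 0.09)
  expect_gt(rej_kw / n_rep, 0.02); expect_lt(rej_kw / n_rep, 0.09)
})

test_that("significance tiers follow the conventional thresholds", {
  expect_identical(significance_tier(c(0.2, 0.04, 0.009, 0.0005)),
                   c("ns", "*", "**", "***"))
})
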