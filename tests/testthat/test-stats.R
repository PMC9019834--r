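test_that("paired t matches a brute-force computation from the t CDF", {
  x <- c(2.1, 1.9, 2.4, 2.0); y <- c(1.8, 1.7, 2.0, 1.9)
  res <- paired_t(x, y, tail = "greater")
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p, pt(t_hand, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # constant differences: t undefined via zero variance
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
  # symmetric data: one-tailed p = 0.5 at t = 0
  sym <- paired_t(c(1, 2, 3, 4), c(2, 1, 4, 3), tail = "greater")
  expect_equal(sym$t, 0, tolerance = 1e-12)
  expect_equal(sym$p, 0.5, tolerance = 1e-12)
})

test_that("signed-rank exact p equals full 2^n enumeration", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(5:10, 1)
    x <- round(rnorm(n, 3, 1), 1)
    y <- round(rnorm(n, 3, 1), 1)
    if (all(x == y)) x[1] <- x[1] + 0.5
    for (tail in c("two.sided", "greater", "less")) {
      res <- wilcoxon_signed_rank(x, y, tail = tail)
      expect_equal(res$p, enumerate_signed_rank_p(x - y, tail),
                   tolerance = 1e-12)
    }
  }
  # strictly positive differences, n = 10: one-sided p = 2^-10
  res <- wilcoxon_signed_rank(11:20 + 0.5, 11:20 - 0.5, tail = "greater")
  expect_equal(res$p, 2^-10, tolerance = 1e-15)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
})

test_that("signed-rank handles ties and large-sample approximation", {
  # heavy ties: exact (conditional) enumeration still applies
  x <- c(3, 3, 4, 4, 5, 5, 2, 2)
  y <- c(2, 2, 3, 5, 4, 4, 3, 1)
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$p, enumerate_signed_rank_p(x - y), tolerance = 1e-12)
  # tie-free case agrees with the base implementation
  set.seed(4)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(x, y)$p,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # n > exact_max switches to the continuity-corrected normal approximation
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40) - 0.5
  res_n <- wilcoxon_signed_rank(x, y)
  expect_equal(res_n$method, "normal approximation")
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(res_n$p, ref$p.value, tolerance = 1e-10)
})

test_that("spearman equals rank-then-Pearson with averaged tied ranks", {
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  res <- spearman_cor(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8)^3)$rho, -1)
  # one-tailed p halves the two-tailed p for positive rho
  set.seed(6)
  a <- rnorm(20); b <- a + rnorm(20)
  expect_equal(spearman_cor(a, b, "greater")$p,
               spearman_cor(a, b, "two.sided")$p / 2, tolerance = 1e-10)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(0.07, 5)), rep(0.07, 5))
  # hand computation: min over k >= i of p(k) * m / k, monotone
  p <- c(0.001, 0.04, 0.02, 0.9, 0.05)
  m <- length(p); o <- order(p)
  hand <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  hand[o] <- rev(cummin(rev(sorted)))
  expect_equal(fdr_bh(p), pmin(hand, 1))
  expect_true(all(fdr_bh(p) >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("VIF matches the closed form and the car oracle", {
  set.seed(7)
  # mutually orthogonal, mean-zero predictors -> VIF exactly 1
  X <- unclass(poly(1:100, 3))
  colnames(X) <- c("a", "b", "c")
  expect_equal(vif_table(X)$vif, rep(1, 3), tolerance = 1e-10)
  # two predictors with correlation 0.6 -> 1/(1-0.36)
  z <- rnorm(4000)
  a <- z; b <- 0.6 * z + sqrt(1 - 0.36) * rnorm(4000)
  ab <- cbind(a = a, b = b)
  r2 <- cor(a, b)^2
  expect_equal(vif_table(ab)$vif, rep(1 / (1 - r2), 2), tolerance = 1e-10)
  # duplicated predictor -> infinite
  dup <- cbind(a = a, b = b, a2 = a)
  expect_true(all(is.infinite(vif_table(dup)$vif[c(1, 3)])))
  if (requireNamespace("car", quietly = TRUE)) {
    y <- rnorm(4000)
    fit <- lm(y ~ a + b + I(rnorm(4000)))
    expect_equal(unname(vif_table(model.matrix(fit)[, -1])$vif),
                 unname(car::vif(fit)), tolerance = 1e-8)
  }
})

test_that("partial correlation equals the residual-correlation definition", {
  set.seed(8)
  z <- rnorm(60); x <- z + rnorm(60); y <- -z + rnorm(60)
  pc <- partial_cor(x, y, data.frame(z = z))
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-12)
  expect_equal(pc$df, 57)
})
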