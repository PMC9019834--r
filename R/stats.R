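#' Paired t-test
#'
#' Thin wrapper around [stats::t.test()] with explicit degenerate-input
#' handling and a tail argument.
#'
#' @param x,y Paired numeric vectors (length >= 3).
#' @param tail `"two.sided"`, `"greater"` (x > y) or `"less"`.
#' @return List: `t`, `df`, `p`, `mean_diff`, `tail`.
#' @export
paired_t <- function(x, y, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 complete pairs required")
  d <- x - y
  if (sd(d) == 0) stop("zero-variance differences: paired t undefined")
  ht <- t.test(x, y, paired = TRUE, alternative = tail)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), tail = tail)
}

# Exact null distribution of the signed-rank statistic W+ for the observed
# (tie-averaged) ranks, via dynamic programming over doubled ranks.
signed_rank_exact_p <- function(w, ranks, tail) {
  r2 <- as.integer(round(2 * ranks))    # average ranks are multiples of 1/2
  total <- sum(r2)
  f <- numeric(total + 1); f[1] <- 1    # f[k+1] = #subsets with sum k
  for (r in r2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  probs <- f / 2^length(r2)
  w2 <- as.integer(round(2 * w))
  p_ge <- sum(probs[(w2 + 1):(total + 1)])
  p_le <- sum(probs[1:(w2 + 1)])
  switch(tail,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped and tied absolute differences receive
#' average ranks. The p-value is exact (conditional on the observed ranks,
#' computed from the full sign-assignment null distribution) for up to
#' `exact_max` retained pairs, and otherwise uses the normal approximation
#' with continuity correction.
#'
#' @param x,y Paired numeric vectors.
#' @param tail `"two.sided"` (default), `"greater"` (x > y) or `"less"`.
#' @param exact_max Largest n for the exact distribution (default 25).
#' @return List: `W` (sum of positive-difference ranks), `n` (retained
#'   pairs), `p`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 tail = c("two.sided", "greater", "less"),
                                 exact_max = 25) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  d <- (x - y)[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(w, r, tail)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    cc <- 0.5
    p_ge <- pnorm((w - mu - cc) / sigma, lower.tail = FALSE)
    p_le <- pnorm((w - mu + cc) / sigma)
    p <- switch(tail, greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "normal approximation"
  }
  list(W = w, n = n, p = p, method = method, tail = tail)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p-value from the
#' t-approximation (via [stats::cor.test()]), one- or two-tailed.
#'
#' @param x,y Numeric vectors (n >= 4).
#' @param tail `"two.sided"`, `"greater"` (positive association) or
#'   `"less"`.
#' @return List: `rho`, `n`, `p`, `tail`.
#' @export
spearman_cor <- function(x, y, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("at least 4 complete pairs required")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: rho undefined")
  ht <- cor.test(x, y, method = "spearman", exact = FALSE, alternative = tail)
  list(rho = unname(ht$estimate), n = length(x), p = ht$p.value, tail = tail)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1), via
#' [stats::p.adjust()].
#'
#' @param p Vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing each predictor column on the
#' others; a perfectly collinear predictor reports `Inf`.
#'
#' @param X Numeric matrix or data frame of predictors (>= 2 columns;
#'   factors in a data frame are expanded via [stats::model.matrix()]).
#' @param flag_threshold Flag value (default 2).
#' @return Data frame: term, vif, flagged.
#' @export
vif_table <- function(X, flag_threshold = 2) {
  if (is.data.frame(X))
    X <- model.matrix(~ ., data = X)[, -1, drop = FALSE]
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("VIF requires at least 2 predictors")
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(term = colnames(X), vif = vifs,
             flagged = vifs > flag_threshold, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Partial Pearson correlation
#'
#' Correlation of the residuals of `x` and `y` after regressing each on
#' the control variables.
#'
#' @param x,y Numeric vectors.
#' @param controls Data frame or matrix of control variables.
#' @return List: `r`, `df` (n - 2 - n_controls), `p` (two-sided).
#' @export
partial_cor <- function(x, y, controls) {
  Z <- model.matrix(~ ., data = as.data.frame(controls))
  rx <- lm.fit(Z, x)$residuals
  ry <- lm.fit(Z, y)$residuals
  r <- cor(rx, ry)
  df <- length(x) - 2 - (ncol(Z) - 1)
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * pt(-abs(tval), df))
}
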