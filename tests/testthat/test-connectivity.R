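toy_matrix <- function(vals, names = paste0("r", seq_len(nrow(vals)))) {
  dimnames(vals) <- list(names, names)
  vals
}

test_that("beta correlation matrices follow hand Pearson computations", {
  b <- cbind(A = c(1, 2, 3, 4), B = c(1, 3, 2, 4))
  C <- beta_corr_matrix(b)
  expect_equal(C["A", "B"], 0.8)
  expect_equal(diag(C), c(A = 1, B = 1))
  ident <- cbind(A = c(1, 2, 3), B = c(1, 2, 3))
  expect_equal(beta_corr_matrix(ident)["A", "B"], 1)
  anti <- cbind(A = c(1, 2, 3), B = -c(1, 2, 3))
  expect_equal(beta_corr_matrix(anti)["A", "B"], -1)
  expect_error(beta_corr_matrix(cbind(A = c(1, 1, 1), B = c(1, 2, 3))), "A")
  expect_error(beta_corr_matrix(b[1:2, ]), "3 trials")
})

test_that("within/between means use the full pair partition", {
  rois <- default_rois()
  set.seed(1)
  b <- matrix(rnorm(24 * 14), 24, 14, dimnames = list(NULL, rois$name))
  C <- beta_corr_matrix(b)
  w_m <- within_network_mean(C, rois, "mentalizing")
  w_r <- within_network_mean(C, rois, "reward")
  bt <- between_network_mean(C, rois, "mentalizing", "reward")
  expect_equal(attr(w_m, "n_pairs"), 21)
  expect_equal(attr(w_r, "n_pairs"), 21)
  expect_equal(attr(bt, "n_pairs"), 49)
  expect_equal(21 + 21 + 49, choose(14, 2))
  # the three families together average every edge once
  all_edges <- mean(C[upper.tri(C)])
  expect_equal(as.numeric(21 * w_m + 21 * w_r + 49 * bt) / 91, all_edges,
               tolerance = 1e-12)
  # bounded by constituent edges
  expect_gte(w_m, min(C[1:7, 1:7][upper.tri(C[1:7, 1:7])]))
  expect_lte(w_m, max(C[1:7, 1:7][upper.tri(C[1:7, 1:7])]))
  expect_error(within_network_mean(C, rois, "nope"), "unknown")
  expect_error(between_network_mean(C, rois, "reward", "reward"), "distinct")
})

test_that("hand-built toys reproduce enumerated means and strengths", {
  rois3 <- data.frame(name = c("a", "b", "c"), network = "n1",
                      x = c(0, 30, 60), y = 0, z = 0, radius = 5)
  C3 <- toy_matrix(matrix(c(1, .1, .2, .1, 1, .6, .2, .6, 1), 3),
                   c("a", "b", "c"))
  expect_equal(as.numeric(within_network_mean(C3, rois3, "n1")), 0.3)
  rois4 <- data.frame(name = c("a", "b", "c", "d"),
                      network = c("n1", "n1", "n2", "n2"),
                      x = c(0, 30, 60, 90), y = 0, z = 0, radius = 5)
  C4 <- toy_matrix(matrix(c(1, .5, .1, .2,
                            .5, 1, .3, .4,
                            .1, .3, 1, .6,
                            .2, .4, .6, 1), 4), c("a", "b", "c", "d"))
  expect_equal(as.numeric(between_network_mean(C4, rois4, "n1", "n2")),
               mean(c(.1, .2, .3, .4)))
  ns <- node_strengths(C4, rois4)
  expect_equal(ns$within_strength, c(.5, .5, .6, .6))
  expect_equal(ns$between_strength, c(mean(c(.1, .2)), mean(c(.3, .4)),
                                      mean(c(.1, .3)), mean(c(.2, .4))))
  # double-counting identity: network mean equals mean of node strengths
  expect_equal(mean(ns$within_strength[1:2]),
               as.numeric(within_network_mean(C4, rois4, "n1")))
  rois_single <- rois4; rois_single$network <- c("n1", "n1", "n1", "n2")
  expect_error(node_strengths(C4, rois_single), "singleton")
})

test_that("summaries are invariant to node ordering", {
  rois <- default_rois()
  set.seed(2)
  b <- matrix(rnorm(30 * 14), 30, 14, dimnames = list(NULL, rois$name))
  C <- beta_corr_matrix(b)
  perm <- sample(14)
  Cp <- C[perm, perm]
  rois_p <- rois[perm, ]
  expect_equal(as.numeric(within_network_mean(C, rois, "reward")),
               as.numeric(within_network_mean(Cp, rois_p, "reward")))
  expect_equal(as.numeric(between_network_mean(C, rois, "mentalizing",
                                               "reward")),
               as.numeric(between_network_mean(Cp, rois_p, "mentalizing",
                                               "reward")))
  ns <- node_strengths(C, rois); nsp <- node_strengths(Cp, rois_p)
  expect_equal(ns[order(ns$name), ], nsp[order(nsp$name), ],
               ignore_attr = TRUE)
})

test_that("condition collapsing is an element-wise mean", {
  rois <- default_rois()
  set.seed(3)
  mats <- lapply(condition_levels(), function(cc)
    beta_corr_matrix(matrix(rnorm(24 * 14), 24, 14,
                            dimnames = list(NULL, rois$name))))
  names(mats) <- condition_levels()
  expect_equal(collapse_conditions(mats[c(1, 1)]), mats[[1]])
  avg <- collapse_conditions(mats)
  expect_equal(avg, (mats[[1]] + mats[[2]] + mats[[3]] + mats[[4]]) / 4)
  neg <- list(a = mats[[1]], b = toy_matrix(-mats[[1]],
                                            rownames(mats[[1]])))
  cz <- collapse_conditions(neg)
  expect_equal(max(abs(cz[upper.tri(cz)])), 0)
  bad <- mats; rownames(bad[[2]])[1] <- "other"
  expect_error(collapse_conditions(bad), "mismatched")
})
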