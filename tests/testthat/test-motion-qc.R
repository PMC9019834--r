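test_that("FD matches hand-computed step displacements", {
  # single 0.5 mm step in y between volumes 1 and 2
  m <- matrix(0, 5, 6)
  m[2:5, 2] <- 0.5
  expect_equal(compute_fd(m), c(0, 0.5, 0, 0, 0), tolerance = 1e-12)
  # single 0.01 rad step in pitch at 50 mm radius -> 0.5 mm arc
  m <- matrix(0, 4, 6)
  m[2:4, 4] <- 0.01
  expect_equal(compute_fd(m, head_radius = 50), c(0, 0.5, 0, 0),
               tolerance = 1e-12)
  # combined trace: sum of absolute backward differences
  set.seed(1)
  m <- matrix(rnorm(60), 10, 6)
  fd_hand <- c(0, rowSums(abs(diff(m[, 1:3]))) +
                 50 * rowSums(abs(diff(m[, 4:6]))))
  expect_equal(compute_fd(m), fd_hand, tolerance = 1e-12)
})

test_that("FD is shift-invariant and linear in head radius for rotations", {
  set.seed(2)
  m <- matrix(rnorm(120, sd = 0.1), 20, 6)
  shifted <- sweep(m, 2, runif(6, -5, 5), `+`)
  expect_equal(compute_fd(m), compute_fd(shifted), tolerance = 1e-12)
  rot_only <- m; rot_only[, 1:3] <- 0
  expect_equal(compute_fd(rot_only, head_radius = 100),
               2 * compute_fd(rot_only, head_radius = 50), tolerance = 1e-12)
  deg <- rot_only; deg[, 4:6] <- deg[, 4:6] * 180 / pi
  expect_equal(compute_fd(deg, rotation_units = "degrees"),
               compute_fd(rot_only), tolerance = 1e-9)
  expect_error(compute_fd(matrix(c(rep(0, 11), NA), 2, 6)), "non-finite")
})

test_that("censoring applies the FD threshold exactly", {
  expect_equal(censor_volumes(c(0, 1.2, 0.3)), c(FALSE, TRUE, FALSE))
  expect_false(any(censor_volumes(c(0, 0.4, 0.9))))
  expect_equal(censor_volumes(c(0, 0.2, 0), threshold = 0),
               c(FALSE, TRUE, FALSE))
})

test_that("run exclusion rules reproduce the worked volume-count case", {
  beh <- data.frame(condition = rep(condition_levels(), each = 6),
                    accuracy = TRUE)
  # 40 of 352 censored -> 312/352 = 88.6% < 90% -> excluded
  fd <- rep(0.1, 352); fd[sample(352, 40)] <- 1.5
  v <- evaluate_run(fd, run_behavior = beh)
  expect_true(v$excluded)
  expect_equal(v$frac_remaining, 312 / 352)
  expect_true("remaining<90%" %in% v$reasons)
  # mean FD rule alone
  v2 <- evaluate_run(rep(0.6, 352), run_behavior = beh)
  expect_true(v2$excluded)
  expect_equal(v2$reasons, "meanFD>0.5")
  # clean run retained
  beh_ok <- beh; beh_ok$accuracy <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
                                        4)
  v3 <- evaluate_run(rep(0.2, 352), run_behavior = beh_ok)
  expect_false(v3$excluded)
  expect_length(v3$reasons, 0)
  # condition accuracy < 50%
  beh_bad <- beh
  beh_bad$accuracy[beh_bad$condition == "Peer Mental"] <-
    c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  v4 <- evaluate_run(rep(0.2, 352), run_behavior = beh_bad)
  expect_true("condition_accuracy<50%" %in% v4$reasons)
  # run accuracy < 66.7%
  beh_run <- beh; beh_run$accuracy <- rep(c(TRUE, FALSE), 12)
  v5 <- evaluate_run(rep(0.2, 352), run_behavior = beh_run)
  expect_true("run_accuracy<66.7%" %in% v5$reasons)
  expect_error(evaluate_run(rep(0.2, 352), run_behavior = NULL),
               "data error")
})

test_that("exclusion is monotone in censored volumes", {
  beh <- data.frame(condition = rep(condition_levels(), each = 6),
                    accuracy = TRUE)
  fd <- rep(0.1, 352)
  worst <- FALSE
  for (k in c(0, 20, 36, 50, 80)) {
    fd_k <- fd; if (k > 0) fd_k[seq_len(k)] <- 1.5
    v <- evaluate_run(fd_k, run_behavior = beh)
    expect_true(!worst || v$excluded)  # never flips back to retained
    worst <- worst || v$excluded
  }
  expect_true(worst)
})

test_that("subjects need at least three usable runs", {
  mk <- function(excluded) list(excluded = excluded, reasons = character(0))
  expect_true(evaluate_subject(lapply(rep(FALSE, 4), mk))$included)
  expect_true(evaluate_subject(lapply(c(FALSE, FALSE, FALSE, TRUE),
                                      mk))$included)
  expect_false(evaluate_subject(lapply(c(FALSE, FALSE, TRUE, TRUE),
                                       mk))$included)
})
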