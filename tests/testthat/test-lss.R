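test_that("one GLM is fit per trial and betas recover isolated amplitudes", {
  d <- make_iso_design(n_trials = 8)
  truth <- noiseless_truth()
  sim <- generate_bold(d, truth, seed = 5)
  bs <- estimate_beta_series(sim$bold[[1]], sim$events, d$tr,
                             baseline_order = 0)
  diag <- attr(bs, "diagnostics")
  expect_equal(unname(vapply(diag, `[[`, numeric(1), "n_fits")),
               rep(2, 4))
  for (cond in names(bs))
    expect_equal(unname(bs[[cond]]), unname(sim$amplitudes[[cond]]),
                 tolerance = 1e-6)
})

test_that("default 24-trial condition runs exactly 24 GLMs", {
  d <- generate_design(seed = 21)
  ev <- events_frame(d)
  lss <- build_lss_matrices(ev, d$volumes_per_run, d$tr, "Peer Mental")
  expect_equal(lss$n_trials, 24)
  expect_length(lss$matrices, 24)
  # the matrices differ only in the target/others split: their task-column
  # sums are identical
  two <- lapply(lss$matrices[1:5], function(X)
    X[, "target"] + X[, "others_same_condition"])
  for (k in 2:5) expect_equal(two[[1]], two[[k]], tolerance = 1e-12)
})

test_that("LSS betas match the explicit normal-equations oracle", {
  # overlapping 1-run schedule with noise, motion, censoring
  d <- generate_design(n_runs = 1, trials_per_run = 12,
                       volumes_per_run = 176, seed = 31)
  truth <- default_truth(age_coupling = 0, rt_conn_coupling = 0)
  mot <- list(generate_motion(176, seed = 7))
  prof <- list(age = 11, rt_intercept = 0)
  beh <- generate_behavior(d, prof, truth, seed = 8)
  sim <- generate_bold(d, truth, beh, mot, age = 11, seed = 9)
  fd <- lapply(mot, compute_fd)
  cens <- lapply(fd, function(f) censor_volumes(f, threshold = 0.6))
  bs <- estimate_beta_series(sim$bold, sim$events, d$tr, motion = mot,
                             censor = cens)
  for (cond in condition_levels()) {
    n_tr <- nrow(bs[[cond]])
    for (i in seq_len(n_tr)) {
      oracle <- normal_equations_lss(sim$bold[[1]], sim$events, d$tr, cond, i,
                                     motion = mot, censor = cens)
      expect_equal(bs[[cond]][i, ], oracle, tolerance = 1e-8)
    }
  }
})

test_that("LSS equals the all-trials-separate solution without overlap", {
  d <- make_iso_design(n_trials = 8)
  truth <- noiseless_truth()
  sim <- generate_bold(d, truth, seed = 15)
  bs <- estimate_beta_series(sim$bold[[1]], sim$events, d$tr,
                             baseline_order = 0)
  # LSA: one GLM, one column per trial
  task <- betaconn:::build_task_regressors(sim$events, d$volumes_per_run,
                                           d$tr)
  X <- cbind(task$trial_cols, feedback = task$feedback, 1)
  lsa <- lm.fit(X, sim$bold[[1]])$coefficients
  for (cond in condition_levels()) {
    idx <- which(task$info$trial_type == cond)
    expect_equal(unname(bs[[cond]]), unname(lsa[idx, , drop = FALSE]),
                 tolerance = 1e-8)
  }
})

test_that("betas are scale-equivariant and nuisance-invariant", {
  d <- generate_design(n_runs = 1, trials_per_run = 8,
                       volumes_per_run = 128, seed = 41)
  truth <- default_truth(age_coupling = 0, rt_conn_coupling = 0)
  mot <- list(generate_motion(128, seed = 2))
  sim <- generate_bold(d, truth, motion = mot, seed = 3)
  bs <- estimate_beta_series(sim$bold, sim$events, d$tr, motion = mot)
  bs3 <- estimate_beta_series(lapply(sim$bold, `*`, 3), sim$events, d$tr,
                              motion = mot)
  for (cond in names(bs))
    expect_equal(3 * bs[[cond]], bs3[[cond]], tolerance = 1e-8)
  # adding arbitrary combinations of nuisance columns leaves betas unchanged
  nuis_extra <- 2.5 * betaconn:::legendre_basis(128, 3)[, 3] -
    1.7 * scale(mot[[1]][, 2], scale = FALSE)
  bold2 <- lapply(sim$bold, function(Y) Y + as.numeric(nuis_extra))
  bs2 <- estimate_beta_series(bold2, sim$events, d$tr, motion = mot)
  for (cond in names(bs))
    expect_equal(bs[[cond]], bs2[[cond]], tolerance = 1e-8)
})

test_that("pure nuisance data yields null betas", {
  d <- generate_design(n_runs = 1, trials_per_run = 8,
                       volumes_per_run = 128, seed = 51)
  mot <- list(generate_motion(128, seed = 4))
  truth <- default_truth(amplitude_mean = 0, amplitude_sd = 0, noise_sd = 0,
                         drift_amp = 2, motion_coupling = 0.5,
                         feedback_amplitude = 0.5, age_coupling = 0,
                         rt_conn_coupling = 0)
  sim <- generate_bold(d, truth, motion = mot, seed = 5)
  bs <- estimate_beta_series(sim$bold, sim$events, d$tr, motion = mot)
  for (cond in names(bs))
    expect_lt(max(abs(bs[[cond]])), 1e-8)
})

test_that("voxel-average betas equal averaged voxel betas (linearity)", {
  d <- make_iso_design(n_trials = 4, volumes = 200)
  truth <- noiseless_truth()
  rois <- default_rois()
  sim <- generate_bold(d, truth, voxel_mode = TRUE, voxel_noise_sd = 0.3,
                       seed = 6)
  roi_series <- extract_roi_series(sim$voxel$data[[1]], sim$voxel$coords,
                                   rois)
  bs_roi <- estimate_beta_series(roi_series, sim$events, d$tr,
                                 baseline_order = 1)
  vox_mat <- t(sim$voxel$data[[1]])
  bs_vox <- estimate_beta_series(vox_mat, sim$events, d$tr,
                                 baseline_order = 1)
  for (cond in names(bs_roi)) {
    vox_avg <- vapply(seq_len(nrow(rois)), function(i) {
      d2 <- (sim$voxel$coords[, 1] - rois$x[i])^2 +
        (sim$voxel$coords[, 2] - rois$y[i])^2 +
        (sim$voxel$coords[, 3] - rois$z[i])^2
      rowMeans(bs_vox[[cond]][, d2 <= rois$radius[i]^2, drop = FALSE])
    }, numeric(nrow(bs_vox[[cond]])))
    expect_equal(as.numeric(bs_roi[[cond]]), as.numeric(vox_avg),
                 tolerance = 1e-8)
  }
})

test_that("oversized models and empty conditions are rejected", {
  d <- make_iso_design(n_trials = 4, volumes = 40, spacing = 8)
  truth <- noiseless_truth()
  sim <- generate_bold(d, truth, seed = 7)
  expect_error(estimate_beta_series(sim$bold[[1]], sim$events, d$tr,
                                    baseline_order = 35),
               "regressors")
  expect_error(build_lss_matrices(sim$events, 40, d$tr, "no-such-condition"),
               "no trials")
})

test_that("planted amplitudes stay recoverable at the default noise level", {
  # regression floor for single-trial recovery under the default SNR
  set.seed(400)
  seeds <- sample.int(1e6, 8)
  per_seed <- vapply(seeds, function(sd) {
    d <- generate_design(n_runs = 2, seed = sd)
    truth <- default_truth(age_coupling = 0, rt_conn_coupling = 0)
    mot <- lapply(1:2, function(r) generate_motion(352))
    prof <- list(age = 10.5, rt_intercept = 0)
    beh <- generate_behavior(d, prof, truth)
    sim <- generate_bold(d, truth, beh, mot, age = 10.5)
    fd <- lapply(mot, compute_fd)
    cens <- lapply(fd, censor_volumes)
    bs <- estimate_beta_series(sim$bold, sim$events, d$tr, motion = mot,
                               censor = cens)
    mean(vapply(names(bs), function(cond)
      mean(diag(cor(bs[[cond]], sim$amplitudes[[cond]]))), numeric(1)))
  }, numeric(1))
  expect_gt(mean(per_seed), 0.25)
  expect_true(all(per_seed > 0.15))
})
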