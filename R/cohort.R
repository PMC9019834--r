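#' Ground-truth parameters of the synthetic cohort
#'
#' One list holding every planted effect and noise parameter. Defaults
#' describe the study conditions the generator emulates: ages uniform on
#' 8.18-12.97 years, 60% male; mean RT about 2.04 s falling with age, Peer
#' responses 0.08 s faster than Character; accuracy 90.17% with a small
#' positive Character-accuracy age slope; within-network trial-amplitude
#' correlation 0.30 versus 0.10 between networks, with the Peer-minus-
#' Character connectivity difference growing by `age_coupling` r-units per
#' year of age and with the subject's Peer connectivity coupled negatively
#' to their RT deviation; AR(1)+drift+white BOLD noise; motion with sparse
#' spikes; mean FD 0.23 +/- 0.08 mm, mildly decreasing with age.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `bc_truth`.
#' @export
default_truth <- function(...) {
  truth <- list(
    # behavior
    rt_base = 2.08, rt_age_slope = -0.12, rt_social_effect = -0.08,
    rt_trial_sd = 0.5, rt_subject_sd = 0.25, rt_missing_prob = 0,
    accuracy_base = 0.9017, acc_age_slope_character = 0.015,
    # demographics
    age_range = c(8.18, 12.97), age_mid = 10.575, gender_prob_male = 0.6,
    iq_mean = 112, iq_sd = 12,
    # connectivity structure (amplitude correlations across trials)
    amplitude_mean = 1, amplitude_sd = 1,
    r_within = 0.30, r_between = 0.10,
    age_coupling = 0.02,        # d(Peer - Character) connectivity per year
    rt_conn_coupling = -0.3,    # Peer connectivity shift per s of RT deviation
    feedback_amplitude = 0.5,
    # BOLD noise
    ar_coef = 0.3, noise_sd = 1, drift_amp = 2, motion_coupling = 0.5,
    # motion & FD covariate (amplitude mode)
    motion_params = motion_parameters(),
    fd_mean = 0.23, fd_sd = 0.08, fd_age_slope = -0.014,
    report_params = report_parameters(), report_subject_sd = 0.6
  )
  structure(modifyList(truth, list(...)), class = "bc_truth")
}

#' Planted amplitude correlation matrix for one condition
#'
#' Base structure has `r_within` within each network, `r_between` across
#' networks. The social manipulation shifts all off-diagonal correlations
#' by +/- half the age-scaled Peer-Character difference, and the Peer
#' condition additionally by the RT-connectivity coupling times the
#' subject's RT deviation.
#'
#' @param truth Ground truth list.
#' @param age Subject age, years.
#' @param social `"Peer"` or `"Character"`.
#' @param rt_intercept Subject RT deviation, seconds.
#' @param rois ROI table defining the network block structure.
#' @return Correlation matrix (checked positive semi-definite).
#' @export
condition_correlation <- function(truth, age, social, rt_intercept = 0,
                                  rois = default_rois()) {
  n <- nrow(rois)
  same <- outer(rois$network, rois$network, `==`)
  R <- ifelse(same, truth$r_within, truth$r_between)
  delta <- truth$age_coupling * (age - truth$age_mid)
  shift <- if (social == "Peer")
    delta / 2 + truth$rt_conn_coupling * rt_intercept
  else -delta / 2
  # clamp tail draws so the planted block structure stays positive definite
  shift <- pmin(pmax(shift, -0.25), 0.6)
  R <- R + shift
  diag(R) <- 1
  R <- pmin(pmax(R, -0.99), 0.99)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("parameter error: amplitude covariance is not positive semi-definite")
  dimnames(R) <- list(rois$name, rois$name)
  R
}

#' Draw trial amplitudes for every condition of a design
#'
#' Per condition, trial amplitudes across ROIs are multivariate normal
#' with mean `amplitude_mean` and covariance
#' `amplitude_sd^2 * condition_correlation(...)`.
#'
#' @param design A `task_design`.
#' @param truth Ground truth list.
#' @param age Subject age.
#' @param rt_intercept Subject RT deviation.
#' @param rois ROI table.
#' @param seed Optional seed.
#' @return Named list per condition of `trials x ROI` amplitude matrices,
#'   rows in design order (run, then trial).
#' @export
generate_amplitudes <- function(design, truth = default_truth(), age,
                                rt_intercept = 0, rois = default_rois(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_roi <- nrow(rois)
  sds <- rep(truth$amplitude_sd, length.out = n_roi)
  mu <- rep(truth$amplitude_mean, length.out = n_roi)
  conds <- condition_table()
  out <- list()
  for (k in seq_len(nrow(conds))) {
    R <- condition_correlation(truth, age, conds$social[k], rt_intercept, rois)
    Sigma <- outer(sds, sds) * R
    n_tr <- sum(design$trials$condition == conds$condition[k])
    A <- if (all(sds == 0)) matrix(0, n_tr, n_roi) else
      matrix(rnorm(n_tr * n_roi), n_tr, n_roi) %*%
        chol(Sigma + diag(1e-12, n_roi))
    A <- sweep(A, 2, mu, `+`)
    colnames(A) <- rois$name
    out[[conds$condition[k]]] <- A
  }
  out
}

# z-score columns, mapping zero-variance columns to 0.
safe_z <- function(m) {
  s <- apply(m, 2, sd)
  ctr <- sweep(m, 2, colMeans(m))
  ok <- s > 0
  ctr[, ok] <- sweep(ctr[, ok, drop = FALSE], 2, s[ok], `/`)
  ctr[, !ok] <- 0
  ctr
}

#' Simulate ROI (or voxel) BOLD for one subject
#'
#' Forward model: each trial contributes its planted amplitude times the
#' duration-modulated HRF regressor of its Guess period; Feedback events
#' add a fixed nuisance amplitude; per-run noise is a Legendre drift with
#' random coefficients, AR(1) noise, and (if motion is supplied) a
#' motion-coupled component linear in the motion parameters. The drawn
#' amplitudes are returned as the recovery ground truth.
#'
#' @param design A `task_design`.
#' @param truth Ground truth list.
#' @param behavior Optional behavior table; response times set the Guess
#'   durations (missing RT falls back to the 8 s window).
#' @param motion Optional list of per-run motion matrices.
#' @param amplitudes Optional pre-drawn amplitudes (see
#'   [generate_amplitudes()]); drawn here when `NULL`.
#' @param age,rt_intercept Subject parameters used when drawing amplitudes.
#' @param rois ROI table.
#' @param hrf Kernel from [build_hrf()].
#' @param voxel_mode If `TRUE`, also returns voxel-level data: each ROI's
#'   signal copied to the voxels of its 5 mm sphere on a 2 mm grid plus
#'   independent voxel noise.
#' @param voxel_noise_sd White noise added per voxel in voxel mode.
#' @param seed Optional seed.
#' @return List: `bold` (per-run `volumes x ROI` matrices), `amplitudes`,
#'   `events` (the event table used), and in voxel mode `voxel` (list with
#'   `data` per run, `coords`, `roi_index`).
#' @export
generate_bold <- function(design, truth = default_truth(), behavior = NULL,
                          motion = NULL, amplitudes = NULL,
                          age = truth$age_mid, rt_intercept = 0,
                          rois = default_rois(), hrf = build_hrf(),
                          voxel_mode = FALSE, voxel_noise_sd = 0.5,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(amplitudes))
    amplitudes <- generate_amplitudes(design, truth, age, rt_intercept, rois)
  events <- events_frame(design, behavior)
  n_roi <- nrow(rois)
  task <- build_task_regressors(events, design$volumes_per_run, design$tr, hrf)
  # amplitude matrix aligned with the guess events (design order per condition)
  A <- matrix(0, nrow(task$info), n_roi)
  for (cond in names(amplitudes)) {
    idx <- which(task$info$trial_type == cond)
    A[idx, ] <- amplitudes[[cond]][seq_along(idx), , drop = FALSE]
  }
  signal <- task$trial_cols %*% A +
    task$feedback %*% t(rep(truth$feedback_amplitude, n_roi))
  bold <- list()
  for (ri in seq_along(task$runs)) {
    nv <- task$n_volumes[ri]
    idx <- task$offsets[ri] + seq_len(nv)
    run_sig <- signal[idx, , drop = FALSE]
    if (truth$drift_amp > 0) {
      base <- legendre_basis(nv, 3)[, -1, drop = FALSE]
      run_sig <- run_sig + base %*% matrix(rnorm(3 * n_roi, 0, truth$drift_amp),
                                           3, n_roi)
    }
    if (truth$noise_sd > 0) {
      innov_sd <- truth$noise_sd * sqrt(1 - truth$ar_coef^2)
      e <- matrix(rnorm(nv * n_roi, 0, innov_sd), nv, n_roi)
      run_sig <- run_sig + apply(e, 2, function(x)
        as.numeric(stats::filter(x, truth$ar_coef, method = "recursive")))
    }
    if (!is.null(motion) && truth$motion_coupling != 0)
      run_sig <- run_sig +
        truth$motion_coupling * rowMeans(safe_z(motion[[ri]]))
    colnames(run_sig) <- rois$name
    bold[[ri]] <- run_sig
  }
  out <- list(bold = bold, amplitudes = amplitudes, events = events)
  if (voxel_mode) {
    grid <- roi_voxel_grid(rois)
    roi_index <- rep(NA_integer_, nrow(grid))
    for (i in seq_len(n_roi)) {
      d2 <- (grid[, 1] - rois$x[i])^2 + (grid[, 2] - rois$y[i])^2 +
        (grid[, 3] - rois$z[i])^2
      roi_index[d2 <= rois$radius[i]^2] <- i
    }
    out$voxel <- list(
      data = lapply(bold, function(Y) {
        vx <- t(Y[, roi_index, drop = FALSE])  # voxels x time
        vx + matrix(rnorm(length(vx), 0, voxel_noise_sd), nrow(vx))
      }),
      coords = grid, roi_index = roi_index
    )
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Draws subject profiles (age, gender, IQ, latent RT deviation), then per
#' subject a task design, in-scanner behavior, post-scan reports, planted
#' trial amplitudes, and — in `"full"` mode — rigid-body motion and ROI
#' BOLD time series. In `"amplitude"` mode BOLD synthesis is skipped and
#' the planted amplitudes serve directly as the beta series (the reduced
#' ROI-level simulation used for statistical calibration), with mean FD
#' simulated as a subject covariate.
#'
#' @param n_subjects Number of subjects (>= 2; default 50).
#' @param truth Ground truth list, see [default_truth()].
#' @param seed Optional integer seed; subjects receive independent derived
#'   seeds.
#' @param mode `"full"` or `"amplitude"`.
#' @param design_args Named list of overrides for [generate_design()].
#' @param rois ROI table.
#' @param voxel_mode Forwarded to [generate_bold()] in full mode.
#' @return Object of class `bc_cohort`: list with `profiles` (data frame),
#'   `subjects` (per subject: profile, design, behavior, reports,
#'   amplitudes, motion, bold, mean_fd), `truth`, `rois`, `mode`.
#' @export
generate_cohort <- function(n_subjects = 50, truth = default_truth(),
                            seed = NULL, mode = c("full", "amplitude"),
                            design_args = list(), rois = default_rois(),
                            voxel_mode = FALSE) {
  stopifnot(n_subjects >= 2)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  ids <- sprintf("sub-%02d", seq_len(n_subjects))
  subjects <- vector("list", n_subjects)
  names(subjects) <- ids
  profiles <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(sub_seeds[s])
    profile <- list(
      subject_id = ids[s],
      age = runif(1, truth$age_range[1], truth$age_range[2]),
      gender = if (runif(1) < truth$gender_prob_male) "M" else "F",
      iq = max(85, rnorm(1, truth$iq_mean, truth$iq_sd)),
      rt_intercept = rnorm(1, 0, truth$rt_subject_sd)
    )
    design <- do.call(generate_design, design_args)
    behavior <- generate_behavior(design, profile, truth)
    reports <- generate_reports(profile, truth)
    amplitudes <- generate_amplitudes(design, truth, profile$age,
                                      profile$rt_intercept, rois)
    subj <- list(profile = profile, design = design, behavior = behavior,
                 reports = reports, amplitudes = amplitudes,
                 motion = NULL, bold = NULL)
    if (mode == "full") {
      mult <- exp(rnorm(1, 0, 0.3))
      mp <- truth$motion_params
      mp$jitter_sd_trans <- mp$jitter_sd_trans * mult
      mp$jitter_sd_rot <- mp$jitter_sd_rot * mult
      subj$motion <- lapply(seq_len(design$n_runs), function(r)
        generate_motion(design$volumes_per_run, mp))
      sim <- generate_bold(design, truth, behavior, subj$motion,
                           amplitudes = amplitudes, rois = rois,
                           voxel_mode = voxel_mode)
      subj$bold <- sim$bold
      subj$voxel <- sim$voxel
      subj$mean_fd <- mean(unlist(lapply(subj$motion, compute_fd)))
    } else {
      fd <- truth$fd_mean + truth$fd_age_slope * (profile$age - truth$age_mid) +
        rnorm(1, 0, truth$fd_sd)
      subj$mean_fd <- max(0.05, fd)
    }
    subjects[[s]] <- subj
    profiles[[s]] <- data.frame(subject_id = ids[s], age = profile$age,
                                gender = profile$gender, iq = profile$iq,
                                rt_intercept = profile$rt_intercept,
                                mean_fd = subj$mean_fd,
                                stringsAsFactors = FALSE)
  }
  structure(list(profiles = do.call(rbind, profiles), subjects = subjects,
                 truth = truth, rois = rois, mode = mode),
            class = "bc_cohort")
}

#' @export
print.bc_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$profiles), "subjects,", x$mode, "mode\n")
  cat(sprintf("  age %.2f-%.2f years, %d male\n", min(x$profiles$age),
              max(x$profiles$age), sum(x$profiles$gender == "M")))
  invisible(x)
}
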