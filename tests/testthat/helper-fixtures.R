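# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A hand-built single-run schedule with trials spaced far enough apart
# that their hemodynamic responses do not overlap (isolated-trial limit).
make_iso_design <- function(n_trials = 8, spacing = 45, tr = 1.25,
                            volumes = 352, guess_duration = 8) {
  conds <- condition_table()
  k <- rep(seq_len(4), length.out = n_trials)
  onsets <- 10 + (seq_len(n_trials) - 1) * spacing
  trials <- data.frame(
    run = 1L, trial = seq_len(n_trials), condition = conds$condition[k],
    social = conds$social[k], mentalizing = conds$mentalizing[k],
    guess_onset = onsets, guess_duration = guess_duration,
    mid_jitter = 3, feedback_onset = onsets + guess_duration + 3,
    feedback_duration = 2, iti_jitter = 3, stringsAsFactors = FALSE)
  structure(list(trials = trials, tr = tr, n_runs = 1L,
                 trials_per_run = n_trials, volumes_per_run = volumes,
                 guess_duration = guess_duration, feedback_duration = 2,
                 run_head_fixation = 10, run_tail_fixation = 15),
            class = "task_design")
}

# Noise-free ground truth (drift, AR noise, couplings all off).
noiseless_truth <- function(...) {
  default_truth(noise_sd = 0, drift_amp = 0, age_coupling = 0,
                rt_conn_coupling = 0, motion_coupling = 0, ...)
}

# Brute-force signed-rank p-value by full enumeration over all 2^n sign
# assignments (independent oracle for wilcoxon_signed_rank).
enumerate_signed_rank_p <- function(d, tail = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_ge <- mean(w_all >= w_obs - 1e-12)
  p_le <- mean(w_all <= w_obs + 1e-12)
  switch(tail, greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Solve one LSS trial by explicitly forming the design matrix and the
# normal equations (independent generic least-squares oracle).
normal_equations_lss <- function(bold, events, tr, condition, trial,
                                 motion = NULL, censor = NULL,
                                 baseline_order = 3) {
  lss <- build_lss_matrices(events, nrow(bold), tr, condition,
                            motion = motion, censor = censor,
                            baseline_order = baseline_order)
  X <- lss$matrices[[trial]]
  solve(crossprod(X), crossprod(X, bold))["target", ]
}
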