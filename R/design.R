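#' Condition labels of the 2x2 social-interaction design
#'
#' The paradigm crosses social context (Peer: live chat partner; Character:
#' story character) with mentalizing content (Mental / Non-Mental), giving
#' four conditions.
#'
#' @return Data frame with columns `condition`, `social`, `mentalizing`.
#' @export
condition_table <- function() {
  data.frame(
    condition   = c("Peer Mental", "Peer Non-Mental",
                    "Character Mental", "Character Non-Mental"),
    social      = c("Peer", "Peer", "Character", "Character"),
    mentalizing = c("Mental", "Non-Mental", "Mental", "Non-Mental"),
    stringsAsFactors = FALSE
  )
}

#' @rdname condition_table
#' @export
condition_levels <- function() condition_table()$condition

# Rate of a shifted exponential truncated to [lo, hi] whose mean is `target`.
# Solves E[X | lo <= X <= hi] = target for the rate of X ~ lo + Exp(rate).
truncated_exp_rate <- function(target, lo = 2, hi = 6) {
  w <- hi - lo
  m <- target - lo
  if (m <= 0 || m >= w / 2)
    stop("truncated exponential mean must lie in (", lo, ", ", lo + w / 2, ")")
  f <- function(r) 1 / r - w * exp(-r * w) / (1 - exp(-r * w)) - m
  stats::uniroot(f, c(1e-6, 50), tol = 1e-12)$root
}

# Inverse-CDF draws from the shifted truncated exponential on [lo, hi].
rtrunc_exp <- function(n, rate, lo = 2, hi = 6) {
  u <- runif(n)
  lo - log(1 - u * (1 - exp(-rate * (hi - lo)))) / rate
}

# Adjust jitters to sum exactly to `target` while staying inside [lo, hi]:
# multiplicative rescale, clip, then redistribute the residual over the
# unclipped jitters until the sum matches to 1e-9 s.
rescale_to_sum <- function(x, target, lo = 2, hi = 6) {
  n <- length(x)
  if (target < n * lo - 1e-12 || target > n * hi + 1e-12)
    stop("scheduling error: required jitter total ", signif(target, 6),
         " s is infeasible for ", n, " jitters in [", lo, ", ", hi, "]")
  s <- pmin(pmax(x * target / sum(x), lo), hi)
  for (i in seq_len(200)) {
    d <- target - sum(s)
    if (abs(d) < 1e-12) break
    free <- if (d > 0) which(s < hi - 1e-15) else which(s > lo + 1e-15)
    if (!length(free)) stop("scheduling error: cannot meet jitter total")
    s[free] <- pmin(pmax(s[free] + d / length(free), lo), hi)
  }
  d <- target - sum(s)
  if (abs(d) > 1e-9) stop("scheduling error: jitter rescaling did not converge")
  # final exactness nudge on one interior jitter
  free <- which(s + d >= lo & s + d <= hi)
  s[free[1]] <- s[free[1]] + d
  s
}

#' Generate the event-related task schedule
#'
#' Builds a multi-run trial schedule for the 2x2 design: each trial is an
#' 8 s Guess period and a 2 s Feedback period separated by a jittered
#' fixation, with a second jittered fixation before the next trial. Jitters
#' are drawn from a shifted exponential on \[2, 6\] s with truncated mean
#' 3.5 s and then rescaled (bounds preserved) so that each run's schedule
#' fills the acquisition window exactly: `volumes_per_run * tr` seconds,
#' 440 s (352 volumes at TR = 1.25 s) by default. Condition order is a
#' uniformly random permutation balanced within run.
#'
#' @param n_runs Number of runs (default 4).
#' @param trials_per_run Trials per run; must be divisible by 4 (default 24).
#' @param tr Repetition time in seconds (default 1.25).
#' @param guess_duration Nominal Guess period duration, seconds (default 8).
#' @param feedback_duration Feedback duration, seconds (default 2).
#' @param run_head_fixation Lead-in fixation, seconds (default 10).
#' @param run_tail_fixation End fixation, seconds (default 15).
#' @param jitter_range Bounds of the jittered fixations, seconds.
#' @param jitter_mean Target (truncated) mean of the jitter law, seconds.
#' @param volumes_per_run Volumes acquired per run (default 352).
#' @param seed Optional integer seed.
#' @return Object of class `task_design`: list with `trials` (one row per
#'   trial: run, trial, condition, social, mentalizing, guess_onset,
#'   guess_duration, mid_jitter, feedback_onset, feedback_duration,
#'   iti_jitter), plus the timing parameters.
#' @export
generate_design <- function(n_runs = 4, trials_per_run = 24, tr = 1.25,
                            guess_duration = 8, feedback_duration = 2,
                            run_head_fixation = 10, run_tail_fixation = 15,
                            jitter_range = c(2, 6), jitter_mean = 3.5,
                            volumes_per_run = 352, seed = NULL) {
  stopifnot(n_runs >= 1, trials_per_run >= 4)
  if (trials_per_run %% 4L != 0L)
    stop("trials_per_run must be divisible by the 4 conditions")
  if (!is.null(seed)) set.seed(seed)
  lo <- jitter_range[1]; hi <- jitter_range[2]
  run_len <- volumes_per_run * tr
  fixed <- run_head_fixation + run_tail_fixation +
    trials_per_run * (guess_duration + feedback_duration)
  jitter_total <- run_len - fixed
  n_jit <- 2L * trials_per_run
  if (jitter_total < n_jit * lo - 1e-12)
    stop("scheduling error: trial content (", fixed, " s) exceeds the run ",
         "length (", run_len, " s) minus minimum jitter")
  if (jitter_total > n_jit * hi + 1e-12)
    stop("scheduling error: run length cannot be filled with jitters <= ",
         hi, " s")
  rate <- truncated_exp_rate(jitter_mean, lo, hi)
  conds <- condition_table()

  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    order_idx <- sample(rep(seq_len(4L), trials_per_run / 4L))
    raw <- rtrunc_exp(n_jit, rate, lo, hi)
    jit <- rescale_to_sum(raw, jitter_total, lo, hi)
    mid <- jit[seq_len(trials_per_run)]
    iti <- jit[trials_per_run + seq_len(trials_per_run)]
    onset <- numeric(trials_per_run)
    t0 <- run_head_fixation
    for (i in seq_len(trials_per_run)) {
      onset[i] <- t0
      t0 <- t0 + guess_duration + mid[i] + feedback_duration + iti[i]
    }
    rows[[r]] <- data.frame(
      run = r, trial = seq_len(trials_per_run),
      condition = conds$condition[order_idx],
      social = conds$social[order_idx],
      mentalizing = conds$mentalizing[order_idx],
      guess_onset = onset, guess_duration = guess_duration,
      mid_jitter = mid,
      feedback_onset = onset + guess_duration + mid,
      feedback_duration = feedback_duration,
      iti_jitter = iti,
      stringsAsFactors = FALSE
    )
    attr(rows[[r]], "raw_jitters") <- raw
  }
  raw_jitters <- unlist(lapply(rows, attr, "raw_jitters"))
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  structure(list(
    trials = trials, tr = tr, n_runs = n_runs,
    trials_per_run = trials_per_run, volumes_per_run = volumes_per_run,
    guess_duration = guess_duration, feedback_duration = feedback_duration,
    run_head_fixation = run_head_fixation,
    run_tail_fixation = run_tail_fixation,
    jitter_range = jitter_range, jitter_mean = jitter_mean,
    raw_jitters = raw_jitters
  ), class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat("Task design:", x$n_runs, "runs x", x$trials_per_run, "trials,",
      "TR", x$tr, "s,", x$volumes_per_run, "volumes/run",
      sprintf("(%.0f s)\n", x$volumes_per_run * x$tr))
  print(table(x$trials$condition))
  invisible(x)
}

#' Total scheduled duration of one run of a design
#'
#' Sums lead-in fixation, all trial segments and jitters, and the end
#' fixation. Equals `volumes_per_run * tr` by construction.
#'
#' @param design A `task_design`.
#' @param run Run index.
#' @return Duration in seconds.
#' @export
run_duration <- function(design, run = 1) {
  tr_rows <- design$trials[design$trials$run == run, ]
  design$run_head_fixation + design$run_tail_fixation +
    sum(tr_rows$guess_duration + tr_rows$mid_jitter +
        tr_rows$feedback_duration + tr_rows$iti_jitter)
}

#' Event table for GLM construction
#'
#' Flattens a design (plus optional behavior) into a BIDS-events-like table
#' with one row per Guess and Feedback event. Guess durations are the trial
#' response times when behavior is supplied (duration-modulated regressor
#' convention); missing responses fall back to the full Guess window.
#'
#' @param design A `task_design`.
#' @param behavior Optional behavior table from [generate_behavior()]
#'   (matched by run and trial).
#' @return Data frame: run, onset, duration, trial_type, response_time.
#' @export
events_frame <- function(design, behavior = NULL) {
  tr_rows <- design$trials
  rt <- rep(NA_real_, nrow(tr_rows))
  if (!is.null(behavior)) {
    key <- paste(tr_rows$run, tr_rows$trial)
    bkey <- paste(behavior$run, behavior$trial)
    rt <- behavior$rt[match(key, bkey)]
  }
  guess_dur <- ifelse(is.na(rt), tr_rows$guess_duration, rt)
  guess <- data.frame(
    run = tr_rows$run, onset = tr_rows$guess_onset, duration = guess_dur,
    trial_type = tr_rows$condition, response_time = rt,
    stringsAsFactors = FALSE
  )
  feedback <- data.frame(
    run = tr_rows$run, onset = tr_rows$feedback_onset,
    duration = tr_rows$feedback_duration, trial_type = "feedback",
    response_time = NA_real_, stringsAsFactors = FALSE
  )
  ev <- rbind(guess, feedback)
  ev <- ev[order(ev$run, ev$onset), ]
  rownames(ev) <- NULL
  ev
}
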