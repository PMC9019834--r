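#' Legendre polynomial baseline basis
#'
#' Orthogonal slow-drift baseline for one run: Legendre polynomials of
#' order 0..`order` evaluated on n points mapped to \[-1, 1\].
#'
#' @param n Number of volumes.
#' @param order Highest polynomial order (default 3).
#' @return Matrix `n x (order + 1)`.
#' @export
legendre_basis <- function(n, order = 3) {
  x <- seq(-1, 1, length.out = n)
  out <- matrix(0, n, order + 1)
  out[, 1] <- 1
  if (order >= 1) out[, 2] <- x
  if (order >= 2)
    for (k in 1:(order - 1))
      out[, k + 2] <- ((2 * k + 1) * x * out[, k + 1] - k * out[, k]) / (k + 1)
  colnames(out) <- paste0("poly", 0:order)
  out
}

# Demeaned motion parameters and their backward-difference derivatives
# (first element 0) for one run.
motion_nuisance <- function(motion) {
  m <- scale(as.matrix(motion), center = TRUE, scale = FALSE)
  d <- rbind(0, diff(m))
  colnames(d) <- paste0(colnames(motion), "_deriv")
  cbind(m, d)
}

# Build per-trial Guess regressors and the aggregate Feedback regressor for
# the concatenated runs of an event table.
build_task_regressors <- function(events, n_volumes, tr, hrf = build_hrf()) {
  runs <- sort(unique(events$run))
  if (length(n_volumes) == 1) n_volumes <- rep(n_volumes, length(runs))
  offsets <- c(0, cumsum(n_volumes))[seq_along(runs)]
  total <- sum(n_volumes)
  guess <- events[events$trial_type != "feedback", , drop = FALSE]
  guess <- guess[order(guess$run, guess$onset), , drop = FALSE]
  trial_cols <- matrix(0, total, nrow(guess))
  for (i in seq_len(nrow(guess))) {
    ri <- match(guess$run[i], runs)
    reg <- make_trial_regressor(guess$onset[i], guess$duration[i], hrf,
                                n_volumes[ri], tr)
    trial_cols[offsets[ri] + seq_len(n_volumes[ri]), i] <- reg
  }
  colnames(trial_cols) <- paste0(gsub("[^A-Za-z]", "", guess$trial_type),
                                 "_", seq_len(nrow(guess)))
  feedback <- numeric(total)
  fb <- events[events$trial_type == "feedback", , drop = FALSE]
  for (i in seq_len(nrow(fb))) {
    ri <- match(fb$run[i], runs)
    reg <- make_trial_regressor(fb$onset[i], fb$duration[i], hrf,
                                n_volumes[ri], tr)
    idx <- offsets[ri] + seq_len(n_volumes[ri])
    feedback[idx] <- feedback[idx] + reg
  }
  list(trial_cols = trial_cols, info = guess, feedback = feedback,
       runs = runs, n_volumes = n_volumes, offsets = offsets, total = total)
}

# Block-diagonal per-run nuisance: demeaned motion + derivatives, censored
# volume indicators, Legendre baseline.
build_nuisance <- function(task, motion = NULL, censor = NULL,
                           baseline_order = 3) {
  total <- task$total
  blocks <- list()
  for (ri in seq_along(task$runs)) {
    idx <- task$offsets[ri] + seq_len(task$n_volumes[ri])
    base <- legendre_basis(task$n_volumes[ri], baseline_order)
    colnames(base) <- paste0("run", task$runs[ri], "_", colnames(base))
    blk <- base
    if (!is.null(motion)) {
      mn <- motion_nuisance(motion[[ri]])
      colnames(mn) <- paste0("run", task$runs[ri], "_", colnames(mn))
      blk <- cbind(mn, blk)
    }
    full <- matrix(0, total, ncol(blk), dimnames = list(NULL, colnames(blk)))
    full[idx, ] <- blk
    blocks[[ri]] <- full
  }
  nuis <- do.call(cbind, blocks)
  if (!is.null(censor)) {
    cens <- unlist(censor)
    if (length(cens) != total)
      stop("censor mask length does not match total volumes")
    bad <- which(cens)
    if (length(bad)) {
      spikes <- matrix(0, total, length(bad),
                       dimnames = list(NULL, paste0("spike_v", bad)))
      spikes[cbind(bad, seq_along(bad))] <- 1
      nuis <- cbind(spikes, nuis)
    }
  }
  nuis
}

#' Build the per-trial LSS design matrices for one condition
#'
#' For a condition with n trials, builds the n least-squares-single design
#' matrices. Each has two task columns — the target trial and the sum of
#' the remaining same-condition trials — plus one aggregate column per
#' other condition's Guess events, one for all Feedback events, demeaned
#' motion parameters and their backward-difference derivatives (per run),
#' one indicator per censored volume, and a per-run Legendre baseline.
#'
#' @param events Event table from [events_frame()].
#' @param n_volumes Volumes per run (scalar or vector over runs present).
#' @param tr Repetition time, seconds.
#' @param condition Condition label (one of [condition_levels()], or any
#'   `trial_type` present).
#' @param motion Optional list of per-run motion matrices.
#' @param censor Optional list of per-run logical censor masks.
#' @param hrf Kernel from [build_hrf()].
#' @param baseline_order Legendre baseline order (default 3).
#' @return List: `matrices` (one design matrix per trial), `trial_info`
#'   (rows of `events` in trial order), `n_trials`.
#' @export
build_lss_matrices <- function(events, n_volumes, tr, condition,
                               motion = NULL, censor = NULL,
                               hrf = build_hrf(), baseline_order = 3) {
  task <- build_task_regressors(events, n_volumes, tr, hrf)
  nuis <- build_nuisance(task, motion, censor, baseline_order)
  is_cond <- task$info$trial_type == condition
  if (!any(is_cond)) stop("no trials of condition '", condition, "'")
  cond_cols <- task$trial_cols[, is_cond, drop = FALSE]
  others <- setdiff(unique(task$info$trial_type), condition)
  other_cols <- vapply(others, function(cc)
    rowSums(task$trial_cols[, task$info$trial_type == cc, drop = FALSE]),
    numeric(task$total))
  if (length(others))
    colnames(other_cols) <- paste0("other_", gsub("[^A-Za-z]", "", others))
  fixed <- cbind(other_cols,
                 if (any(task$feedback != 0)) cbind(feedback = task$feedback),
                 nuis)
  n_trials <- ncol(cond_cols)
  mats <- lapply(seq_len(n_trials), function(i) {
    two <- if (n_trials > 1)
      cbind(target = cond_cols[, i],
            others_same_condition = rowSums(cond_cols[, -i, drop = FALSE]))
    else cbind(target = cond_cols[, i])
    cbind(two, fixed)
  })
  list(matrices = mats,
       trial_info = task$info[is_cond, , drop = FALSE],
       n_trials = n_trials)
}

#' Estimate trial-wise beta series by least-squares-single GLMs
#'
#' For each condition, fits one ordinary-least-squares GLM per trial (the
#' iterative LSS scheme: a 24-trial condition yields 24 separate GLM fits)
#' and collects the target-trial coefficients into a trials x ROI beta
#' matrix. Censored volumes are retained and absorbed by per-volume spike
#' regressors.
#'
#' @param bold List of per-run `volumes x ROI` matrices (or one matrix for
#'   a single run). Column names label the ROIs.
#' @param events Event table from [events_frame()].
#' @param tr Repetition time, seconds.
#' @param conditions Conditions to estimate (default: all Guess
#'   `trial_type`s present).
#' @param motion,censor Optional per-run nuisance inputs, as in
#'   [build_lss_matrices()].
#' @param hrf Kernel from [build_hrf()].
#' @param baseline_order Legendre baseline order.
#' @return Object of class `beta_series`: named list (per condition) of
#'   `trials x ROI` beta matrices, with a `diagnostics` attribute recording
#'   the number of GLM fits, design rank, and column counts per condition.
#' @export
estimate_beta_series <- function(bold, events, tr, conditions = NULL,
                                 motion = NULL, censor = NULL,
                                 hrf = build_hrf(), baseline_order = 3) {
  if (is.matrix(bold)) bold <- list(bold)
  Y <- do.call(rbind, lapply(bold, as.matrix))
  if (!all(is.finite(Y))) stop("data error: non-finite BOLD values")
  n_volumes <- vapply(bold, nrow, integer(1))
  if (is.null(conditions)) {
    conditions <- unique(events$trial_type[events$trial_type != "feedback"])
  }
  out <- list()
  diagnostics <- list()
  for (cond in conditions) {
    lss <- build_lss_matrices(events, n_volumes, tr, cond, motion, censor,
                              hrf, baseline_order)
    betas <- matrix(NA_real_, lss$n_trials, ncol(Y),
                    dimnames = list(NULL, colnames(Y)))
    ranks <- integer(lss$n_trials)
    for (i in seq_len(lss$n_trials)) {
      X <- lss$matrices[[i]]
      if (ncol(X) >= nrow(X))
        stop("more regressors (", ncol(X), ") than volumes (", nrow(X), ")")
      fit <- lm.fit(X, Y)
      ranks[i] <- fit$rank
      b <- fit$coefficients
      if (is.null(dim(b))) b <- matrix(b, ncol = 1, dimnames = list(names(b)))
      bt <- b["target", ]
      if (fit$rank < ncol(X) && any(is.na(bt))) {
        warning("rank-deficient LSS design for trial ", i, " of '", cond,
                "'; beta set to NA")
        bt[] <- NA_real_
      }
      betas[i, ] <- bt
    }
    out[[cond]] <- betas
    diagnostics[[cond]] <- list(n_fits = lss$n_trials, rank = ranks,
                                n_regressors = ncol(lss$matrices[[1]]),
                                n_volumes = nrow(Y))
  }
  structure(out, class = "beta_series", diagnostics = diagnostics)
}

#' @export
print.beta_series <- function(x, ...) {
  cat("Beta series:", length(x), "conditions\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %d trials x %d ROIs\n", nm, nrow(x[[nm]]),
                ncol(x[[nm]])))
  invisible(x)
}

#' Collinearity check of the condition-level task regressors
#'
#' Largest absolute pairwise correlation among the aggregate
#' condition-of-interest regressors (and the Feedback regressor); warns
#' above the threshold. A schedule-quality check standing in for a trial
#' order optimizer.
#'
#' @param events Event table.
#' @param n_volumes Volumes per run.
#' @param tr Repetition time.
#' @param hrf Kernel from [build_hrf()].
#' @param warn_threshold Warning threshold for max |r| (default 0.5).
#' @return Max absolute off-diagonal correlation (invisibly also the full
#'   matrix as attribute `correlations`).
#' @export
design_collinearity <- function(events, n_volumes, tr, hrf = build_hrf(),
                                warn_threshold = 0.5) {
  task <- build_task_regressors(events, n_volumes, tr, hrf)
  conds <- unique(task$info$trial_type)
  agg <- vapply(conds, function(cc)
    rowSums(task$trial_cols[, task$info$trial_type == cc, drop = FALSE]),
    numeric(task$total))
  if (any(task$feedback != 0)) agg <- cbind(agg, feedback = task$feedback)
  cc <- cor(agg)
  mx <- max(abs(cc[upper.tri(cc)]))
  if (mx > warn_threshold)
    warning(sprintf("task regressor collinearity: max |r| = %.2f", mx))
  structure(mx, correlations = cc)
}
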