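#' Default motion/behavior quality-control thresholds
#'
#' Volumes with FD above `fd_censor` are censored; a run is excluded when
#' fewer than `min_volumes_frac` of its volumes survive censoring, its mean
#' FD exceeds `fd_mean_max`, any condition's accuracy falls below
#' `min_condition_acc`, or overall run accuracy falls below `min_run_acc`;
#' a subject is included with at least `min_usable_runs` usable runs.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(fd_censor = 1.0, fd_mean_max = 0.5, min_volumes_frac = 0.90,
       min_condition_acc = 0.50, min_run_acc = 0.667, min_usable_runs = 3L)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Per-volume sum of absolute backward differences of the six parameters,
#' rotations converted to arc length on a sphere of `head_radius` mm
#' (Power-style FD). The first volume's FD is 0.
#'
#' @param motion Matrix `volumes x 6`: three translations (mm) then three
#'   rotations.
#' @param head_radius Reference sphere radius in mm (default 50).
#' @param rotation_units `"radians"` (default) or `"degrees"`.
#' @return Numeric FD vector (mm), same length as volumes.
#' @export
compute_fd <- function(motion, head_radius = 50,
                       rotation_units = c("radians", "degrees")) {
  rotation_units <- match.arg(rotation_units)
  motion <- as.matrix(motion)
  if (nrow(motion) < 2 || ncol(motion) != 6)
    stop("motion must be a [volumes x 6] matrix with >= 2 volumes")
  if (!all(is.finite(motion))) stop("data error: non-finite motion parameters")
  rot <- motion[, 4:6, drop = FALSE]
  if (rotation_units == "degrees") rot <- rot * pi / 180
  d_trans <- abs(diff(motion[, 1:3, drop = FALSE]))
  d_rot <- abs(diff(rot))
  c(0, rowSums(d_trans) + head_radius * rowSums(d_rot))
}

#' Censor high-motion volumes
#'
#' @param fd FD vector from [compute_fd()].
#' @param threshold Censor threshold in mm (default 1.0).
#' @return Logical mask, `TRUE` where `fd > threshold`.
#' @export
censor_volumes <- function(fd, threshold = qc_thresholds()$fd_censor) {
  if (any(!is.finite(fd)) || any(fd < 0)) stop("data error: invalid FD vector")
  fd > threshold
}

#' Run-level exclusion verdict
#'
#' Applies the four run-exclusion rules: remaining volumes < 90%, mean FD
#' (over all volumes, pre-censoring) > 0.5 mm, any condition accuracy
#' < 50%, or run accuracy < 66.7%. All triggered reasons are recorded.
#'
#' @param fd FD vector for the run.
#' @param censor_mask Logical censor mask (default: from [censor_volumes()]).
#' @param run_behavior Data frame with columns `condition` and `accuracy`
#'   for this run's trials.
#' @param thresholds See [qc_thresholds()].
#' @return List: `excluded`, `reasons` (character), `mean_fd`,
#'   `frac_remaining`, `n_censored`, `run_accuracy`, `condition_accuracy`.
#' @export
evaluate_run <- function(fd, censor_mask = NULL, run_behavior,
                         thresholds = qc_thresholds()) {
  if (is.null(censor_mask)) censor_mask <- censor_volumes(fd, thresholds$fd_censor)
  if (missing(run_behavior) || is.null(run_behavior) || !nrow(run_behavior))
    stop("data error: run behavior required for accuracy rules")
  mean_fd <- mean(fd)
  frac_remaining <- 1 - mean(censor_mask)
  cond_acc <- tapply(run_behavior$accuracy, run_behavior$condition, mean)
  run_acc <- mean(run_behavior$accuracy)
  reasons <- character(0)
  if (frac_remaining < thresholds$min_volumes_frac)
    reasons <- c(reasons, "remaining<90%")
  if (mean_fd > thresholds$fd_mean_max) reasons <- c(reasons, "meanFD>0.5")
  if (any(cond_acc < thresholds$min_condition_acc))
    reasons <- c(reasons, "condition_accuracy<50%")
  if (run_acc < thresholds$min_run_acc) reasons <- c(reasons, "run_accuracy<66.7%")
  list(excluded = length(reasons) > 0, reasons = reasons, mean_fd = mean_fd,
       frac_remaining = frac_remaining, n_censored = sum(censor_mask),
       run_accuracy = run_acc, condition_accuracy = cond_acc)
}

#' Subject-level inclusion verdict
#'
#' @param run_verdicts List of run verdicts from [evaluate_run()].
#' @param min_usable Minimum usable runs for inclusion (default 3).
#' @return List: `included`, `n_usable`, `usable_runs` (indices).
#' @export
evaluate_subject <- function(run_verdicts,
                             min_usable = qc_thresholds()$min_usable_runs) {
  usable <- which(!vapply(run_verdicts, `[[`, logical(1), "excluded"))
  list(included = length(usable) >= min_usable, n_usable = length(usable),
       usable_runs = usable)
}

#' Full QC for one subject
#'
#' Computes FD and censor masks per run, run verdicts and the subject
#' verdict in one call.
#'
#' @param motion_list List of per-run motion matrices.
#' @param behavior Trial behavior table (column `run` selects run trials).
#' @param thresholds See [qc_thresholds()].
#' @param head_radius FD reference radius, mm.
#' @return List: `fd` (per-run list), `censor` (per-run list), `runs`
#'   (per-run verdicts), `subject` (subject verdict), `mean_fd`
#'   (subject-level mean FD across all volumes of all runs).
#' @export
qc_subject <- function(motion_list, behavior, thresholds = qc_thresholds(),
                       head_radius = 50) {
  fd <- lapply(motion_list, compute_fd, head_radius = head_radius)
  censor <- lapply(fd, censor_volumes, threshold = thresholds$fd_censor)
  runs <- lapply(seq_along(fd), function(r)
    evaluate_run(fd[[r]], censor[[r]],
                 behavior[behavior$run == r, , drop = FALSE], thresholds))
  list(fd = fd, censor = censor, runs = runs,
       subject = evaluate_subject(runs, thresholds$min_usable_runs),
       mean_fd = mean(unlist(fd)))
}
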