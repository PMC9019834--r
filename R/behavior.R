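#' Simulate in-scanner behavior for one subject
#'
#' Reaction times follow `base(age) + subject intercept + social effect +
#' trial noise`, truncated to (0.2, 8\] s, where the base decreases with age
#' and the social effect (default -0.08 s) makes responses to the Peer
#' condition faster. Accuracy is Bernoulli with a base rate (default
#' 0.9017) and an optional planted age slope in the Character condition.
#'
#' @param design A `task_design`.
#' @param profile Subject profile list/row with at least `age`; optional
#'   `rt_intercept` (subject-level RT deviation, seconds).
#' @param truth Ground-truth parameter list, see [default_truth()].
#' @param seed Optional integer seed.
#' @return Data frame with one row per trial: run, trial, condition,
#'   social, mentalizing, accuracy (logical), rt (seconds, NA if the
#'   response is missing).
#' @export
generate_behavior <- function(design, profile, truth = default_truth(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr_rows <- design$trials
  n <- nrow(tr_rows)
  age_c <- profile$age - truth$age_mid
  u <- profile$rt_intercept %||% 0
  base <- truth$rt_base + truth$rt_age_slope * age_c + u
  rt <- base + ifelse(tr_rows$social == "Peer", truth$rt_social_effect, 0) +
    rnorm(n, 0, truth$rt_trial_sd)
  rt <- pmin(pmax(rt, 0.2 + 1e-6), 8)
  if (truth$rt_missing_prob > 0)
    rt[runif(n) < truth$rt_missing_prob] <- NA_real_
  p_acc <- truth$accuracy_base +
    ifelse(tr_rows$social == "Character",
           truth$acc_age_slope_character * age_c, 0)
  p_acc <- pmin(pmax(p_acc, 0), 1)
  acc <- runif(n) < p_acc
  data.frame(
    run = tr_rows$run, trial = tr_rows$trial,
    condition = tr_rows$condition, social = tr_rows$social,
    mentalizing = tr_rows$mentalizing,
    accuracy = acc, rt = rt, stringsAsFactors = FALSE
  )
}

#' Default latent-normal parameters for the post-scan reports
#'
#' Location/scale of the latent normal behind each 5-point ordinal report,
#' per measure and social level. Defaults follow the observed group means
#' and SDs of the paradigm's post-scan questionnaire (enjoyment, motivation
#' and attention measures shifted toward Peer; Perceived Difficulty
#' essentially unshifted).
#'
#' @return Data frame: measure, peer_mean, peer_sd, char_mean, char_sd.
#' @export
report_parameters <- function() {
  data.frame(
    measure  = c("Liked Chatting", "Liked Guessing", "Felt When Matched",
                 "Wanted to See", "Paid Attention", "Perceived Difficulty"),
    peer_mean = c(4.30, 3.84, 4.26, 4.08, 3.90, 2.38),
    peer_sd   = c(0.81, 0.96, 0.83, 0.92, 0.91, 1.23),
    char_mean = c(2.76, 3.26, 3.96, 3.38, 3.40, 2.20),
    char_sd   = c(1.04, 1.12, 0.88, 1.23, 0.97, 1.29),
    stringsAsFactors = FALSE
  )
}

#' Simulate post-scan ordinal reports for one subject
#'
#' Each of the six 5-point measures is generated for both social levels by
#' discretizing a latent normal draw (round, then clip to 1..5). The latent
#' value is a shared subject response tendency (SD
#' `truth$report_subject_sd`, inducing the within-subject correlation of
#' repeated questionnaire measures) plus a measure-specific residual whose
#' scale is chosen so the marginal SD matches the configured value.
#'
#' @param profile Subject profile (unused by the default model, kept for
#'   interface symmetry).
#' @param truth Ground-truth list; `truth$report_params` holds the latent
#'   locations/scales (defaults to [report_parameters()]).
#' @param seed Optional integer seed.
#' @return Data frame: measure, social, score (integer 1..5).
#' @export
generate_reports <- function(profile = NULL, truth = default_truth(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rp <- truth$report_params %||% report_parameters()
  tau <- truth$report_subject_sd %||% 0
  u <- rnorm(1, 0, tau)
  resid_sd <- function(s) sqrt(pmax(s^2 - tau^2, if (tau > 0) 0.01 else 0))
  latent <- c(rnorm(nrow(rp), rp$peer_mean, resid_sd(rp$peer_sd)),
              rnorm(nrow(rp), rp$char_mean, resid_sd(rp$char_sd))) + u
  data.frame(
    measure = rep(rp$measure, 2),
    social  = rep(c("Peer", "Character"), each = nrow(rp)),
    score   = as.integer(pmin(pmax(round(latent), 1), 5)),
    stringsAsFactors = FALSE
  )
}
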