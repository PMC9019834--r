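#' Beta series for every cohort subject
#'
#' In `"amplitude"` mode the planted trial amplitudes are the beta series
#' (the reduced simulation used for statistical calibration). In `"full"`
#' mode each subject's beta series is estimated from their simulated BOLD
#' by the LSS GLM, using the QC-retained runs and censor masks.
#'
#' @param cohort A `bc_cohort`.
#' @param thresholds QC thresholds, see [qc_thresholds()] (full mode).
#' @param hrf Kernel from [build_hrf()] (full mode).
#' @param baseline_order Legendre baseline order (full mode).
#' @return Named list per included subject of `beta_series`-like lists
#'   (per condition, trials x ROI), with attribute `qc` (per subject QC,
#'   full mode only).
#' @export
cohort_beta_series <- function(cohort, thresholds = qc_thresholds(),
                               hrf = build_hrf(), baseline_order = 3) {
  if (cohort$mode == "amplitude")
    return(lapply(cohort$subjects, `[[`, "amplitudes"))
  out <- list()
  qc_all <- list()
  for (id in names(cohort$subjects)) {
    subj <- cohort$subjects[[id]]
    qc <- qc_subject(subj$motion, subj$behavior, thresholds)
    qc_all[[id]] <- qc
    if (!qc$subject$included) next
    keep <- qc$subject$usable_runs
    events <- events_frame(subj$design, subj$behavior)
    events <- events[events$run %in% keep, , drop = FALSE]
    out[[id]] <- estimate_beta_series(
      subj$bold[keep], events, subj$design$tr,
      motion = subj$motion[keep], censor = qc$censor[keep],
      hrf = hrf, baseline_order = baseline_order)
  }
  structure(out, qc = qc_all)
}

#' Build the long analysis tables for a cohort
#'
#' Turns per-subject beta series into the tidy tables consumed by the
#' inference suite: per-condition network summaries, node strengths,
#' behavioral cell means, collapsed (Peer/Character) summaries, and the
#' ordinal reports, each joined with the subject covariates (age, gender,
#' IQ, mean FD).
#'
#' @param cohort A `bc_cohort`.
#' @param beta_list Optional named list of per-subject beta series
#'   (default: [cohort_beta_series()]).
#' @param fisher_z Use Fisher z rather than raw r (default `FALSE`).
#' @param include Which tables to build (subset of `"network"`, `"node"`,
#'   `"behavior"`, `"collapsed"`, `"reports"`); trimming the set speeds up
#'   large simulation loops.
#' @return List of data frames: `network` (subject x condition rows with
#'   one `within_*`/`between_*` column per network/pair), `node`
#'   (x ROI x strength type), `behavior`, `collapsed` (subject x social),
#'   `reports`, plus `matrices` (per subject: per-condition connectivity
#'   matrices) and `profiles`.
#' @export
cohort_tables <- function(cohort, beta_list = NULL, fisher_z = FALSE,
                          include = c("network", "node", "behavior",
                                      "collapsed", "reports")) {
  include <- match.arg(include, several.ok = TRUE)
  if (is.null(beta_list)) beta_list <- cohort_beta_series(cohort)
  rois <- cohort$rois
  nets <- unique(rois$network)
  net_pairs <- if (length(nets) > 1) utils::combn(nets, 2, simplify = FALSE)
    else list()
  prof <- cohort$profiles
  net_rows <- list(); node_rows <- list(); beh_rows <- list()
  col_rows <- list(); rep_rows <- list(); mats_all <- list()
  conds <- condition_table()
  for (id in names(beta_list)) {
    subj <- cohort$subjects[[id]]
    p <- prof[prof$subject_id == id, ]
    mats <- lapply(beta_list[[id]], beta_corr_matrix, fisher_z = fisher_z)
    mats_all[[id]] <- mats
    cov_row <- data.frame(subject_id = id, age = p$age, gender = p$gender,
                          iq = p$iq, mean_fd = p$mean_fd,
                          stringsAsFactors = FALSE)
    beh <- subj$behavior
    for (k in seq_len(nrow(conds))) {
      cond <- conds$condition[k]
      if (is.null(mats[[cond]])) next
      if (!any(c("network", "node") %in% include)) break
      sm <- network_summary_fast(mats[[cond]], rois,
                                 nodes = "node" %in% include)
      row <- cbind(cov_row,
                   data.frame(condition = cond, social = conds$social[k],
                              mentalizing = conds$mentalizing[k],
                              stringsAsFactors = FALSE))
      for (nw in nets) row[[paste0("within_", nw)]] <- sm$within[[nw]]
      for (pp in net_pairs)
        row[[paste0("between_", pp[1], "_", pp[2])]] <-
          sm$between[[paste(pp, collapse = "|")]]
      bsel <- beh[beh$condition == cond, ]
      row$rt <- mean(bsel$rt, na.rm = TRUE)
      row$accuracy <- mean(bsel$accuracy)
      net_rows[[length(net_rows) + 1]] <- row
      if ("node" %in% include)
        node_rows[[length(node_rows) + 1]] <- cbind(
          row[rep(1, nrow(sm$nodes)),
              c("subject_id", "age", "gender", "iq", "mean_fd", "condition",
                "social", "mentalizing")],
          sm$nodes)
    }
    # behavioral cell means for all four conditions (independent of betas)
    if ("behavior" %in% include) for (k in seq_len(nrow(conds))) {
      bsel <- beh[beh$condition == conds$condition[k], ]
      beh_rows[[length(beh_rows) + 1]] <- cbind(
        cov_row, data.frame(condition = conds$condition[k],
                            social = conds$social[k],
                            mentalizing = conds$mentalizing[k],
                            rt = mean(bsel$rt, na.rm = TRUE),
                            accuracy = mean(bsel$accuracy),
                            stringsAsFactors = FALSE))
    }
    # collapsed Peer / Character summaries
    if ("collapsed" %in% include) for (soc in c("Peer", "Character")) {
      sel <- conds$condition[conds$social == soc]
      sel <- sel[sel %in% names(mats)]
      if (length(sel) < 1) next
      Cc <- collapse_conditions(mats, sel)
      sm <- network_summary_fast(Cc, rois, nodes = FALSE)
      bsel <- beh[beh$social == soc, ]
      row <- cbind(cov_row, data.frame(social = soc, stringsAsFactors = FALSE))
      for (nw in nets) row[[paste0("within_", nw)]] <- sm$within[[nw]]
      for (pp in net_pairs)
        row[[paste0("between_", pp[1], "_", pp[2])]] <-
          sm$between[[paste(pp, collapse = "|")]]
      row$rt <- mean(bsel$rt, na.rm = TRUE)
      row$accuracy <- mean(bsel$accuracy)
      rep_sub <- subj$reports[subj$reports$social == soc, ]
      for (m in seq_len(nrow(rep_sub)))
        row[[gsub("[^A-Za-z]", "", rep_sub$measure[m])]] <- rep_sub$score[m]
      col_rows[[length(col_rows) + 1]] <- row
    }
    if ("reports" %in% include && !is.null(subj$reports))
      rep_rows[[length(rep_rows) + 1]] <- cbind(
        cov_row[rep(1, nrow(subj$reports)), ], subj$reports)
  }
  finish <- function(rows) {
    if (!length(rows)) return(NULL)
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    if ("social" %in% names(df))
      df$social <- factor(df$social, levels = c("Character", "Peer"))
    if ("mentalizing" %in% names(df))
      df$mentalizing <- factor(df$mentalizing,
                               levels = c("Non-Mental", "Mental"))
    if ("gender" %in% names(df)) df$gender <- factor(df$gender)
    df
  }
  list(network = finish(net_rows), node = finish(node_rows),
       behavior = finish(beh_rows), collapsed = finish(col_rows),
       reports = finish(rep_rows), matrices = mats_all,
       profiles = prof[prof$subject_id %in% names(beta_list), ])
}

# outcome columns of a network table (within_* then between_*)
network_outcomes <- function(tab) {
  grep("^(within|between)_", names(tab), value = TRUE)
}

# network_summary with optional node strengths (skipping them speeds up
# the large simulation loops); results identical to network_summary()
network_summary_fast <- function(C, rois, nodes = TRUE) {
  if (nodes) return(network_summary(C, rois))
  nets <- unique(rois$network[match(rownames(C), rois$name)])
  within <- vapply(nets, function(nw) within_network_mean(C, rois, nw),
                   numeric(1))
  pairs <- if (length(nets) > 1) utils::combn(nets, 2, simplify = FALSE)
    else list()
  between <- vapply(pairs, function(p)
    between_network_mean(C, rois, p[1], p[2]), numeric(1))
  names(between) <- vapply(pairs, paste, character(1), collapse = "|")
  list(within = within, between = between, nodes = NULL)
}
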