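#' Default pipeline configuration
#'
#' All thresholds and simulation settings of the pipeline in one nested
#' list; round-trips losslessly through YAML or JSON via [write_config()]
#' / [read_config()].
#'
#' @param ... Named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return Configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_subjects = 50L, seed = 1L, mode = "full", voxel_mode = FALSE,
    design = list(n_runs = 4L, trials_per_run = 24L, tr = 1.25,
                  volumes_per_run = 352L),
    truth = list(),
    qc = c(qc_thresholds(), list(head_radius = 50)),
    glm = list(hrf_dt = 0.02, baseline_order = 3L),
    connectivity = list(fisher_z = FALSE, roi_file = NULL)
  )
  over <- list(...)
  if (length(over)) cfg <- modifyList(cfg, over)
  cfg
}

#' @rdname default_config
#' @param path File ending in .yaml/.yml or .json.
#' @param config Configuration list to serialize.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  modifyList(default_config(), raw)
}

config_rois <- function(config) {
  if (!is.null(config$connectivity$roi_file))
    read_roi_table(config$connectivity$roi_file)
  else default_rois()
}

config_truth <- function(config) do.call(default_truth, config$truth)

subject_dirs <- function(bids_dir) {
  sort(list.dirs(bids_dir, recursive = FALSE, full.names = FALSE))[
    grepl("^sub-", sort(list.dirs(bids_dir, recursive = FALSE,
                                  full.names = FALSE)))]
}

#' Simulate a synthetic cohort to disk
#'
#' Writes a BIDS-like layout: `participants.tsv`, `reports.tsv`, and per
#' subject `sub-XX/func/` with per-run events.tsv (incl. accuracy),
#' motion.txt and bold_roi.tsv, plus a ground_truth.json with the planted
#' amplitudes and subject parameters.
#'
#' @param config Configuration (see [default_config()]).
#' @param out_dir Output directory.
#' @param force Overwrite an existing simulated cohort.
#' @return The output directory, invisibly; attribute `cohort` carries the
#'   in-memory cohort.
#' @export
cmd_simulate <- function(config = default_config(), out_dir, force = FALSE) {
  if (file.exists(file.path(out_dir, "participants.tsv")) && !force)
    stop("existing simulated cohort at ", out_dir, "; use force = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- config_truth(config)
  rois <- config_rois(config)
  cohort <- generate_cohort(config$n_subjects, truth, seed = config$seed,
                            mode = "full", design_args = config$design,
                            rois = rois, voxel_mode = isTRUE(config$voxel_mode))
  prof <- cohort$profiles
  write.table(prof[, c("subject_id", "age", "gender", "iq")],
              file.path(out_dir, "participants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  reports <- do.call(rbind, lapply(names(cohort$subjects), function(id)
    cbind(subject_id = id, cohort$subjects[[id]]$reports)))
  write.table(reports, file.path(out_dir, "reports.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (id in names(cohort$subjects)) {
    subj <- cohort$subjects[[id]]
    func <- file.path(out_dir, id, "func")
    dir.create(func, recursive = TRUE, showWarnings = FALSE)
    ev_all <- events_frame(subj$design, subj$behavior)
    for (r in seq_len(subj$design$n_runs)) {
      ev <- ev_all[ev_all$run == r, , drop = FALSE]
      acc <- rep(NA, nrow(ev))
      guess <- ev$trial_type != "feedback"
      acc[guess] <- subj$behavior$accuracy[subj$behavior$run == r]
      ev$accuracy <- acc
      write_events_tsv(ev, file.path(func, sprintf(
        "%s_task-social_run-%d_events.tsv", id, r)))
      write_motion_txt(subj$motion[[r]], file.path(func, sprintf(
        "%s_task-social_run-%d_motion.txt", id, r)))
      write_bold_tsv(subj$bold[[r]], file.path(func, sprintf(
        "%s_task-social_run-%d_bold_roi.tsv", id, r)))
    }
    gt <- list(subject_id = id, age = subj$profile$age,
               rt_intercept = subj$profile$rt_intercept,
               amplitudes = lapply(subj$amplitudes, function(a)
                 as.data.frame(a)))
    jsonlite::write_json(gt, file.path(out_dir, id, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(invisible(out_dir), cohort = cohort)
}

# Reconstruct a cohort-like object from a simulated BIDS directory.
read_bids_cohort <- function(bids_dir, config = default_config()) {
  rois <- config_rois(config)
  prof <- read.delim(file.path(bids_dir, "participants.tsv"),
                     stringsAsFactors = FALSE)
  reports_path <- file.path(bids_dir, "reports.tsv")
  reports <- if (file.exists(reports_path))
    read.delim(reports_path, stringsAsFactors = FALSE) else NULL
  conds <- condition_table()
  subjects <- list()
  for (id in prof$subject_id) {
    func <- file.path(bids_dir, id, "func")
    ev_files <- sort(list.files(func, "_events\\.tsv$", full.names = TRUE))
    if (!length(ev_files)) stop("no events files for ", id, " in ", func)
    events <- list(); behavior <- list(); motion <- list(); bold <- list()
    for (f in ev_files) {
      r <- as.integer(sub(".*_run-(\\d+)_events\\.tsv$", "\\1", f))
      ev <- read_events_tsv(f)
      ev$run <- r
      events[[r]] <- ev
      guess <- ev[ev$trial_type != "feedback", , drop = FALSE]
      k <- match(guess$trial_type, conds$condition)
      behavior[[r]] <- data.frame(
        run = r, trial = seq_len(nrow(guess)), condition = guess$trial_type,
        social = conds$social[k], mentalizing = conds$mentalizing[k],
        accuracy = as.logical(guess$accuracy), rt = guess$response_time,
        stringsAsFactors = FALSE)
      mf <- sub("_events\\.tsv$", "_motion.txt", f)
      if (file.exists(mf)) motion[[r]] <- read_motion_txt(mf)
      bf <- sub("_events\\.tsv$", "_bold_roi.tsv", f)
      if (file.exists(bf)) bold[[r]] <- read_bold_tsv(bf)
    }
    subjects[[id]] <- list(
      profile = as.list(prof[prof$subject_id == id, ]),
      events = do.call(rbind, events),
      behavior = do.call(rbind, behavior),
      motion = motion, bold = bold,
      reports = if (!is.null(reports))
        reports[reports$subject_id == id, c("measure", "social", "score")]
      else NULL)
  }
  prof$mean_fd <- NA_real_
  structure(list(profiles = prof, subjects = subjects, rois = rois,
                 truth = config_truth(config), mode = "disk"),
            class = "bc_cohort")
}

#' Run pipeline stages on a simulated cohort directory
#'
#' Executes, in order, the requested stages: `qc` (framewise displacement,
#' censor masks, run/subject exclusions), `betas` (LSS beta series for
#' retained subjects), `connectivity` (per-condition matrices and network
#' summaries), `stats` (the mixed-model battery). Outputs are written
#' under `derivatives_dir`; each stage reads its inputs from the previous
#' stage's files.
#'
#' @param config Configuration list.
#' @param bids_dir Simulated cohort directory (from [cmd_simulate()]).
#' @param derivatives_dir Output directory.
#' @param stages Subset of `c("qc", "betas", "connectivity", "stats")`.
#' @return List of per-stage summaries; a run manifest (config, seeds,
#'   file checksums) is written to `derivatives_dir/manifest.json`.
#' @export
cmd_run <- function(config = default_config(), bids_dir, derivatives_dir,
                    stages = c("qc", "betas", "connectivity", "stats")) {
  stages <- match.arg(stages, c("qc", "betas", "connectivity", "stats"),
                      several.ok = TRUE)
  dir.create(derivatives_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- read_bids_cohort(bids_dir, config)
  thresholds <- config$qc[names(qc_thresholds())]
  out <- list()

  qc_dir <- file.path(derivatives_dir, "qc")
  if ("qc" %in% stages) {
    dir.create(qc_dir, showWarnings = FALSE)
    excl <- list(); subj_rows <- list()
    for (id in names(cohort$subjects)) {
      subj <- cohort$subjects[[id]]
      if (!length(subj$motion)) stop("stage qc: no motion files for ", id)
      qc <- qc_subject(subj$motion, subj$behavior, thresholds,
                       head_radius = config$qc$head_radius)
      fd_tab <- do.call(rbind, lapply(seq_along(qc$fd), function(r)
        data.frame(run = r, volume = seq_along(qc$fd[[r]]), fd = qc$fd[[r]],
                   censored = qc$censor[[r]])))
      write.table(fd_tab, file.path(qc_dir, paste0(id, "_qc.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      for (r in seq_along(qc$runs))
        excl[[paste(id, r)]] <- data.frame(
          subject_id = id, run = r, excluded = qc$runs[[r]]$excluded,
          reasons = paste(qc$runs[[r]]$reasons, collapse = ";"),
          mean_fd = qc$runs[[r]]$mean_fd,
          frac_remaining = qc$runs[[r]]$frac_remaining,
          stringsAsFactors = FALSE)
      subj_rows[[id]] <- data.frame(
        subject_id = id, included = qc$subject$included,
        n_usable = qc$subject$n_usable,
        usable_runs = paste(qc$subject$usable_runs, collapse = ","),
        mean_fd = qc$mean_fd, stringsAsFactors = FALSE)
      if (qc$subject$included)
        message("qc: ", id, " included (", qc$subject$n_usable, " runs)")
      else message("qc: ", id, " EXCLUDED (usable runs = ",
                   qc$subject$n_usable, ")")
    }
    write.table(do.call(rbind, excl), file.path(qc_dir, "exclusions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(do.call(rbind, subj_rows),
                file.path(qc_dir, "subjects.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$qc <- do.call(rbind, subj_rows)
  }

  betas_dir <- file.path(derivatives_dir, "betas")
  if ("betas" %in% stages) {
    subj_tab_path <- file.path(qc_dir, "subjects.tsv")
    if (!file.exists(subj_tab_path))
      stop("stage betas: missing qc outputs (", subj_tab_path,
           "); run the qc stage first")
    subj_tab <- read.delim(subj_tab_path, stringsAsFactors = FALSE)
    dir.create(betas_dir, showWarnings = FALSE)
    hrf <- build_hrf(dt = config$glm$hrf_dt)
    for (id in subj_tab$subject_id[subj_tab$included]) {
      subj <- cohort$subjects[[id]]
      keep <- as.integer(strsplit(
        subj_tab$usable_runs[subj_tab$subject_id == id], ",")[[1]])
      fd <- lapply(subj$motion, compute_fd,
                   head_radius = config$qc$head_radius)
      censor <- lapply(fd, censor_volumes, threshold = thresholds$fd_censor)
      ev <- subj$events
      ev$duration[is.na(ev$duration)] <- 8
      ev <- ev[ev$run %in% keep, , drop = FALSE]
      bs <- estimate_beta_series(subj$bold[keep], ev, config$design$tr,
                                 motion = subj$motion[keep],
                                 censor = censor[keep], hrf = hrf,
                                 baseline_order = config$glm$baseline_order)
      for (cond in names(bs))
        write.table(bs[[cond]], file.path(betas_dir, sprintf(
          "%s_desc-%s_betas.tsv", id, gsub("[^A-Za-z]", "", cond))),
          sep = "\t", quote = FALSE, row.names = FALSE)
      diag <- attr(bs, "diagnostics")
      coll <- suppressWarnings(design_collinearity(
        ev, vapply(subj$bold[keep], nrow, integer(1)), config$design$tr, hrf))
      jsonlite::write_json(
        list(subject = id, runs_used = keep,
             n_fits = lapply(diag, `[[`, "n_fits"),
             n_regressors = lapply(diag, `[[`, "n_regressors"),
             max_task_regressor_correlation = as.numeric(coll)),
        file.path(betas_dir, paste0(id, "_design.json")),
        auto_unbox = TRUE, digits = NA)
      message("betas: ", id, " estimated (runs ",
              paste(keep, collapse = ","), ")")
    }
  }

  conn_dir <- file.path(derivatives_dir, "connectivity")
  if ("connectivity" %in% stages || "stats" %in% stages) {
    beta_files <- list.files(betas_dir, "_betas\\.tsv$")
    if (!length(beta_files))
      stop("stage connectivity: no beta series under ", betas_dir,
           "; run the betas stage first")
  }
  if ("connectivity" %in% stages) {
    dir.create(conn_dir, showWarnings = FALSE)
    beta_list <- read_beta_dir(betas_dir)
    rois <- config_rois(config)
    long <- list(); mats <- list()
    for (id in names(beta_list)) {
      mats[[id]] <- lapply(beta_list[[id]], beta_corr_matrix,
                           fisher_z = isTRUE(config$connectivity$fisher_z))
      for (cond in names(mats[[id]])) {
        C <- mats[[id]][[cond]]
        sm <- network_summary(C, rois)
        long[[paste(id, cond)]] <- rbind(
          data.frame(subject_id = id, condition = cond, measure =
                       paste0("within_", names(sm$within)),
                     value = unname(sm$within), stringsAsFactors = FALSE),
          data.frame(subject_id = id, condition = cond, measure =
                       paste0("between_", gsub("\\|", "_", names(sm$between))),
                     value = unname(sm$between), stringsAsFactors = FALSE),
          data.frame(subject_id = id, condition = cond, measure =
                       paste0("node_within_", sm$nodes$name),
                     value = sm$nodes$within_strength,
                     stringsAsFactors = FALSE),
          data.frame(subject_id = id, condition = cond, measure =
                       paste0("node_between_", sm$nodes$name),
                     value = sm$nodes$between_strength,
                     stringsAsFactors = FALSE))
        ut <- which(upper.tri(C), arr.ind = TRUE)
        edge <- data.frame(subject_id = id, condition = cond,
                           roi1 = rownames(C)[ut[, 1]],
                           roi2 = colnames(C)[ut[, 2]], r = C[ut],
                           stringsAsFactors = FALSE)
        write.table(edge, file.path(conn_dir, sprintf(
          "%s_desc-%s_matrix.tsv", id, gsub("[^A-Za-z]", "", cond))),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    write.table(do.call(rbind, long), file.path(conn_dir, "summaries.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$connectivity <- length(mats)
  }

  stats_dir <- file.path(derivatives_dir, "stats")
  if ("stats" %in% stages) {
    if (!file.exists(file.path(qc_dir, "subjects.tsv")))
      stop("stage stats: missing qc outputs; run the qc stage first")
    dir.create(stats_dir, showWarnings = FALSE)
    beta_list <- read_beta_dir(betas_dir)
    subj_tab <- read.delim(file.path(qc_dir, "subjects.tsv"),
                           stringsAsFactors = FALSE)
    cohort$profiles$mean_fd <-
      subj_tab$mean_fd[match(cohort$profiles$subject_id,
                             subj_tab$subject_id)]
    tables <- cohort_tables(cohort, beta_list,
                            fisher_z = isTRUE(config$connectivity$fisher_z))
    conn <- run_connectivity_models(tables)
    beh <- run_behavior_models(tables)
    reps <- if (!is.null(tables$reports)) run_report_models(tables) else NULL
    bb <- run_brain_behavior_models(tables, "rt")
    res <- rbind(
      cbind(family = "network", conn$network_table),
      cbind(family = "brain_behavior", bb$table))
    write.table(res, file.path(stats_dir, "models.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(conn$within_between,
                file.path(stats_dir, "within_between.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(conn$node_table))
      write.table(conn$node_table, file.path(stats_dir, "nodes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(reps))
      write.table(reps$table, file.path(stats_dir, "reports.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    out$stats <- res
  }

  files <- list.files(derivatives_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("betaconn")),
    seed = config$seed, stages = stages, config = config,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(derivatives_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

read_beta_dir <- function(betas_dir) {
  files <- list.files(betas_dir, "_betas\\.tsv$", full.names = TRUE)
  ids <- unique(sub("_desc-.*$", "", basename(files)))
  conds <- condition_table()
  key <- gsub("[^A-Za-z]", "", conds$condition)
  out <- list()
  for (id in ids) {
    bl <- list()
    for (k in seq_along(key)) {
      f <- file.path(betas_dir, sprintf("%s_desc-%s_betas.tsv", id, key[k]))
      if (file.exists(f)) bl[[conds$condition[k]]] <-
          as.matrix(read.delim(f, check.names = FALSE))
    }
    out[[id]] <- bl
  }
  out
}

#' Human-readable summary of a pipeline run
#'
#' Markdown report: exclusion counts, network pair counts, mean
#' connectivity per condition, and the fitted model tables with FDR flags.
#'
#' @param derivatives_dir Directory written by [cmd_run()].
#' @param path Optional output file (default
#'   `derivatives_dir/report.md`).
#' @return The report text, invisibly.
#' @export
cmd_report <- function(derivatives_dir,
                       path = file.path(derivatives_dir, "report.md")) {
  qc_path <- file.path(derivatives_dir, "qc", "subjects.tsv")
  if (!file.exists(qc_path) &&
      !file.exists(file.path(derivatives_dir, "connectivity",
                             "summaries.tsv"))) {
    message("nothing to report: no pipeline outputs under ",
            derivatives_dir)
    return(invisible(""))
  }
  lines <- c("# Pipeline report", "")
  rois <- default_rois()
  nets <- table(rois$network)
  n_within <- sum(choose(nets, 2))
  n_between <- prod(nets)
  lines <- c(lines, sprintf(
    "Default node set: %d ROIs, %s; %d within-network pairs per network (%s), %d between-network pairs.",
    nrow(rois), paste(names(nets), nets, sep = "=", collapse = ", "),
    choose(nets[[1]], 2), paste(choose(nets, 2), collapse = "/"), n_between),
    "")
  if (file.exists(qc_path)) {
    subj <- read.delim(qc_path, stringsAsFactors = FALSE)
    lines <- c(lines, "## Exclusions", "",
               sprintf("- %d of %d subjects included (>= 3 usable runs)",
                       sum(subj$included), nrow(subj)),
               sprintf("- mean FD across subjects: %.3f mm",
                       mean(subj$mean_fd)), "")
  }
  summ_path <- file.path(derivatives_dir, "connectivity", "summaries.tsv")
  if (file.exists(summ_path)) {
    summ <- read.delim(summ_path, stringsAsFactors = FALSE)
    net <- summ[grepl("^(within|between)_", summ$measure), ]
    agg <- aggregate(value ~ condition + measure, net, mean)
    lines <- c(lines, "## Mean connectivity by condition", "",
               "| condition | measure | mean r |", "|---|---|---|",
               sprintf("| %s | %s | %.3f |", agg$condition, agg$measure,
                       agg$value), "")
  }
  models_path <- file.path(derivatives_dir, "stats", "models.tsv")
  if (file.exists(models_path)) {
    mt <- read.delim(models_path, stringsAsFactors = FALSE)
    lines <- c(lines, "## Model results", "",
               "| family | model | term | F | df | p |", "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %.2f | (%d, %d) | %.4g |",
                       mt$family, mt$model, mt$term, mt$F, mt$df1, mt$df2,
                       mt$p), "")
  }
  writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}
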