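# Mean-center continuous covariates so that marginal main-effect tests in
# models with interactions are evaluated at the covariate mean (slopes and
# interaction terms are unaffected).
center_covariates <- function(d, cols) {
  for (cc in intersect(cols, names(d)))
    d[[cc]] <- d[[cc]] - mean(d[[cc]], na.rm = TRUE)
  d
}

# One-sided within- vs between-network paired t-tests (per network), on
# connectivity averaged across all conditions, FDR-corrected.
within_between_tests <- function(tables) {
  col <- tables$collapsed
  if (is.null(col)) return(NULL)
  nets <- sub("^within_", "", grep("^within_", names(col), value = TRUE))
  bet_cols <- grep("^between_", names(col), value = TRUE)
  if (!length(bet_cols)) return(NULL)
  bet_col <- bet_cols[1]
  agg <- aggregate(col[, c(paste0("within_", nets), bet_col)],
                   by = list(subject_id = col$subject_id), FUN = mean)
  res <- do.call(rbind, lapply(nets, function(nw) {
    tt <- paired_t(agg[[paste0("within_", nw)]], agg[[bet_col]],
                   tail = "greater")
    data.frame(network = nw, t = tt$t, df = tt$df, p = tt$p,
               mean_diff = tt$mean_diff, stringsAsFactors = FALSE)
  }))
  res$p_fdr <- fdr_bh(res$p)
  res
}

#' Network- and node-level connectivity regressions
#'
#' Fits the network-level mixed models (one per within-/between-network
#' outcome): connectivity ~ social + mentalizing + age + social:age, with
#' gender, mean FD and IQ as covariates and a random intercept per
#' subject. For outcomes whose social x age interaction is significant,
#' runs per-condition post-hoc OLS regressions of collapsed connectivity
#' on age (controlling gender, mean FD, IQ). Also fits node-level models
#' of each ROI's within- and between-network strength, with BH-FDR on the
#' interaction p-values across the node x strength family, and the
#' one-tailed within- versus between-network paired t-tests.
#'
#' @param tables Output of [cohort_tables()].
#' @param alpha Significance level gating post-hoc tests (default 0.05).
#' @return List: `network` (named list of `bc_model`), `network_table`,
#'   `posthoc` (per-condition age regressions), `node_table` (one row per
#'   node x strength with interaction F/p and `p_fdr`), `node_models`,
#'   `within_between` (paired t table).
#' @export
run_connectivity_models <- function(tables, alpha = 0.05) {
  tab <- center_covariates(tables$network, c("age", "iq", "mean_fd"))
  outcomes <- network_outcomes(tab)
  models <- list()
  for (oc in outcomes) {
    d <- tab; d$value <- d[[oc]]
    models[[oc]] <- fit_lmm(
      value ~ social + mentalizing + age + social:age + gender + mean_fd + iq,
      d, label = oc)
  }
  # post-hoc per-condition age regressions where the interaction is significant
  posthoc <- list()
  col <- tables$collapsed
  if (!is.null(col)) for (oc in outcomes) {
    p_int <- model_term(models[[oc]], "social:age")$p
    if (is.na(p_int) || p_int >= alpha) next
    for (soc in levels(col$social)) {
      d <- col[col$social == soc, ]
      d$value <- d[[oc]]
      fit <- lm(value ~ age + gender + mean_fd + iq, data = d)
      dr <- drop1(fit, test = "F")
      posthoc[[paste(oc, soc, sep = ".")]] <- data.frame(
        outcome = oc, social = soc,
        estimate = coef(fit)[["age"]],
        F = dr["age", "F value"], df1 = 1, df2 = fit$df.residual,
        p = dr["age", "Pr(>F)"], stringsAsFactors = FALSE)
    }
  }
  posthoc <- if (length(posthoc)) do.call(rbind, posthoc) else NULL
  # node-strength models with FDR across the node x strength family
  node_models <- list(); node_rows <- list()
  if (!is.null(tables$node)) {
    nd <- center_covariates(tables$node, c("age", "iq", "mean_fd"))
    strengths <- c("within_strength", "between_strength")
    strengths <- strengths[vapply(strengths, function(s)
      !all(is.na(nd[[s]])), logical(1))]
    for (strength in strengths) {
      for (nm in unique(nd$name)) {
        d <- nd[nd$name == nm, ]; d$value <- d[[strength]]
        key <- paste(nm, strength, sep = ".")
        m <- fit_lmm(
          value ~ social + mentalizing + age + social:age + gender +
            mean_fd + iq, d, label = key)
        node_models[[key]] <- m
        it <- model_term(m, "social:age")
        node_rows[[key]] <- data.frame(
          node = nm, strength = strength, F = it$F, df1 = it$df1,
          df2 = it$df2, p = it$p, stringsAsFactors = FALSE)
      }
    }
  }
  node_table <- if (length(node_rows)) {
    nt <- do.call(rbind, node_rows); rownames(nt) <- NULL
    nt$p_fdr <- fdr_bh(nt$p)
    nt
  } else NULL
  list(network = models, network_table = model_table(models),
       posthoc = posthoc, node_table = node_table,
       node_models = node_models,
       within_between = within_between_tests(tables))
}

#' In-scanner behavior regressions
#'
#' Mixed models for RT and accuracy cell means: outcome ~ social +
#' mentalizing + age + social:age + gender + iq, random intercept per
#' subject. Post-hocs: paired t-test of Peer versus Character mean RT and
#' per-condition accuracy-age OLS regressions (controlling gender, IQ).
#'
#' @param tables Output of [cohort_tables()].
#' @param alpha Gate for post-hoc tests.
#' @return List: `rt`, `accuracy` (`bc_model` or `NULL` when degenerate),
#'   `rt_paired_t`, `accuracy_age_posthoc`.
#' @export
run_behavior_models <- function(tables, alpha = 0.05) {
  beh <- center_covariates(tables$behavior, c("age", "iq"))
  fit_one <- function(outcome) {
    d <- beh; d$value <- d[[outcome]]
    if (sd(d$value, na.rm = TRUE) == 0) {
      warning("degenerate ", outcome, " outcome (zero variance): skipped")
      return(NULL)
    }
    fit_lmm(value ~ social + mentalizing + age + social:age + gender + iq,
            d, label = outcome)
  }
  rt_m <- fit_one("rt")
  acc_m <- fit_one("accuracy")
  agg <- aggregate(cbind(rt, accuracy) ~ subject_id + social, beh, mean)
  peer <- agg[agg$social == "Peer", ]
  char <- agg[agg$social == "Character", ]
  char <- char[match(peer$subject_id, char$subject_id), ]
  rt_t <- paired_t(peer$rt, char$rt)
  acc_post <- NULL
  if (!is.null(acc_m)) {
    p_int <- model_term(acc_m, "social:age")$p
    if (!is.na(p_int) && p_int < alpha) {
      prof <- tables$profiles
      acc_post <- do.call(rbind, lapply(c("Peer", "Character"), function(soc) {
        d <- agg[agg$social == soc, ]
        d <- merge(d, prof, by = "subject_id")
        fit <- lm(accuracy ~ age + gender + iq, data = d)
        dr <- drop1(fit, test = "F")
        data.frame(social = soc, estimate = coef(fit)[["age"]],
                   F = dr["age", "F value"], df2 = fit$df.residual,
                   p = dr["age", "Pr(>F)"], stringsAsFactors = FALSE)
      }))
    }
  }
  list(rt = rt_m, accuracy = acc_m, rt_paired_t = rt_t,
       accuracy_age_posthoc = acc_post)
}

#' Subjective-report regressions and post-hoc Wilcoxon tests
#'
#' Per measure: score ~ social + age + social:age + gender + iq with a
#' random intercept per subject; interaction p-values FDR-corrected across
#' the six measures; paired Wilcoxon signed-rank Peer versus Character
#' post-hocs.
#'
#' @param tables Output of [cohort_tables()].
#' @return List: `models` (per measure), `table` (measure, social-effect
#'   and interaction F/p with `p_int_fdr`, Wilcoxon p).
#' @export
run_report_models <- function(tables) {
  rep_tab <- center_covariates(tables$reports, c("age", "iq"))
  rep_tab$social <- factor(rep_tab$social, levels = c("Character", "Peer"))
  rep_tab$gender <- factor(rep_tab$gender)
  models <- list(); rows <- list()
  for (m in unique(rep_tab$measure)) {
    d <- rep_tab[rep_tab$measure == m, ]
    d$value <- d$score
    fit <- fit_lmm(value ~ social + age + social:age + gender + iq, d,
                   label = m)
    models[[m]] <- fit
    wide_p <- d$score[d$social == "Peer"][order(d$subject_id[d$social == "Peer"])]
    wide_c <- d$score[d$social == "Character"][order(d$subject_id[d$social == "Character"])]
    wx <- tryCatch(wilcoxon_signed_rank(wide_p, wide_c),
                   error = function(e) list(p = NA_real_))
    rows[[m]] <- data.frame(
      measure = m,
      F_social = model_term(fit, "social")$F,
      p_social = model_term(fit, "social")$p,
      F_int = model_term(fit, "social:age")$F,
      p_int = model_term(fit, "social:age")$p,
      p_wilcoxon = wx$p, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  tab$p_int_fdr <- fdr_bh(tab$p_int)
  list(models = models, table = tab)
}

#' Brain-behavior mixed models
#'
#' On the collapsed Peer/Character summaries: connectivity ~ social +
#' behavior + social:behavior + age + gender + mean FD + IQ with a random
#' intercept per subject, one model per network outcome. For significant
#' interactions, per-condition post-hoc OLS regressions and partial
#' Pearson correlations controlling for age.
#'
#' @param tables Output of [cohort_tables()].
#' @param behavior Column of the collapsed table to use as the behavioral
#'   predictor (default `"rt"`; report measures use their compacted names,
#'   e.g. `"LikedChatting"`).
#' @param alpha Gate for post-hoc tests.
#' @return List: `models`, `table`, `posthoc`, `partial_cor` (per outcome,
#'   across-condition mean connectivity vs behavior controlling age).
#' @export
run_brain_behavior_models <- function(tables, behavior = "rt",
                                      alpha = 0.05) {
  col <- tables$collapsed
  if (!behavior %in% names(col)) stop("unknown behavior measure: ", behavior)
  if (sd(col[[behavior]], na.rm = TRUE) == 0)
    stop("degenerate predictor: '", behavior, "' is constant")
  outcomes <- network_outcomes(col)
  models <- list(); posthoc <- list(); pcors <- list()
  col_c <- center_covariates(col, c("age", "iq", "mean_fd", behavior))
  for (oc in outcomes) {
    d <- col_c; d$value <- d[[oc]]; d$beh <- d[[behavior]]
    if (any(tapply(d$beh, d$subject_id, function(v) sd(v) == 0)) &&
        sd(tapply(d$beh, d$subject_id, mean)) == 0)
      stop("degenerate predictor: '", behavior, "' is constant")
    m <- fit_lmm(value ~ social + beh + social:beh + age + gender +
                   mean_fd + iq, d, label = paste(oc, behavior, sep = "~"))
    models[[oc]] <- m
    p_int <- model_term(m, "social:beh")$p
    if (!is.na(p_int) && p_int < alpha) {
      for (soc in levels(col$social)) {
        ds <- d[d$social == soc, ]
        fit <- lm(value ~ beh + age + gender + mean_fd + iq, data = ds)
        dr <- drop1(fit, test = "F")
        posthoc[[paste(oc, soc, sep = ".")]] <- data.frame(
          outcome = oc, social = soc, estimate = coef(fit)[["beh"]],
          F = dr["beh", "F value"], df2 = fit$df.residual,
          p = dr["beh", "Pr(>F)"], stringsAsFactors = FALSE)
      }
    }
    # across-condition mean connectivity vs behavior, controlling age
    agg <- aggregate(d[, c("value", "beh", "age")],
                     by = list(subject_id = d$subject_id), FUN = mean)
    pc <- partial_cor(agg$value, agg$beh, agg[, "age", drop = FALSE])
    pcors[[oc]] <- data.frame(outcome = oc, r = pc$r, df = pc$df, p = pc$p,
                              stringsAsFactors = FALSE)
  }
  list(models = models, table = model_table(models),
       posthoc = if (length(posthoc)) do.call(rbind, posthoc) else NULL,
       partial_cor = do.call(rbind, pcors))
}

#' Age-quartile Peer versus Character contrasts
#'
#' Splits subjects at the empirical 25th/75th age percentiles (strict
#' inequalities, linear-interpolation quantiles) and runs two-tailed
#' paired t-tests of collapsed Peer versus Character connectivity within
#' each group, per network outcome.
#'
#' @param tables Output of [cohort_tables()].
#' @param min_group Minimum subjects per quartile group (default 3).
#' @return Data frame: outcome, group, n, mean_diff (Peer - Character),
#'   t, df, p; attribute `cutoffs` holds the quartile boundaries.
#' @export
quartile_contrast <- function(tables, min_group = 3) {
  col <- tables$collapsed
  ages <- tapply(col$age, col$subject_id, unique)
  if (sd(ages) == 0) stop("age is constant: quartiles undefined")
  q <- quantile(ages, c(0.25, 0.75), type = 7)
  groups <- list(younger = names(ages)[ages < q[1]],
                 older = names(ages)[ages > q[2]])
  outcomes <- network_outcomes(col)
  rows <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) < min_group)
      stop("quartile group '", g, "' has fewer than ", min_group, " subjects")
    sel <- col[col$subject_id %in% ids, ]
    for (oc in outcomes) {
      peer <- sel[sel$social == "Peer", ]
      char <- sel[sel$social == "Character", ]
      char <- char[match(peer$subject_id, char$subject_id), ]
      tt <- paired_t(peer[[oc]], char[[oc]])
      rows[[paste(g, oc)]] <- data.frame(
        outcome = oc, group = g, n = nrow(peer), mean_diff = tt$mean_diff,
        t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  attr(out, "cutoffs") <- q
  out
}

#' Re-run the connectivity models on a low age-motion subsample
#'
#' Default selector greedily removes the subject whose removal most
#' reduces `|cor(age, mean FD)|` until the correlation falls below
#' `threshold` or the target sample size is reached, then refits the
#' network-level models on the retained subjects.
#'
#' @param tables Output of [cohort_tables()].
#' @param target_n Sample size floor (default 30).
#' @param threshold Target `|cor(age, mean_fd)|` (default 0.05).
#' @param selector Optional function `profiles -> subject ids` replacing
#'   the greedy rule.
#' @return List: `subjects`, `cor_age_fd`, `models`
#'   (from [run_connectivity_models()] on the subsample).
#' @export
subsample_reanalysis <- function(tables, target_n = 30, threshold = 0.05,
                                 selector = NULL) {
  prof <- tables$profiles
  if (target_n > nrow(prof))
    stop("target_n exceeds the cohort size (", nrow(prof), ")")
  if (target_n < 10) stop("selector infeasible: need at least 10 subjects")
  if (is.null(selector)) {
    keep <- prof$subject_id
    repeat {
      r_now <- cor(prof$age[prof$subject_id %in% keep],
                   prof$mean_fd[prof$subject_id %in% keep])
      if (abs(r_now) < threshold || length(keep) <= target_n) break
      cand <- vapply(keep, function(drop_id) {
        ids <- setdiff(keep, drop_id)
        abs(cor(prof$age[prof$subject_id %in% ids],
                prof$mean_fd[prof$subject_id %in% ids]))
      }, numeric(1))
      keep <- setdiff(keep, keep[which.min(cand)])
    }
  } else keep <- selector(prof)
  if (length(keep) < 10) stop("selector infeasible: fewer than 10 subjects")
  sub_tables <- tables
  for (nm in c("network", "node", "behavior", "collapsed", "reports"))
    if (!is.null(sub_tables[[nm]]))
      sub_tables[[nm]] <-
        sub_tables[[nm]][sub_tables[[nm]]$subject_id %in% keep, ]
  sub_tables$profiles <- prof[prof$subject_id %in% keep, ]
  sub_tables$node <- NULL  # network-level refit only
  list(subjects = keep,
       cor_age_fd = cor(sub_tables$profiles$age, sub_tables$profiles$mean_fd),
       models = run_connectivity_models(sub_tables))
}
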