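cohort_cache <- new.env()
get_cohort_tables <- function() {
  if (is.null(cohort_cache$tabs)) {
    co <- generate_cohort(52, default_truth(), seed = 2027,
                          mode = "amplitude")
    cohort_cache$tabs <- cohort_tables(co)
  }
  cohort_cache$tabs
}

test_that("amplitude-mode cohorts carry complete planted structure", {
  co <- generate_cohort(2, default_truth(), seed = 99, mode = "amplitude")
  expect_equal(nrow(co$profiles), 2)
  expect_length(co$subjects, 2)
  s1 <- co$subjects[[1]]
  expect_equal(nrow(s1$behavior), 96)
  expect_equal(dim(s1$amplitudes[["Peer Mental"]]), c(24, 14))
  expect_equal(nrow(s1$reports), 12)
  # distinct subjects received distinct draws
  expect_false(identical(co$subjects[[1]]$amplitudes,
                         co$subjects[[2]]$amplitudes))
  # determinism
  co2 <- generate_cohort(2, default_truth(), seed = 99, mode = "amplitude")
  expect_identical(co$profiles, co2$profiles)
  expect_identical(co$subjects[[2]]$amplitudes, co2$subjects[[2]]$amplitudes)
})

test_that("zero age coupling leaves no expected Peer-Character difference", {
  truth <- default_truth(age_coupling = 0, rt_conn_coupling = 0)
  for (age in c(8.5, 12.5)) {
    Rp <- condition_correlation(truth, age, "Peer")
    Rc <- condition_correlation(truth, age, "Character")
    expect_equal(Rp, Rc, tolerance = 1e-12)
  }
  # positive coupling orders the conditions by age
  truth2 <- default_truth()
  Rp <- condition_correlation(truth2, 12.5, "Peer")
  Rc <- condition_correlation(truth2, 12.5, "Character")
  expect_gt(Rp[1, 2], Rc[1, 2])
  Rp_y <- condition_correlation(truth2, 8.5, "Peer")
  Rc_y <- condition_correlation(truth2, 8.5, "Character")
  expect_lt(Rp_y[1, 2], Rc_y[1, 2])
  expect_error(condition_correlation(default_truth(r_within = -0.9,
                                                   r_between = 0.9),
                                     10, "Peer"),
               "positive semi-definite")
})

test_that("the connectivity battery emits the full model set", {
  tabs <- get_cohort_tables()
  res <- run_connectivity_models(tabs)
  expect_setequal(names(res$network),
                  c("within_mentalizing", "within_reward",
                    "between_mentalizing_reward"))
  expect_equal(nrow(res$node_table), 28)  # 14 nodes x 2 strengths
  expect_true(all(res$node_table$p_fdr >= res$node_table$p - 1e-12))
  expect_equal(nrow(res$within_between), 2)
  # planted structure: within > between by construction
  expect_true(all(res$within_between$mean_diff > 0))
  expect_true(all(res$within_between$p < 0.001))
  # every network model reports the full term list
  for (m in res$network)
    expect_setequal(m$terms$term,
                    c("social", "mentalizing", "age", "gender", "mean_fd",
                      "iq", "social:age"))
})

test_that("single-network configurations yield one network model", {
  rois <- default_rois()[1:7, ]
  co <- generate_cohort(12, default_truth(), seed = 31, mode = "amplitude",
                        rois = rois)
  tabs <- cohort_tables(co)
  res <- run_connectivity_models(tabs)
  expect_equal(names(res$network), "within_mentalizing")
  expect_equal(sort(unique(res$node_table$node)), sort(rois$name))
  expect_equal(nrow(res$node_table), 7)  # within strength only
  expect_null(res$within_between)
})

test_that("behavior battery recovers the planted RT contrast", {
  tabs <- get_cohort_tables()
  res <- run_behavior_models(tabs)
  expect_equal(res$rt_paired_t$df, 51)
  # planted -0.08 s Peer speed-up, MC error at n=52 ~ 0.02
  expect_lt(abs(res$rt_paired_t$mean_diff - (-0.08)), 0.05)
  expect_lt(res$rt_paired_t$p, 0.01)
  expect_lt(model_term(res$rt, "social")$p, 0.01)
  # age slows nothing: RT decreases with age by construction
  expect_lt(model_term(res$rt, "age")$estimate, 0)
  # degenerate accuracy outcome is skipped with a warning
  tabs2 <- get_cohort_tables()
  tabs2$behavior$accuracy <- 1
  expect_warning(res2 <- run_behavior_models(tabs2), "degenerate")
  expect_null(res2$accuracy)
})

test_that("report battery finds Peer shifts on shifted measures only", {
  tabs <- get_cohort_tables()
  res <- run_report_models(tabs)
  expect_equal(nrow(res$table), 6)
  strong <- res$table$measure %in% c("Liked Chatting", "Liked Guessing",
                                     "Wanted to See")
  expect_true(all(res$table$p_wilcoxon[strong] < 0.05))
  expect_lt(res$table$p_wilcoxon[res$table$measure == "Liked Chatting"],
            1e-4)
  expect_gt(res$table$p_wilcoxon[res$table$measure == "Perceived Difficulty"],
            0.05)
  expect_true(all(res$table$p_int_fdr >= res$table$p_int - 1e-12))
})

test_that("brain-behavior battery requires a varying predictor", {
  tabs <- get_cohort_tables()
  res <- run_brain_behavior_models(tabs, "rt")
  expect_equal(nrow(res$partial_cor), 3)
  expect_setequal(unique(res$table$model),
                  c("within_mentalizing", "within_reward",
                    "between_mentalizing_reward"))
  tabs2 <- get_cohort_tables()
  tabs2$collapsed$rt <- 2
  expect_error(run_brain_behavior_models(tabs2, "rt"), "degenerate")
  expect_error(run_brain_behavior_models(tabs, "nope"), "unknown")
})

test_that("age quartiles split evenly and show the planted sign pattern", {
  tabs <- get_cohort_tables()
  qc <- quartile_contrast(tabs)
  # 52 uniform ages -> 13 subjects in each quartile group
  expect_true(all(qc$n == 13))
  expect_setequal(qc$group, c("younger", "older"))
  tabs_const <- tabs
  tabs_const$collapsed$age <- 10
  expect_error(quartile_contrast(tabs_const), "constant")
})

test_that("the greedy subsample selector decorrelates age and motion", {
  tabs <- get_cohort_tables()
  # induce a strong age-motion correlation
  set.seed(14)
  prof <- tabs$profiles
  prof$mean_fd <- 0.25 - 0.02 * (prof$age - mean(prof$age)) +
    rnorm(nrow(prof), 0, 0.04)
  tabs$profiles <- prof
  for (nm in c("network", "collapsed"))
    tabs[[nm]]$mean_fd <- prof$mean_fd[match(tabs[[nm]]$subject_id,
                                             prof$subject_id)]
  r0 <- cor(prof$age, prof$mean_fd)
  expect_lt(r0, -0.3)
  res <- subsample_reanalysis(tabs, target_n = 30, threshold = 0.05)
  expect_lt(abs(res$cor_age_fd), 0.05)
  expect_gte(length(res$subjects), 30)
  # identity selector reproduces the full-cohort fit
  res_id <- subsample_reanalysis(tabs, selector = function(p) p$subject_id)
  expect_equal(res_id$models$network_table$F,
               run_connectivity_models(tabs)$network_table$F,
               tolerance = 1e-8)
  expect_error(subsample_reanalysis(tabs, target_n = 500), "exceeds")
})
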