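#' Fit a random-intercept linear mixed model with marginal F tests
#'
#' REML fit of `fixed` with a single random intercept per subject via
#' [nlme::lme()], reporting marginal (drop-one) F tests per fixed term.
#' The denominator degrees of freedom follow the grouping-level
#' convention: terms varying within subject are tested against
#' `n_obs - n_subjects - p_within` df (e.g. F(1, 147) for 200 observations
#' from 50 subjects with three within-subject terms), between-subject
#' terms against `n_subjects - p_between - 1`. On convergence failure the
#' model falls back to ordinary least squares with a warning.
#'
#' @param fixed Fixed-effects formula, e.g.
#'   `value ~ social * age + mentalizing + gender + mean_fd + iq`.
#' @param data Long-format data frame; one row per subject x condition cell.
#' @param subject Name of the grouping column (default `"subject_id"`).
#' @param label Model label carried into the result.
#' @return Object of class `bc_model`: list with `label`, `fit_type`
#'   (`"lme"` or `"ols"`), `terms` (term, F, df1, df2, p), `coefficients`,
#'   `vif`, `converged`, and the underlying `fit`.
#' @export
fit_lmm <- function(fixed, data, subject = "subject_id", label = NULL) {
  data <- as.data.frame(data)
  vars <- all.vars(fixed)
  if (!all(vars %in% names(data)))
    stop("missing variables: ",
         paste(setdiff(vars, names(data)), collapse = ", "))
  data <- data[complete.cases(data[, vars]), , drop = FALSE]
  random <- as.formula(paste("~ 1 |", subject))
  fit <- tryCatch(
    nlme::lme(fixed, random = random, data = data, method = "REML"),
    error = function(e) e
  )
  mm <- model.matrix(fixed, data = data)
  term_map <- setNames(
    c("(Intercept)", attr(terms(fixed, data = data), "term.labels"))[
      attr(mm, "assign") + 1L],
    colnames(mm))
  if (inherits(fit, "error")) {
    warning("mixed model did not converge (", conditionMessage(fit),
            "); falling back to OLS")
    ols <- lm(fixed, data = data)
    dr <- drop1(ols, test = "F")
    terms_tab <- data.frame(
      term = rownames(dr)[-1],
      F = dr$`F value`[-1], df1 = dr$Df[-1],
      df2 = ols$df.residual, p = dr$`Pr(>F)`[-1],
      stringsAsFactors = FALSE, row.names = NULL
    )
    res <- list(label = label, fit_type = "ols", terms = terms_tab,
                coefficients = coef(ols), vif = lmm_vif(fixed, data),
                converged = FALSE, fit = ols, n_obs = nrow(data),
                term_map = term_map,
                n_subjects = length(unique(data[[subject]])))
    return(structure(res, class = "bc_model"))
  }
  an <- anova(fit, type = "marginal")
  keep <- rownames(an) != "(Intercept)"
  terms_tab <- data.frame(
    term = rownames(an)[keep],
    F = an$`F-value`[keep], df1 = an$numDF[keep], df2 = an$denDF[keep],
    p = an$`p-value`[keep], stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(label = label, fit_type = "lme", terms = terms_tab,
                 coefficients = nlme::fixef(fit),
                 vif = lmm_vif(fixed, data), converged = TRUE, fit = fit,
                 n_obs = nrow(data), term_map = term_map,
                 n_subjects = length(unique(data[[subject]]))),
            class = "bc_model")
}

# VIF of the fixed-effects design (intercept dropped); interaction columns
# are expected to exceed the collinearity flag and are reported as-is.
lmm_vif <- function(fixed, data) {
  X <- model.matrix(fixed, data = data)[, -1, drop = FALSE]
  if (ncol(X) < 2) return(NULL)
  vif_table(X)
}

#' @export
print.bc_model <- function(x, ...) {
  cat("Model", if (!is.null(x$label)) paste0("'", x$label, "'"),
      sprintf("(%s, %d obs / %d subjects)\n", x$fit_type, x$n_obs,
              x$n_subjects))
  tt <- x$terms
  tt$F <- round(tt$F, 3); tt$p <- signif(tt$p, 3)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Extract one term's row from a fitted model
#'
#' @param model A `bc_model`.
#' @param term Term label as it appears in `model$terms$term`.
#' @return One-row data frame (F, df1, df2, p) plus the coefficient
#'   estimate when the term maps to a single column.
#' @export
model_term <- function(model, term) {
  row <- model$terms[model$terms$term == term, , drop = FALSE]
  if (!nrow(row)) stop("term not in model: ", term)
  cols <- names(model$term_map)[model$term_map == term]
  est <- model$coefficients[intersect(cols, names(model$coefficients))]
  row$estimate <- if (length(est) == 1) unname(est) else NA_real_
  row
}

#' Tidy table of fixed-term tests across models
#'
#' @param models Named list of `bc_model` objects.
#' @return Data frame: model, term, F, df1, df2, p.
#' @export
model_table <- function(models) {
  do.call(rbind, lapply(names(models), function(nm) {
    tt <- models[[nm]]$terms
    cbind(data.frame(model = nm, stringsAsFactors = FALSE), tt)
  }))
}
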