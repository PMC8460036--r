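# Nested burden association models.
#
# Covariate sets follow the staged design: M0 adjusts for sequencing center
# and the top ten PCs; M1 adds age and sex; M2 adds the APOE e2/e4 allele
# counts. The Cox models drop age (it is the time axis). The burden enters
# as the residualized score, whose confounders (rare-variant count, PCs)
# were regressed out beforehand; the PCs nonetheless re-enter M0-M2, since
# the staged design lists them there.

#' Covariate set for a nested model
#'
#' @param model `"M0"`, `"M1"` or `"M2"`.
#' @param time_to_event Drop age (used by the Cox models).
#' @param pc_cols PC column names.
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(model = c("M0", "M1", "M2"),
                             time_to_event = FALSE,
                             pc_cols = paste0("PC", 1:10)) {
  model <- match.arg(model)
  covs <- c("center", pc_cols)
  if (model %in% c("M1", "M2")) covs <- c(covs, "age", "sex")
  if (model == "M2") covs <- c(covs, "apoe_e2", "apoe_e4")
  if (time_to_event) covs <- setdiff(covs, "age")
  covs
}

# assemble a model frame; factors with a single observed level are dropped
# (they carry no information and would break the contrasts)
build_design <- function(data, burden_col, covariates) {
  miss <- setdiff(covariates, names(data))
  if (length(miss)) {
    abort_endo(sprintf("missing covariate column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  keep <- vapply(covariates, function(cc) {
    v <- data[[cc]]
    !(is.character(v) || is.factor(v)) || length(unique(na.omit(v))) > 1
  }, logical(1))
  covariates <- covariates[keep]
  rhs <- paste(c("burden", covariates), collapse = " + ")
  df <- data.frame(burden = data[[burden_col]],
                   data[, covariates, drop = FALSE])
  list(df = df, formula_rhs = rhs, covariates = covariates)
}

check_burden_varies <- function(x) {
  if (sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
    abort_endo("burden score has no variation")
  }
}

#' Logistic burden association test
#'
#' Maximum-likelihood logistic regression of case/control status on the
#' residualized burden plus the model's covariates; Wald SE and two-sided p
#' for the burden coefficient. Samples whose status is neither case nor
#' control (e.g. MCI) are excluded. Under (quasi-)separation the Wald p is
#' replaced by a likelihood-ratio p and the result flagged.
#'
#' @param data Tibble with `status`, the burden column, and covariates.
#' @param model `"M0"`, `"M1"` or `"M2"`.
#' @param burden_col Burden column (default `"residual"`).
#' @param covariates Covariate columns; defaults to [model_covariates()].
#' @param phenotype Label recorded in the result.
#' @return One-row association tibble (estimate = log OR).
#' @export
logistic_burden_test <- function(data, model = "M2",
                                 burden_col = "residual",
                                 covariates = NULL,
                                 phenotype = "ad") {
  covariates <- covariates %||% model_covariates(model)
  dat <- data[data$status %in% c("case", "control"), , drop = FALSE]
  des <- build_design(dat, burden_col, covariates)
  des$df$y <- as.integer(dat$status == "case")
  des$df <- des$df[complete.cases(des$df), , drop = FALSE]
  check_burden_varies(des$df$burden)
  fit <- glm(as.formula(paste("y ~", des$formula_rhs)), data = des$df,
             family = binomial())
  est <- coef(fit)["burden"]
  se <- sqrt(vcov(fit)["burden", "burden"])
  p <- wald_p(est, se)
  flagged <- FALSE
  if (!fit$converged || se > 50 || abs(est) > 15) {
    # (quasi-)separation: Wald collapses, fall back on the LRT profile
    rhs0 <- if (length(des$covariates)) {
      paste(des$covariates, collapse = " + ")
    } else "1"
    fit0 <- glm(as.formula(paste("y ~", rhs0)), data = des$df,
                family = binomial())
    p <- stats::anova(fit0, fit, test = "Chisq")[2, "Pr(>Chi)"]
    flagged <- TRUE
  }
  out <- new_assoc_result(model, unname(est), unname(se), p,
                          nrow(des$df), phenotype, "log_or")
  out$flagged <- flagged
  attr(out, "fit") <- fit
  out
}

#' Ordinal (proportional-odds) burden test for Braak stages
#'
#' Proportional-odds logistic regression of the ordered Braak stage (0-VI)
#' on the burden and covariates, Wald p on the asymptotic information.
#'
#' @inheritParams logistic_burden_test
#' @param braak_col Column holding the integer stage 0..6.
#' @return One-row association tibble (estimate = log odds per stage shift).
#' @export
ordinal_burden_test <- function(data, model = "M2",
                                burden_col = "residual",
                                braak_col = "braak",
                                covariates = NULL,
                                phenotype = "braak") {
  covariates <- covariates %||% model_covariates(model)
  dat <- data[!is.na(data[[braak_col]]), , drop = FALSE]
  des <- build_design(dat, burden_col, covariates)
  des$df$y <- factor(dat[[braak_col]], levels = 0:6, ordered = TRUE)
  des$df <- des$df[complete.cases(des$df), , drop = FALSE]
  des$df$y <- droplevels(des$df$y)
  if (nlevels(des$df$y) < 2) abort_endo("fewer than 2 observed stages")
  check_burden_varies(des$df$burden)
  if (nlevels(des$df$y) == 2L) {
    # with two categories the proportional-odds model IS logistic regression
    des$df$y01 <- as.integer(des$df$y == levels(des$df$y)[2])
    fit <- glm(as.formula(paste("y01 ~", des$formula_rhs)), data = des$df,
               family = binomial())
  } else {
    fit <- MASS::polr(as.formula(paste("y ~", des$formula_rhs)),
                      data = des$df, method = "logistic", Hess = TRUE)
  }
  est <- coef(fit)["burden"]
  se <- sqrt(vcov(fit)["burden", "burden"])
  out <- new_assoc_result(model, unname(est), unname(se), wald_p(est, se),
                          nrow(des$df), phenotype, "log_or")
  attr(out, "fit") <- fit
  out
}

#' Cox proportional-hazards burden test
#'
#' Partial-likelihood fit (Efron tie handling) of the time-to-event outcome
#' (age at onset for cases; controls enter censored at age at last
#' observation) on the burden and covariates; age itself is never a
#' covariate.
#'
#' @inheritParams logistic_burden_test
#' @param time_col,event_col Survival time and 0/1 event indicator columns.
#' @return One-row association tibble (estimate = log HR, `ratio` = HR).
#' @export
cox_burden_test <- function(data, model = "M2",
                            burden_col = "residual",
                            time_col = "event_time",
                            event_col = "event_flag",
                            covariates = NULL,
                            phenotype = "aao") {
  covariates <- covariates %||% model_covariates(model, time_to_event = TRUE)
  des <- build_design(data, burden_col, covariates)
  des$df$time <- data[[time_col]]
  des$df$event <- data[[event_col]]
  des$df <- des$df[complete.cases(des$df), , drop = FALSE]
  if (sum(des$df$event) < 1) abort_endo("no events observed")
  check_burden_varies(des$df$burden)
  fit <- survival::coxph(
    as.formula(paste("survival::Surv(time, event) ~", des$formula_rhs)),
    data = des$df, ties = "efron")
  est <- coef(fit)["burden"]
  se <- sqrt(vcov(fit)["burden", "burden"])
  out <- new_assoc_result(model, unname(est), unname(se), wald_p(est, se),
                          fit$n, phenotype, "log_hr")
  attr(out, "fit") <- fit
  out
}
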