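# broom-style tidiers and plotting helpers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the kernel-test null model
#'
#' @param x An `endo_null`.
#' @param ... Unused.
#' @return Coefficient tibble of the underlying covariate GLM.
#' @exportS3Method generics::tidy
tidy.endo_null <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @rdname tidy.endo_null
#' @exportS3Method generics::glance
glance.endo_null <- function(x, ...) {
  tibble::tibble(family = x$family, n = x$n,
                 df_covariates = ncol(x$x),
                 deviance = x$fit$deviance, aic = x$fit$aic)
}

#' Tidy / summarise a study bundle
#'
#' @param x An `endo_study` from [run_study()].
#' @param ... Unused.
#' @return `tidy()`: the meta-analysis table; `glance()`: one-row summary.
#' @exportS3Method generics::tidy
tidy.endo_study <- function(x, ...) x$meta

#' @rdname tidy.endo_study
#' @exportS3Method generics::glance
glance.endo_study <- function(x, ...) {
  tibble::tibble(n_cohorts = length(x$config$cohorts),
                 n_assoc_rows = nrow(x$assoc),
                 n_meta_rows = nrow(x$meta),
                 bonferroni = x$bonferroni,
                 n_significant = sum(x$meta$significant, na.rm = TRUE))
}

#' Forest plot of per-cohort burden associations
#'
#' One panel per phenotype, odds/hazard ratios with 95% confidence
#' intervals per cohort and model.
#'
#' @param assoc Association tibble (rows from the burden tests, e.g.
#'   `endo_study$assoc`).
#' @return A ggplot object.
#' @export
plot_forest <- function(assoc) {
  dat <- dplyr::mutate(
    assoc,
    lo = exp(.data$estimate - 1.96 * .data$se),
    hi = exp(.data$estimate + 1.96 * .data$se),
    label = if ("cohort" %in% names(assoc)) {
      paste(.data$cohort, .data$model)
    } else {
      .data$model
    })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ratio, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~phenotype) +
    ggplot2::labs(x = "odds / hazard ratio per residual-burden unit",
                  y = NULL)
}

#' QQ plot of per-gene kernel-test p-values
#'
#' @param results Kernel-result tibble (e.g. from [per_gene_scan()]).
#' @return A ggplot object.
#' @export
plot_qq <- function(results) {
  p <- sort(results$p[!is.na(results$p)])
  dat <- tibble::tibble(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(p))
  ggplot2::ggplot(dat, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "expected p"),
                  y = expression(-log[10] ~ "observed p"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.endo_study <- function(object, ...) plot_forest(object$assoc)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
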