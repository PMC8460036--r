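# Cross-cohort combination: fixed-effects inverse-variance meta-analysis,
# direction-aware Fisher combination, Bonferroni and BH-FDR helpers.

#' Fixed-effects inverse-variance meta-analysis
#'
#' Weights each study by the inverse squared standard error:
#' `beta = sum(w b) / sum(w)`, `SE = 1 / sqrt(sum(w))`, two-sided p from the
#' normal z statistic.
#'
#' @param inputs Tibble with one row per study: `estimate`, `se`, and
#'   optionally `cohort`.
#' @return One-row tibble: estimate, se, p, method, k. A single input is
#'   passed through with a warning.
#' @export
inverse_variance_meta <- function(inputs) {
  if (any(inputs$se <= 0, na.rm = TRUE) || anyNA(inputs$se)) {
    abort_endo("all standard errors must be positive")
  }
  k <- nrow(inputs)
  if (k == 1L) {
    warn("single study: inverse-variance meta is a passthrough")
    return(tibble::tibble(estimate = inputs$estimate, se = inputs$se,
                          p = wald_p(inputs$estimate, inputs$se),
                          method = "inverse_variance", k = 1L))
  }
  w <- 1 / inputs$se^2
  est <- sum(w * inputs$estimate) / sum(w)
  se <- 1 / sqrt(sum(w))
  tibble::tibble(estimate = est, se = se, p = wald_p(est, se),
                 method = "inverse_variance", k = k)
}

#' Direction-aware Fisher combination of p-values
#'
#' Each two-sided p is converted to a one-sided p in the consensus
#' direction (that of the first, discovery, study unless given): p/2 when
#' the study's direction agrees, 1 - p/2 when it disagrees. Fisher's
#' statistic `-2 sum log p_one` is referred to the chi-square with 2k df.
#' The one-sided combined p is reported as-is by default (the convention of
#' the published meta columns); `two_sided = TRUE` doubles it, capped at 1.
#'
#' @param inputs Tibble with `p` (two-sided) and `direction` (+1/-1).
#' @param consensus Consensus direction; default the first study's.
#' @param two_sided Double the combined one-sided p.
#' @return One-row tibble: p, statistic, df, method, k.
#' @export
directional_fisher <- function(inputs, consensus = NULL, two_sided = FALSE) {
  if (any(is.na(inputs$p)) || any(inputs$p <= 0 | inputs$p > 1)) {
    abort_endo("p-values must lie in (0, 1]")
  }
  consensus <- consensus %||% inputs$direction[1]
  p_one <- ifelse(inputs$direction == consensus,
                  inputs$p / 2, 1 - inputs$p / 2)
  x2 <- -2 * sum(log(p_one))
  k <- nrow(inputs)
  p <- pchisq(x2, df = 2 * k, lower.tail = FALSE)
  if (two_sided) p <- min(2 * p, 1)
  tibble::tibble(p = p, statistic = x2, df = 2L * k,
                 method = "directional_fisher", k = k)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise alpha.
#' @param m Number of tests.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 8)  # 0.00625, the gene-set family threshold
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) abort_endo("`m` must be at least 1")
  alpha / m
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values (monotone in the p rank, capped at 1).
#'
#' @param pvals Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  p.adjust(pvals, method = "BH")
}

#' Pick the best nested model by smallest p
#'
#' Among the M0/M1/M2 results for one gene-set and phenotype, returns the
#' row with the smallest p; ties break toward the more-adjusted model.
#'
#' @param results Association tibble with `model` and `p` columns.
#' @return The selected row.
#' @export
select_best_model <- function(results) {
  ord <- order(results$p, -match(results$model, c("M0", "M1", "M2")))
  results[ord[1], , drop = FALSE]
}
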