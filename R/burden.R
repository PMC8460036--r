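# Per-individual burden scores and covariate residualization.

#' Per-individual gene-set burden score
#'
#' The weighted fraction of alternative minor alleles each individual
#' carries across the selected variants:
#' `raw_i = sum_j w_j d_ij / (2 * sum_j w_j)`, where both sums run over the
#' variants non-missing for individual i. Restricting the denominator to
#' observed genotypes keeps scores comparable across samples with different
#' missingness. With uniform weights the score lies in \[0, 1\].
#'
#' @param dosage Samples x variants dosage matrix.
#' @param selected Selection tibble from [select_variants()] (needs
#'   `variant_id` and `weight`), or a character vector of variant ids.
#' @return Tibble with `sample_id`, `raw`, `n_observed`; samples missing at
#'   every selected variant get `NA` and `flagged = TRUE`.
#' @export
burden_score <- function(dosage, selected) {
  if (is.character(selected)) {
    selected <- tibble::tibble(variant_id = selected, weight = 1)
  }
  if (nrow(selected) == 0L) abort_endo("no selected variants")
  ids <- selected$variant_id
  if (!all(ids %in% colnames(dosage))) {
    abort_endo("selected variants absent from the genotype matrix")
  }
  g <- dosage[, ids, drop = FALSE]
  w <- selected$weight
  obs <- !is.na(g)
  num <- as.vector((ifelse(obs, g, 0)) %*% w)
  den <- 2 * as.vector(obs %*% w)
  raw <- ifelse(den > 0, num / den, NA_real_)
  tibble::tibble(sample_id = rownames(dosage), raw = raw,
                 n_observed = as.integer(rowSums(obs)),
                 flagged = den == 0)
}

#' Residualize burden scores on confounders
#'
#' Ordinary-least-squares residuals of the raw burden on an intercept, the
#' genome-wide rare-variant count, and the top principal components. The
#' residual has zero mean and zero sample correlation with every covariate.
#' Collinear covariate columns are dropped with a warning.
#'
#' @param scores Tibble from [burden_score()] (or with `sample_id`, `raw`).
#' @param covariates Tibble with `sample_id`, `n_rare_total`, and PC columns
#'   (`PC1`...), e.g. a join of the phenotype table and [compute_pcs()].
#' @param pc_cols PC column names (default `PC1..PC10`).
#' @param standardize Scale the residuals to unit variance (default TRUE).
#'   The raw fraction-of-minor-alleles has a very small spread, so the
#'   unit-variance residual keeps the association models well conditioned
#'   and makes effects read as "per SD of residual burden"; zero mean and
#'   zero covariate correlation are unaffected.
#' @return `scores` with a `residual` column appended.
#' @export
residualize <- function(scores, covariates, pc_cols = paste0("PC", 1:10),
                        standardize = TRUE) {
  covariates <- covariates[, unique(c("sample_id", "n_rare_total", pc_cols))]
  dat <- dplyr::inner_join(scores, covariates, by = "sample_id")
  dat <- dat[!is.na(dat$raw), , drop = FALSE]
  x <- as.matrix(cbind(1, dat[, c("n_rare_total", pc_cols)]))
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    warn(sprintf("dropping collinear covariate column(s): %s",
                 paste(dropped, collapse = ", ")))
    x <- x[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }
  res <- lm.fit(x, dat$raw)$residuals
  if (standardize && sd(res) > 0) res <- res / sd(res)
  out <- tibble::tibble(sample_id = dat$sample_id, residual = res)
  dplyr::left_join(scores, out, by = "sample_id")
}
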