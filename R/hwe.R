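# Exact Hardy-Weinberg equilibrium test on genotype counts.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on observed genotype counts: conditional on the
#' allele counts, the p-value sums the probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count. Computation is on the log scale for stability.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @return Exact two-sided p-value in (0, 1].
#' @examples
#' hwe_exact_test(100, 0, 0)   # monomorphic: p = 1
#' hwe_exact_test(57, 14, 50)  # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort_endo("genotype counts must be non-negative integers")
  }
  if (sum(counts) == 0) abort_endo("all genotype counts are zero")
  n <- sum(counts)
  n_a <- 2 * n_hom_alt + n_het   # alt allele count
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)

  # possible heterozygote counts share the parity of the minor allele count
  h_obs <- n_het
  h_all <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het = h | n, n_minor) up to a constant:
  #   log(n!) - log(h!) - log(((n_minor-h)/2)!) - log(((n_maj-h)/2)!) + h log 2
  n_major <- 2 * n - n_minor
  logp <- h_all * log(2) - lgamma(h_all + 1) -
    lgamma((n_minor - h_all) / 2 + 1) - lgamma((n_major - h_all) / 2 + 1)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  p_obs <- prob[h_all == h_obs]
  min(sum(prob[prob <= p_obs * (1 + 1e-12)]), 1)
}

#' Control-only HWE filter for rare variants
#'
#' Computes the exact HWE p-value per variant on unaffected (control)
#' samples only, and removes rare variants with p strictly below the cutoff.
#' Non-rare variants are untouched by this filter; the boundary p == cutoff
#' is retained.
#'
#' @param dosage Samples x variants dosage matrix (post GQ-mask).
#' @param samples Phenotype tibble with `sample_id` and `status`.
#' @param cutoff HWE p-value cutoff (default 0.001).
#' @param maf_threshold A variant counts as rare when its control-sample
#'   minor-allele frequency is below this threshold (default 0.01); ignored
#'   when `rare_mask` is given.
#' @param rare_mask Optional logical vector (or variant-id vector) marking
#'   the variants the rarity rule has already classified as rare, e.g. from
#'   [is_rare()].
#' @return List with `keep` (variant ids), `p` (per-variant control HWE p,
#'   NA for variants the filter does not apply to), and `report`.
#' @export
hwe_filter <- function(dosage, samples, cutoff = 0.001, maf_threshold = 0.01,
                       rare_mask = NULL) {
  ctrl_ids <- samples$sample_id[samples$status == "control"]
  ctrl_ids <- intersect(ctrl_ids, rownames(dosage))
  if (!length(ctrl_ids)) abort_endo("no control samples identifiable")
  g <- dosage[ctrl_ids, , drop = FALSE]

  n0 <- colSums(g == 0, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  n2 <- colSums(g == 2, na.rm = TRUE)
  nn <- n0 + n1 + n2
  af <- (2 * n2 + n1) / (2 * nn)
  maf <- pmin(af, 1 - af)
  if (is.null(rare_mask)) {
    rare <- !is.na(maf) & maf < maf_threshold & maf > 0
  } else if (is.character(rare_mask)) {
    rare <- colnames(g) %in% rare_mask & !is.na(maf) & maf > 0
  } else {
    rare <- rare_mask & !is.na(maf) & maf > 0
  }

  p <- rep(NA_real_, ncol(g))
  idx <- which(rare & nn > 0)
  p[idx] <- vapply(idx, function(j) hwe_exact_test(n0[j], n1[j], n2[j]),
                   numeric(1))
  drop <- !is.na(p) & p < cutoff
  list(keep = colnames(g)[!drop],
       p = setNames(p, colnames(g)),
       report = qc_step("hwe_controls", "variants", ncol(g), sum(drop),
                        sprintf("rare (MAF<%g) control-only exact HWE p<%g",
                                maf_threshold, cutoff)))
}
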