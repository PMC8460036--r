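# Genotype principal components on frequency-standardized common variants.

#' Compute genotype principal components
#'
#' Centers each common variant at twice its allele frequency, standardizes
#' by the binomial SD sqrt(2 p (1-p)), mean-imputes missing entries (zero
#' after centering), optionally thins variants to one per window (the
#' synthetic data carry no linkage disequilibrium, so thinning stands in for
#' LD pruning), and returns the top-k left singular vectors, which are
#' orthonormal over samples.
#'
#' @param dosage Samples x variants dosage matrix of common variants.
#' @param k Number of components (default 10); silently reduced to the
#'   matrix rank with a warning when larger.
#' @param maf_min Minimum MAF for inclusion (default 0.05).
#' @param thin_window Keep at most one variant per this many base pairs per
#'   chromosome when `positions` is given; `NULL` disables thinning.
#' @param positions Optional tibble with variant_id, chrom, pos for thinning.
#' @return Tibble with `sample_id` and `PC1..PCk`.
#' @export
compute_pcs <- function(dosage, k = 10L, maf_min = 0.05,
                        thin_window = NULL, positions = NULL) {
  assert_dosage(dosage)
  af <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  use <- !is.na(maf) & maf >= maf_min & maf > 0
  if (!is.null(thin_window) && !is.null(positions)) {
    pos <- positions[match(colnames(dosage), positions$variant_id), ]
    bin <- paste(pos$chrom, pos$pos %/% thin_window)
    first <- !duplicated(bin)
    use <- use & first
  }
  g <- dosage[, use, drop = FALSE]
  p <- af[use]
  x <- sweep(g, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0    # mean imputation after centering

  sv <- svd(x)
  rank <- sum(sv$d > max(dim(x)) * max(sv$d) * 1e-12)
  if (k > rank) {
    warn(sprintf("requested %d PCs but rank is %d; returning %d", k, rank,
                 rank))
    k <- rank
  }
  pcs <- sv$u[, seq_len(k), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(dosage)),
                   tibble::as_tibble(pcs))
}
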