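# Method-of-moments IBD relatedness (PLINK-style PI_HAT) and pruning.

#' Estimate pairwise relatedness from common variants
#'
#' Method-of-moments identity-by-descent estimation from identity-by-state
#' counts and allele frequencies, on common variants only. For each pair the
#' IBS=0/1/2 counts over mutually non-missing variants are compared with
#' their expectations under IBD=0/1/2, giving P(IBD=k) and the summary
#' pi-hat = P(IBD=1)/2 + P(IBD=2), clamped to \[0, 1\].
#'
#' @param dosage Samples x variants dosage matrix restricted to common
#'   variants (internal MAF >= `maf_min`); columns outside that range are
#'   dropped with a note in the result.
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @return List with `pairs` (tibble: id1, id2, ibs0/1/2, pi_hat) and
#'   `warnings` (character; e.g. fewer than 100 usable variants).
#' @export
estimate_relatedness <- function(dosage, maf_min = 0.05) {
  assert_dosage(dosage)
  af <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  use <- !is.na(maf) & maf >= maf_min
  warnings <- character(0)
  if (sum(use) < 100) {
    warnings <- sprintf("only %d usable common variants (<100)", sum(use))
  }
  g <- dosage[, use, drop = FALSE]

  # expected IBS-class probabilities given IBD state, with the standard
  # finite-sample correction: allele frequencies are estimated from the
  # sample itself, so expectations use falling factorials of the observed
  # allele counts rather than plug-in powers of p
  xa <- colSums(g, na.rm = TRUE)                  # alt allele count
  tt <- 2 * colSums(!is.na(g))                    # total allele count
  ya <- tt - xa
  ff <- function(n, k) {
    out <- rep(1, length(n))
    for (i in seq_len(k)) out <- out * (n - i + 1)
    out
  }
  d4 <- ff(tt, 4); d3 <- ff(tt, 3)
  e0_ibd0 <- sum(2 * ff(xa, 2) * ff(ya, 2) / d4)
  e1_ibd0 <- sum(4 * (ff(xa, 3) * ya + xa * ff(ya, 3)) / d4)
  e1_ibd1 <- sum(2 * (ff(xa, 2) * ya + xa * ff(ya, 2)) / d3)
  m_tot <- ncol(g)

  i0 <- (!is.na(g)) & g == 0
  i1 <- (!is.na(g)) & g == 1
  i2 <- (!is.na(g)) & g == 2
  obs <- (!is.na(g)) * 1
  n_obs <- tcrossprod(obs)
  ibs2 <- tcrossprod(i0) + tcrossprod(i1) + tcrossprod(i2)
  ibs0 <- tcrossprod(i0, i2) + tcrossprod(i2, i0)
  ibs1 <- n_obs - ibs2 - ibs0

  ids <- rownames(g)
  n <- length(ids)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  frac <- n_obs[pair_idx] / m_tot   # scale expectations to observed variants
  p0 <- (ibs0[pair_idx] / frac) / e0_ibd0
  p1 <- (ibs1[pair_idx] / frac - p0 * e1_ibd0) / e1_ibd1
  p0 <- pmin(pmax(p0, 0), 1)
  p1 <- pmin(pmax(p1, 0), 1)
  p2 <- pmin(pmax(1 - p0 - p1, 0), 1)
  pi_hat <- pmin(pmax(p1 / 2 + p2, 0), 1)

  pairs <- tibble::tibble(
    id1 = ids[pair_idx[, 1]], id2 = ids[pair_idx[, 2]],
    n_variants = as.integer(n_obs[pair_idx]),
    ibs0 = as.integer(ibs0[pair_idx]), ibs1 = as.integer(ibs1[pair_idx]),
    ibs2 = as.integer(ibs2[pair_idx]),
    k0 = p0, k1 = p1, k2 = p2, pi_hat = pi_hat)
  list(pairs = pairs, warnings = warnings)
}

#' Prune related samples
#'
#' Builds a graph over sample pairs whose pi-hat exceeds the second-degree
#' threshold and keeps exactly one sample per connected component: the one
#' with the lowest genotype missing rate, ties broken by sample-id order.
#'
#' @param pairs Pair tibble from [estimate_relatedness()].
#' @param sample_ids All sample ids under consideration.
#' @param threshold Pi-hat above which a pair is considered second-degree or
#'   closer (default 0.185).
#' @param missing_rate Optional named per-sample missing rate used to pick
#'   the representative of each cluster.
#' @return Character vector of retained sample ids.
#' @export
prune_related <- function(pairs, sample_ids, threshold = 0.185,
                          missing_rate = NULL) {
  rel <- pairs[pairs$pi_hat > threshold, , drop = FALSE]
  if (nrow(rel) == 0) return(sample_ids)
  gr <- igraph::graph_from_data_frame(rel[, c("id1", "id2")],
                                      directed = FALSE,
                                      vertices = unique(c(rel$id1, rel$id2)))
  comp <- igraph::components(gr)$membership
  drop <- unlist(lapply(split(names(comp), comp), function(members) {
    mr <- if (is.null(missing_rate)) setNames(rep(0, length(members)), members)
          else missing_rate[members]
    keep_one <- members[order(mr, members)][1]
    setdiff(members, keep_one)
  }), use.names = FALSE)
  setdiff(sample_ids, drop)
}
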