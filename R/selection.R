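# Dual-source rare-variant rule, deleteriousness classifier, gene sets.

#' Selection configuration
#'
#' @param maf_threshold Rarity threshold, 0.001 or 0.01 in the study design
#'   (any positive value accepted).
#' @param use_cadd Additionally require scaled CADD > `cadd_cutoff`.
#' @param cadd_cutoff Scaled-CADD cutoff (default 15, strict `>`).
#' @param weight_scheme `"uniform"` (weight 1) or `"pli"` (gene pLI score).
#' @param pli Optional tibble with `gene_id`, `pli` for the pli scheme.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(maf_threshold = 0.01, use_cadd = FALSE,
                             cadd_cutoff = 15, weight_scheme = c("uniform",
                                                                 "pli"),
                             pli = NULL) {
  if (!is.numeric(maf_threshold) || maf_threshold <= 0) {
    abort_endo("`maf_threshold` must be positive")
  }
  weight_scheme <- match.arg(weight_scheme)
  if (weight_scheme == "pli" && is.null(pli)) {
    abort_endo("pli weight scheme needs a `pli` table")
  }
  structure(list(maf_threshold = maf_threshold, use_cadd = use_cadd,
                 cadd_cutoff = cadd_cutoff, weight_scheme = weight_scheme,
                 pli = pli),
            class = "selection_config")
}

#' Internal minor-allele frequency per variant
#'
#' Alt-allele frequency over non-missing genotypes of the retained samples,
#' folded to the minor allele. Monomorphic variants get 0; variants missing
#' in every sample get `NA` and are flagged.
#'
#' @param dosage Samples x variants dosage matrix.
#' @param samples Optional sample ids to restrict to (QC-retained set).
#' @return Tibble with `variant_id`, `af_alt`, `af_internal` (folded),
#'   `all_missing`.
#' @export
compute_internal_af <- function(dosage, samples = NULL) {
  g <- if (is.null(samples)) dosage else dosage[samples, , drop = FALSE]
  n_obs <- colSums(!is.na(g))
  af_alt <- colSums(g, na.rm = TRUE) / (2 * n_obs)
  af_alt[n_obs == 0] <- NA_real_
  af_alt <- unname(af_alt)
  tibble::tibble(
    variant_id = colnames(g),
    af_alt = af_alt,
    af_internal = pmin(af_alt, 1 - af_alt),
    all_missing = unname(n_obs == 0))
}

#' Dual-source rarity rule
#'
#' A variant present in either external reference (1KG EUR, gnomAD NFE) is
#' rare iff every *present* external frequency is strictly below the
#' threshold (when the two sources disagree across the threshold the variant
#' is conservatively not rare). A variant absent from both references falls
#' back to the internal minor-allele frequency. A recorded external
#' frequency of zero counts as present.
#'
#' @param variants Variant table with `af_kg_eur`, `af_gnomad_nfe` and an
#'   `af_internal` column (see [compute_internal_af()]).
#' @param cfg A [selection_config()] (or a bare threshold).
#' @return Logical vector along the rows of `variants`.
#' @export
is_rare <- function(variants, cfg) {
  thr <- if (inherits(cfg, "selection_config")) cfg$maf_threshold else cfg
  kg <- variants$af_kg_eur
  gn <- variants$af_gnomad_nfe
  has_ext <- !is.na(kg) | !is.na(gn)
  ext_ok <- (is.na(kg) | kg < thr) & (is.na(gn) | gn < thr)
  internal_ok <- !is.na(variants$af_internal) & variants$af_internal < thr
  ifelse(has_ext, ext_ok, internal_ok)
}

#' Deleteriousness classifier
#'
#' True for protein-truncating / splice-disrupting consequences (stop-gain,
#' stop-loss, frameshift, splice-donor, splice-acceptor) and for missense
#' variants flagged damaging. With `use_cadd`, additionally requires scaled
#' CADD > 15.
#'
#' @param variants Variant table with `consequence`, `polyphen_damaging`,
#'   `cadd_scaled`.
#' @param cfg A [selection_config()].
#' @return Logical vector along the rows of `variants`.
#' @export
is_deleterious <- function(variants, cfg = selection_config()) {
  lof <- variants$consequence %in% DELETERIOUS_CLASSES
  mis <- grepl("^missense", variants$consequence) &
    !is.na(variants$polyphen_damaging) & variants$polyphen_damaging == 1
  out <- lof | mis
  if (isTRUE(cfg$use_cadd)) {
    out <- out & !is.na(variants$cadd_scaled) &
      variants$cadd_scaled > cfg$cadd_cutoff
  }
  out
}

#' Build gene sets from GMT records
#'
#' Deduplicates each term's members, forms the deduplicated union across
#' terms, and reports pairwise overlap counts.
#'
#' @param sets Named list of character gene vectors (e.g. [read_gmt()]).
#' @return List with `sets` (deduplicated), `union` (character vector),
#'   `sizes`, and `overlap` (matrix of pairwise shared-gene counts).
#' @export
build_gene_sets <- function(sets) {
  if (!length(sets)) abort_endo("no gene sets supplied")
  if (any(!vapply(sets, length, 1L))) {
    abort_endo("empty gene-set term")
  }
  sets <- lapply(sets, unique)
  nm <- names(sets)
  overlap <- outer(nm, nm, Vectorize(function(a, b) {
    length(intersect(sets[[a]], sets[[b]]))
  }))
  dimnames(overlap) <- list(nm, nm)
  list(sets = sets, union = unique(unlist(sets, use.names = FALSE)),
       sizes = vapply(sets, length, 1L), overlap = overlap)
}

#' Select rare deleterious variants in a gene set
#'
#' Variants that are rare (dual-source rule), deleterious, and assigned to a
#' member gene. Weights are 1 under the uniform scheme or the gene's pLI
#' under the pli scheme (genes absent from the pLI table are ignored with a
#' warning and weighted 0).
#'
#' @param variants Variant table (with `af_internal`; see
#'   [compute_internal_af()]).
#' @param gene_set Character vector of member gene ids.
#' @param cfg A [selection_config()].
#' @return Tibble with `variant_id`, `gene_id`, `weight`, `maf_source`
#'   (external/internal), plus `n_genes_hit` as an attribute.
#' @export
select_variants <- function(variants, gene_set, cfg = selection_config()) {
  sel <- is_rare(variants, cfg) & is_deleterious(variants, cfg) &
    variants$gene_id %in% gene_set
  out <- variants[sel, c("variant_id", "gene_id"), drop = FALSE]
  out$maf_source <- ifelse(
    (!is.na(variants$af_kg_eur) | !is.na(variants$af_gnomad_nfe))[sel],
    "external", "internal")
  if (cfg$weight_scheme == "pli") {
    w <- cfg$pli$pli[match(out$gene_id, cfg$pli$gene_id)]
    unknown <- setdiff(cfg$pli$gene_id, variants$gene_id)
    if (length(unknown)) {
      warn(sprintf("%d pLI gene ids not in the variant table; ignored",
                   length(unknown)))
    }
    if (anyNA(w)) {
      warn(sprintf("%d selected variants in genes without pLI; weighted 0",
                   sum(is.na(w))))
      w[is.na(w)] <- 0
    }
    out$weight <- w
  } else {
    out$weight <- 1
  }
  out <- tibble::as_tibble(out)
  attr(out, "n_genes_hit") <- length(unique(out$gene_id))
  out
}
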