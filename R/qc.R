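# Sample- and variant-level QC: site filters, GQ masking, missingness,
# control-only HWE, relatedness pruning, genotype PCA. The canonical order
# (applied by run_qc) is: site filter (PASS, biallelic SNV) -> GQ mask ->
# sample missingness -> variant missingness -> HWE. GQ masking precedes the
# missingness filters, so masked entries count as missing there.

qc_step <- function(step, unit, n_in, n_removed, params = "") {
  tibble::tibble(step = step, unit = unit, n_in = as.integer(n_in),
                 n_removed = as.integer(n_removed),
                 n_retained = as.integer(n_in - n_removed),
                 params = params)
}

#' Mask genotypes with low genotype quality
#'
#' Entries with GQ strictly below the threshold are set to missing; a GQ
#' equal to the threshold is kept.
#'
#' @param dosage Samples x variants dosage matrix.
#' @param gq Matching GQ matrix.
#' @param gq_threshold Masking threshold (default 21, i.e. GQ < 21 masked).
#' @return Dosage matrix with low-GQ entries set to `NA`.
#' @export
mask_low_gq <- function(dosage, gq, gq_threshold = 21L) {
  assert_dosage(dosage)
  if (is.null(gq)) abort_endo("no GQ data available for masking")
  if (!identical(dim(dosage), dim(gq))) {
    abort_endo("dosage and GQ matrices must have identical dimensions")
  }
  dosage[gq < gq_threshold] <- NA
  dosage
}

#' Site-level filter: PASS, biallelic SNVs only
#'
#' Removes variants failing the site filter (non-PASS) and multi-allelic
#' sites. Input rows representing split multi-allelic records are rejected
#' rather than silently kept.
#'
#' @param variants Variant table with `filter` and `biallelic` columns.
#' @param dosage Samples x variants dosage matrix.
#' @return List with filtered `variants`, `dosage`, and a `report` tibble.
#' @export
filter_variants_basic <- function(variants, dosage) {
  if (!all(c("filter", "biallelic") %in% names(variants))) {
    abort_endo("variant table must carry `filter` and `biallelic` columns")
  }
  keep <- variants$filter == "PASS" & variants$biallelic
  report <- dplyr::bind_rows(
    qc_step("site_filter", "variants", nrow(variants),
            sum(variants$filter != "PASS"), "FILTER == PASS"),
    qc_step("biallelic", "variants", sum(variants$filter == "PASS"),
            sum(variants$filter == "PASS" & !variants$biallelic),
            "biallelic SNV"))
  list(variants = variants[keep, , drop = FALSE],
       dosage = dosage[, variants$variant_id[keep], drop = FALSE],
       report = report)
}

#' Per-sample missingness filter
#'
#' Samples whose fraction of missing genotypes exceeds the cutoff are
#' removed; a sample exactly at the cutoff is retained.
#'
#' @param dosage Samples x variants dosage matrix.
#' @param cutoff Maximum tolerated missing fraction (default 0.05).
#' @return List with `keep` (sample ids), `missing_rate`, and `report`.
#' @export
sample_missingness_filter <- function(dosage, cutoff = 0.05) {
  rate <- rowMeans(is.na(dosage))
  keep <- rate <= cutoff
  list(keep = rownames(dosage)[keep],
       missing_rate = setNames(rate, rownames(dosage)),
       report = qc_step("sample_missingness", "samples", nrow(dosage),
                        sum(!keep), sprintf("cutoff=%g", cutoff)))
}

#' Per-variant missingness filter
#'
#' @param dosage Samples x variants dosage matrix.
#' @param cutoff Maximum tolerated missing fraction (default 0.02); a
#'   variant exactly at the cutoff is retained.
#' @return List with `keep` (variant ids) and `report`.
#' @export
variant_missingness_filter <- function(dosage, cutoff = 0.02) {
  rate <- colMeans(is.na(dosage))
  keep <- rate <= cutoff
  list(keep = colnames(dosage)[keep],
       report = qc_step("variant_missingness", "variants", ncol(dosage),
                        sum(!keep), sprintf("cutoff=%g", cutoff)))
}

#' Run the full QC chain on a cohort
#'
#' Applies, in order: site filter (PASS, biallelic), GQ masking, sample
#' missingness, variant missingness, and the control-only HWE filter on rare
#' variants. Returns the filtered data plus an ordered QC report; re-running
#' on the retained data is a no-op.
#'
#' @param cohort An `endo_cohort` (or compatible list with `panel`, `dosage`,
#'   `gq`, `samples`).
#' @param gq_threshold,sample_miss,variant_miss,hwe_cutoff Thresholds
#'   (defaults 21, 0.05, 0.02, 0.001).
#' @param maf_threshold Rarity threshold used to decide which variants the
#'   HWE filter applies to (default 0.01).
#' @return List with `dosage`, `variants`, `samples`, and `report`.
#' @export
run_qc <- function(cohort, gq_threshold = 21L, sample_miss = 0.05,
                   variant_miss = 0.02, hwe_cutoff = 0.001,
                   maf_threshold = 0.01) {
  basic <- filter_variants_basic(cohort$panel, cohort$dosage)
  gq <- cohort$gq[, basic$variants$variant_id, drop = FALSE]
  dosage <- mask_low_gq(basic$dosage, gq, gq_threshold)
  report <- dplyr::bind_rows(
    basic$report,
    qc_step("gq_mask", "entries", length(dosage),
            sum(is.na(dosage)) - sum(is.na(basic$dosage)),
            sprintf("GQ<%d set missing", gq_threshold)))

  sm <- sample_missingness_filter(dosage, sample_miss)
  dosage <- dosage[sm$keep, , drop = FALSE]
  vm <- variant_missingness_filter(dosage, variant_miss)
  dosage <- dosage[, vm$keep, drop = FALSE]
  variants <- basic$variants[basic$variants$variant_id %in% vm$keep, ,
                             drop = FALSE]
  samples <- cohort$samples[cohort$samples$sample_id %in% sm$keep, ,
                            drop = FALSE]

  hw <- hwe_filter(dosage, samples, cutoff = hwe_cutoff,
                   maf_threshold = maf_threshold)
  dosage <- dosage[, hw$keep, drop = FALSE]
  variants <- variants[variants$variant_id %in% hw$keep, , drop = FALSE]
  report <- dplyr::bind_rows(report, sm$report, vm$report, hw$report)

  list(dosage = dosage, variants = variants, samples = samples,
       report = report)
}

#' Write a QC report as JSON
#'
#' @param report QC report tibble.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
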