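# Cohort serialization: VCF (GT+GQ), TSV tables, GMT gene sets, MatrixMarket
# single-cell counts. Writing is plain deterministic text so that identical
# config + seed reproduces byte-identical files; reading goes through vcfR /
# readr / Matrix.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                   trim = TRUE)
  }, character(1))
  out
}

# read a TSV strictly; any parse problem is reported with file and line
read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) {
    abort_endo(sprintf("missing file: %s", path),
               class = "endoburden_parse_error")
  }
  out <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort_endo(sprintf("parse error in %s at line %d: expected %s, got %s",
                       path, probs$row[1] + 1L, probs$expected[1],
                       probs$actual[1]),
               class = "endoburden_parse_error")
  }
  out
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene...`.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort_endo(sprintf("missing file: %s", path),
               class = "endoburden_parse_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      abort_endo(sprintf("parse error in %s at line %d: fewer than 3 fields",
                         path, i),
                 class = "endoburden_parse_error")
    }
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character gene vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

write_vcf_text <- function(panel, dosage, gq, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  alt <- ifelse(panel$biallelic, panel$alt,
                paste0(panel$alt, ",",
                       ifelse(panel$alt == "G", "T", "G")))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=VQSRTrancheSNP99.90to100.00,Description=\"VQSR failed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosage)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(panel)), function(j) {
    g <- dosage[, j]
    cells <- paste0(ifelse(is.na(g), "./.", gt_code[as.character(g)]),
                    ":", gq[, j])
    paste(c(panel$chrom[j], panel$pos[j], panel$variant_id[j], panel$ref[j],
            alt[j], ".", panel$filter[j], ".", "GT:GQ", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

read_vcf_geno <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gqm <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  code <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L)
  dosage <- matrix(code[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  fix <- tibble::as_tibble(vcfR::getFIX(vcf))
  names(fix) <- tolower(names(fix))
  list(
    dosage = t(dosage),
    gq = t(matrix(as.integer(gqm), nrow = nrow(gqm), dimnames = dimnames(gqm))),
    sites = tibble::tibble(
      variant_id = fix$id, chrom = fix$chrom, pos = as.integer(fix$pos),
      ref = fix$ref, alt = fix$alt, filter = fix$filter,
      biallelic = !grepl(",", fix$alt, fixed = TRUE))
  )
}

#' Write a synthetic cohort to a directory
#'
#' Emits `cohort.vcf` (VCFv4.2 with GT and GQ), `annotations.tsv`,
#' `phenotypes.tsv`, `genesets.gmt`, `gene_windows.tsv`, `bulk_expr.tsv`,
#' `sc_counts.mtx` + `sc_cells.tsv` + `sc_genes.tsv`, a `families/` subtree
#' (own VCF, phenotypes and `kinship.tsv`), and `truth.json`. All files are
#' plain text and the write is deterministic.
#'
#' @param cohort An `endo_cohort` from [simulate_cohort()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$panel) || nrow(cohort$panel) == 0L) {
    abort_endo("refusing to write an empty cohort")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  write_vcf_text(cohort$panel, cohort$dosage, cohort$gq, p("cohort.vcf"))
  ann <- cohort$panel[, c("variant_id", "chrom", "pos", "ref", "alt",
                          "gene_id", "consequence", "polyphen_damaging",
                          "cadd_scaled", "af_kg_eur", "af_gnomad_nfe")]
  readr::write_tsv(ann, p("annotations.tsv"))
  readr::write_tsv(cohort$samples, p("phenotypes.tsv"))
  write_gmt(cohort$gene_sets, p("genesets.gmt"))
  readr::write_tsv(cohort$gene_windows, p("gene_windows.tsv"))

  if (!is.null(cohort$bulk)) {
    be <- tibble::as_tibble(cohort$bulk$expr, rownames = "gene_id")
    readr::write_tsv(be, p("bulk_expr.tsv"))
  }
  if (!is.null(cohort$sc)) {
    Matrix::writeMM(cohort$sc$counts, p("sc_counts.mtx"))
    readr::write_tsv(cohort$sc$cells, p("sc_cells.tsv"))
    readr::write_tsv(cohort$sc$genes, p("sc_genes.tsv"))
  }
  if (!is.null(cohort$families)) {
    fdir <- p("families")
    dir.create(fdir, showWarnings = FALSE)
    fam <- cohort$families
    write_vcf_text(cohort$panel, fam$dosage, fam$gq,
                   file.path(fdir, "cohort.vcf"))
    readr::write_tsv(fam$samples, file.path(fdir, "phenotypes.tsv"))
    kin <- tibble::as_tibble(fam$kinship, rownames = "sample_id")
    readr::write_tsv(kin, file.path(fdir, "kinship.tsv"))
  }
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return An `endo_cohort`-shaped list; round trips [write_cohort()]
#'   losslessly (up to numeric print precision in the TSV tables).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir) || !file.exists(file.path(dir, "cohort.vcf"))) {
    abort_endo(sprintf("not a cohort directory: %s", dir),
               class = "endoburden_parse_error")
  }
  p <- function(f) file.path(dir, f)
  vc <- read_vcf_geno(p("cohort.vcf"))
  ann <- read_tsv_strict(p("annotations.tsv"), col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    polyphen_damaging = readr::col_integer()))
  panel <- dplyr::left_join(
    ann, vc$sites[, c("variant_id", "filter", "biallelic")], by = "variant_id")
  samples <- read_tsv_strict(p("phenotypes.tsv"), col_types = readr::cols(
    sample_id = readr::col_character(), status = readr::col_character(),
    center = readr::col_character(), family_id = readr::col_character()))

  out <- list(
    panel = panel,
    dosage = vc$dosage[, panel$variant_id, drop = FALSE],
    gq = vc$gq[, panel$variant_id, drop = FALSE],
    samples = samples,
    gene_sets = read_gmt(p("genesets.gmt")),
    gene_windows = read_tsv_strict(p("gene_windows.tsv"),
                                   col_types = readr::cols(
                                     chrom = readr::col_character()))
  )
  if (file.exists(p("bulk_expr.tsv"))) {
    be <- read_tsv_strict(p("bulk_expr.tsv"))
    m <- as.matrix(be[, -1])
    rownames(m) <- be$gene_id
    out$bulk <- list(expr = m, genes = be$gene_id)
  }
  if (file.exists(p("sc_counts.mtx"))) {
    counts <- Matrix::readMM(p("sc_counts.mtx"))
    cells <- read_tsv_strict(p("sc_cells.tsv"))
    genes <- read_tsv_strict(p("sc_genes.tsv"))
    dimnames(counts) <- list(cells$cell_id, genes$gene_id)
    out$sc <- list(counts = methods::as(counts, "CsparseMatrix"),
                   cells = cells, genes = genes)
  }
  fdir <- p("families")
  if (dir.exists(fdir)) {
    fvc <- read_vcf_geno(file.path(fdir, "cohort.vcf"))
    kin <- read_tsv_strict(file.path(fdir, "kinship.tsv"))
    km <- as.matrix(kin[, -1])
    rownames(km) <- kin$sample_id
    out$families <- list(
      dosage = fvc$dosage, gq = fvc$gq, kinship = km,
      samples = read_tsv_strict(file.path(fdir, "phenotypes.tsv"),
                                col_types = readr::cols(
                                  sample_id = readr::col_character(),
                                  family_id = readr::col_character(),
                                  center = readr::col_character(),
                                  status = readr::col_character())))
  }
  if (file.exists(p("truth.json"))) {
    out$truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  }
  structure(out, class = "endo_cohort")
}
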