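# Bulk-expression functional analyses (rare-variant eGene test, case/control
# contrasts, Braak correlation) and single-cell preprocessing + per-cell-type
# differential expression.

#' Rare variants in a gene's cis window
#'
#' The cis window is the union of the gene body and TSS +/- 20 kb, with
#' 1-based closed intervals and endpoints included (a variant exactly at
#' TSS + 20,000 is in; at TSS + 20,001 it is out unless inside the body).
#'
#' @param variants Variant table with `chrom`, `pos`.
#' @param window One row of a gene-window table (`chrom`, `body_start`,
#'   `body_end`, `tss`).
#' @param flank Flank size around the TSS (default 20000).
#' @return Logical vector along the rows of `variants`.
#' @export
in_cis_window <- function(variants, window, flank = 20000L) {
  variants$chrom == window$chrom &
    ((variants$pos >= window$body_start & variants$pos <= window$body_end) |
       (variants$pos >= window$tss - flank & variants$pos <= window$tss + flank))
}

#' Rare-variant eGene test for one gene
#'
#' Continuous-trait kernel test of a gene's expression on the aggregated
#' rare variants in its cis window (delegates to [kernel_test()] with the
#' expression row as outcome).
#'
#' @param expr Named numeric vector of expression values (names = sample
#'   ids) for one gene.
#' @param g Dosage matrix of the rare variants in the gene's cis window.
#' @param covariates Tibble with `sample_id` and covariate columns.
#' @param covariate_cols Covariate column names.
#' @param gene_id Label for the result.
#' @return One-row kernel-result tibble (p `NA` with a reason when no
#'   polymorphic variant lies in the window).
#' @export
egene_test <- function(expr, g, covariates,
                       covariate_cols = c("age", "sex", "center", "apoe_e2",
                                          "apoe_e4", paste0("PC", 1:10)),
                       gene_id = NA_character_) {
  dat <- covariates
  dat$expr <- as.numeric(expr[dat$sample_id])
  null <- fit_null(dat, "expr", intersect(covariate_cols, names(dat)),
                   family = "continuous")
  if (is.null(g) || ncol(as.matrix(g)) == 0) {
    return(tibble::tibble(gene_id = gene_id, Q = NA_real_, p = NA_real_,
                          rho = 0, n_variants = 0L, n = null$n,
                          method = "kernel", skipped = "no variants in window"))
  }
  kernel_test(null, g, rho = 0, gene_id = gene_id)
}

#' eGene scan over all genes with FDR control
#'
#' Runs [egene_test()] for every gene in the window table, then attaches
#' BH q-values at the requested FDR.
#'
#' @param bulk Gene x sample expression matrix.
#' @param dosage Samples x variants dosage matrix.
#' @param variants Variant table with `chrom`, `pos`, `variant_id` and an
#'   `is_rare` logical column (or use `rare_ids`).
#' @param windows Gene-window tibble ([sim_gene_windows()] shape).
#' @param covariates Tibble with `sample_id` plus covariates.
#' @param rare_ids Variant ids to consider (already rarity-filtered).
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @inheritParams egene_test
#' @return Tibble of per-gene results with `q` and `significant`.
#' @export
egene_scan <- function(bulk, dosage, variants, windows, covariates,
                       rare_ids, fdr = 0.05,
                       covariate_cols = c("age", "sex", "center", "apoe_e2",
                                          "apoe_e4", paste0("PC", 1:10))) {
  genes <- intersect(rownames(bulk), windows$gene_id)
  rows <- purrr::map(genes, function(gid) {
    w <- windows[windows$gene_id == gid, ]
    vid <- variants$variant_id[in_cis_window(variants, w)]
    vid <- intersect(vid, rare_ids)
    g <- if (length(vid)) dosage[, vid, drop = FALSE] else NULL
    egene_test(bulk[gid, ], g, covariates, covariate_cols, gene_id = gid)
  })
  out <- dplyr::bind_rows(rows)
  tested <- !is.na(out$p)
  out$q <- NA_real_
  out$q[tested] <- bh_fdr(out$p[tested])
  out$significant <- !is.na(out$q) & out$q < fdr
  out
}

#' Two-sample differential-expression t-test
#'
#' Welch (unequal-variance) two-sided t-test of one gene's expression
#' between cases and controls; pooled variance behind a flag.
#'
#' @param expr Numeric expression values.
#' @param status Character/logical case indicator aligned with `expr`
#'   (`"case"` / `"control"` or TRUE/FALSE).
#' @param pooled Use the pooled-variance (classic Student) form.
#' @return One-row tibble: t, p, direction (+1 when cases higher), n_case,
#'   n_control; constant groups give p `NA` with a `flagged` note.
#' @export
de_ttest <- function(expr, status, pooled = FALSE) {
  is_case <- if (is.logical(status)) status else status == "case"
  keep <- !is.na(expr) & !is.na(is_case) &
    (is.logical(status) | status %in% c("case", "control"))
  x <- expr[keep & is_case]
  y <- expr[keep & !is_case]
  if (length(x) < 2 || length(y) < 2) {
    abort_endo("need at least 2 samples per group")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    return(tibble::tibble(t = NA_real_, p = NA_real_,
                          direction = sign(mean(x) - mean(y)),
                          n_case = length(x), n_control = length(y),
                          flagged = "zero variance in both groups"))
  }
  tt <- t.test(x, y, var.equal = pooled)
  tibble::tibble(t = unname(tt$statistic), p = tt$p.value,
                 direction = sign(mean(x) - mean(y)),
                 n_case = length(x), n_control = length(y),
                 flagged = NA_character_)
}

#' Pearson correlation of expression with Braak stage
#'
#' @param expr Numeric expression values.
#' @param braak Integer stages 0..6 aligned with `expr` (NA dropped).
#' @return One-row tibble: r, p (t transform), n.
#' @export
braak_correlation <- function(expr, braak) {
  keep <- !is.na(expr) & !is.na(braak)
  ct <- cor.test(expr[keep], braak[keep], method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Single-cell quality filter
#'
#' Keeps cells with between `min_genes` and `max_genes` detected genes
#' (inclusive) and mitochondrial count fraction not exceeding `max_mito`
#' (cells strictly over the threshold are removed).
#'
#' @param counts Cell x gene count matrix (sparse or dense).
#' @param mito_genes Character vector (or logical mask) of mitochondrial
#'   genes.
#' @param min_genes,max_genes Detected-gene bounds (defaults 200 and 2500).
#' @param max_mito Mitochondrial fraction bound (default 0.05).
#' @return Tibble per cell: cell_id, n_genes, mito_frac, keep.
#' @export
sc_filter_cells <- function(counts, mito_genes, min_genes = 200L,
                            max_genes = 2500L, max_mito = 0.05) {
  n_genes <- Matrix::rowSums(counts > 0)
  if (is.logical(mito_genes)) mito_genes <- colnames(counts)[mito_genes]
  mito_idx <- colnames(counts) %in% mito_genes
  total <- Matrix::rowSums(counts)
  mito_frac <- Matrix::rowSums(counts[, mito_idx, drop = FALSE]) /
    pmax(total, 1)
  tibble::tibble(
    cell_id = rownames(counts),
    n_genes = as.integer(n_genes),
    mito_frac = as.numeric(mito_frac),
    keep = n_genes >= min_genes & n_genes <= max_genes &
      mito_frac <= max_mito)
}

#' Global-scaling log-normalization
#'
#' `ln(1 + count / cell_total * scale)` per cell, the standard
#' log-normalization of single-cell counts (natural log, scale 10,000).
#'
#' @param counts Cell x gene count matrix.
#' @param scale Scale factor (default 10000).
#' @return Matrix of normalized values, same dimensions.
#' @export
sc_lognormalize <- function(counts, scale = 10000) {
  total <- Matrix::rowSums(counts)
  total[total == 0] <- 1
  norm <- counts / total * scale
  if (inherits(norm, "sparseMatrix")) {
    norm@x <- log1p(norm@x)
    norm
  } else {
    log1p(norm)
  }
}

#' Per-cell-type differential expression between cases and controls
#'
#' Applies [de_ttest()] per cell type (or subcluster) on per-cell
#' normalized values. Directions are reported per type, so opposite-sign
#' effects across types are representable. Per-cell tests mirror the
#' single-cell DE procedure of the study design; per-sample pseudobulk
#' (mean per sample, then test over samples) is available since per-cell
#' tests are anti-conservative under within-sample correlation.
#'
#' @param norm Cell x gene normalized matrix ([sc_lognormalize()]).
#' @param cells Tibble with `cell_id`, `sample_id`, `celltype`,
#'   `subcluster`.
#' @param status Named status vector (`"case"`/`"control"`) by sample id.
#' @param genes Genes to test (default all columns).
#' @param level `"major"` (cell types) or `"subcluster"`.
#' @param pseudobulk Aggregate to per-sample means before testing.
#' @return Tibble: gene_id, group, t, p, direction, n per group; groups
#'   lacking two samples per status are skipped with a reason.
#' @export
celltype_de <- function(norm, cells, status, genes = colnames(norm),
                        level = c("major", "subcluster"),
                        pseudobulk = FALSE) {
  level <- match.arg(level)
  group_col <- if (level == "major") "celltype" else "subcluster"
  cells <- cells[match(rownames(norm), cells$cell_id), , drop = FALSE]
  cells$status <- unname(status[cells$sample_id])
  groups <- split(seq_len(nrow(cells)), cells[[group_col]])
  rows <- purrr::imap(groups, function(idx, grp) {
    sub <- cells[idx, , drop = FALSE]
    n_case_samp <- length(unique(sub$sample_id[sub$status == "case"]))
    n_ctrl_samp <- length(unique(sub$sample_id[sub$status == "control"]))
    if (n_case_samp < 2 || n_ctrl_samp < 2) {
      return(tibble::tibble(gene_id = genes, group = grp, t = NA_real_,
                            p = NA_real_, direction = NA_real_,
                            skipped = "fewer than 2 samples per status"))
    }
    purrr::map(genes, function(gid) {
      if (pseudobulk) {
        agg <- tapply(as.numeric(norm[idx, gid]), sub$sample_id, mean)
        st <- unname(status[names(agg)])
        res <- de_ttest(as.numeric(agg), st)
      } else {
        res <- de_ttest(as.numeric(norm[idx, gid]), sub$status)
      }
      tibble::tibble(gene_id = gid, group = grp, t = res$t, p = res$p,
                     direction = res$direction, skipped = NA_character_)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
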