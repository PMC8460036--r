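# Bulk and single-cell expression generator with known eGene / DE truth.

#' Simulate bulk and single-cell expression
#'
#' Bulk expression is Gaussian around a per-gene baseline with (a) a cis
#' rare-variant eGene effect proportional to the standardized carrier burden
#' of rare variants in the gene's cis window for designated eGenes and (b) a
#' case-associated shift for designated differential genes. Single-cell
#' counts are negative binomial with per-cell size factors, six labelled cell
#' types, per-type case shifts on designated marker genes, and per-cell
#' mitochondrial fractions and detected-gene counts that span the quality
#' thresholds used downstream.
#'
#' @param geno Genotype list (or dosage matrix) for the cohort samples.
#' @param panel Variant table.
#' @param samples Phenotype tibble from [simulate_phenotypes()].
#' @param cfg A [sim_config()].
#' @return List with `bulk` (list: `expr` gene x sample matrix, `genes`),
#'   `sc` (list: `counts` sparse cell x gene matrix, `cells`, `genes`), and
#'   `truth` (eGene/DE designations).
#' @export
simulate_expression <- function(geno, panel, samples, cfg) {
  dosage <- if (is.list(geno)) geno$dosage else geno
  ex <- cfg$expression
  windows <- sim_gene_windows(cfg)

  # ---- bulk ----
  n_expr <- min(ex$n_expr_genes, cfg$n_genes)
  expr_genes <- windows$gene_id[seq_len(n_expr)]
  n <- nrow(dosage)
  rare <- panel$af_true < 0.01

  carrier_z <- vapply(expr_genes, function(g) {
    w <- windows[windows$gene_id == g, ]
    in_win <- panel$chrom == w$chrom &
      ((panel$pos >= w$body_start & panel$pos <= w$body_end) |
         (panel$pos >= w$tss - 20000L & panel$pos <= w$tss + 20000L))
    vid <- panel$variant_id[in_win & rare]
    if (!length(vid)) return(rep(0, n))
    cb <- rowSums(dosage[, vid, drop = FALSE], na.rm = TRUE)
    s <- sd(cb)
    if (s > 0) (cb - mean(cb)) / s else cb * 0
  }, numeric(n))

  has_signal <- apply(carrier_z, 2, sd) > 0
  n_egene <- min(ceiling(ex$frac_egene * n_expr), sum(has_signal))
  egenes <- expr_genes[has_signal][seq_len(n_egene)]
  de_genes <- utils::tail(expr_genes, max(1L, ceiling(0.2 * n_expr)))

  is_case <- as.integer(samples$status == "case")
  expr <- matrix(rnorm(n_expr * n, mean = 10), nrow = n_expr,
                 dimnames = list(expr_genes, samples$sample_id))
  expr <- expr + t(carrier_z) * ex$egene_effect *
    (expr_genes %in% egenes)
  expr <- expr + outer(as.numeric(expr_genes %in% de_genes),
                       as.numeric(is_case)) * ex$bulk_case_shift
  bulk <- list(expr = expr, genes = expr_genes)

  # ---- single cell ----
  cc <- samples$sample_id[samples$status %in% c("case", "control")]
  n_sc <- min(ex$n_sc_samples, length(cc))
  cases <- samples$sample_id[samples$status == "case"]
  ctrls <- samples$sample_id[samples$status == "control"]
  half <- n_sc %/% 2L
  sc_samples <- c(head(cases, half), head(ctrls, n_sc - half))

  ng <- ex$n_sc_genes
  n_mito <- min(50L, max(1L, round(ng / 60)))
  gene_ids <- c(sprintf("MT-%02d", seq_len(n_mito)),
                sprintf("SG%04d", seq_len(ng - n_mito)))
  mito <- seq_len(n_mito)
  marker <- n_mito + seq_len(min(5L, ng - n_mito))  # per-type case-shift genes

  m_g <- rexp(ng, rate = 2)           # gene-level mean expression
  m_g[mito] <- m_g[mito] * 0          # mito means set per cell below
  shift <- ex$case_shift_per_celltype

  cells <- list(); counts <- list()
  type_probs <- c(Ex = 0.35, In = 0.15, Ast = 0.15, Oli = 0.20,
                  Opc = 0.07, Mic = 0.08)
  for (s in sc_samples) {
    ncell <- ex$n_cells_per_sample
    ctype <- sample(CELL_TYPES, ncell, replace = TRUE, prob = type_probs)
    sub <- paste0(ctype, sample(0:3, ncell, replace = TRUE))
    size_f <- exp(rnorm(ncell, 0, 0.6))
    f_mito <- rbeta(ncell, ex$mito_shape1, ex$mito_shape2)
    case_here <- as.integer(s %in% cases)
    mu <- outer(size_f, m_g)
    if (case_here == 1L && length(marker)) {
      for (ty in CELL_TYPES) {
        rows <- ctype == ty
        if (any(rows) && shift[[ty]] != 0) {
          mu[rows, marker] <- mu[rows, marker] * exp(shift[[ty]])
        }
      }
    }
    tot_nonmito <- rowSums(mu)
    mu[, mito] <- (f_mito / (1 - f_mito)) * tot_nonmito / length(mito)
    cnt <- matrix(rnbinom(ncell * ng, mu = mu, size = ex$nb_size),
                  nrow = ncell)
    cid <- sprintf("%s_c%03d", s, seq_len(ncell))
    rownames(cnt) <- cid
    counts[[s]] <- cnt
    cells[[s]] <- tibble::tibble(cell_id = cid, sample_id = s,
                                 celltype = ctype, subcluster = sub)
  }
  counts <- do.call(rbind, counts)
  colnames(counts) <- gene_ids
  sc <- list(
    counts = Matrix::Matrix(counts, sparse = TRUE),
    cells = dplyr::bind_rows(cells),
    genes = tibble::tibble(gene_id = gene_ids,
                           mito = seq_along(gene_ids) %in% mito)
  )

  list(bulk = bulk, sc = sc,
       truth = list(egenes = egenes, bulk_de_genes = de_genes,
                    sc_marker_genes = gene_ids[marker],
                    sc_case_shift = shift))
}
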