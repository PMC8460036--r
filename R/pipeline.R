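# End-to-end orchestration of the two-stage-plus-meta study design.

#' Study configuration
#'
#' @param cohorts Named list of cohorts (each an `endo_cohort` or a
#'   directory for [read_cohort()]). Exactly one name must be
#'   `"discovery"`; other case-control cohorts are replication sets; a
#'   cohort named `"family"` is analysed with the kinship mixed model.
#' @param gene_sets Named list of gene sets; default: the discovery
#'   cohort's bundled sets, control sets excluded.
#' @param maf_thresholds Rarity thresholds (default 0.01 and 0.001).
#' @param phenotypes Phenotypes to run, subset of `ad`, `braak`, `aao`.
#' @param alpha Family-wise alpha (default 0.05).
#' @param n_tests Tests in the gene-set family; default
#'   `length(gene_sets) * length(maf_thresholds)` (8 in the study design).
#' @param use_computed_pcs Replace the phenotype table's PC columns with
#'   genotype PCs from [compute_pcs()].
#' @param run_gene_scan Also run the per-gene kernel scan.
#' @return List of class `study_config`.
#' @export
study_config <- function(cohorts, gene_sets = NULL,
                         maf_thresholds = c(0.01, 0.001),
                         phenotypes = c("ad", "braak", "aao"),
                         alpha = 0.05, n_tests = NULL,
                         use_computed_pcs = FALSE,
                         run_gene_scan = FALSE) {
  if (sum(names(cohorts) == "discovery") != 1L) {
    abort_endo("exactly one cohort must be named 'discovery'")
  }
  phenotypes <- match.arg(phenotypes, several.ok = TRUE)
  structure(list(cohorts = cohorts, gene_sets = gene_sets,
                 maf_thresholds = maf_thresholds, phenotypes = phenotypes,
                 alpha = alpha, n_tests = n_tests,
                 use_computed_pcs = use_computed_pcs,
                 run_gene_scan = run_gene_scan),
            class = "study_config")
}

# QC + AF + (optional) PC refresh for one cohort
prepare_cohort <- function(cohort, use_computed_pcs = FALSE,
                           is_family = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is_family && !is.null(cohort$families)) {
    fam <- cohort$families
    cohort <- list(panel = cohort$panel, dosage = fam$dosage, gq = fam$gq,
                   samples = fam$samples, kinship = fam$kinship,
                   gene_sets = cohort$gene_sets)
  }
  qc <- run_qc(cohort)
  af <- compute_internal_af(qc$dosage)
  variants <- dplyr::left_join(qc$variants, af, by = "variant_id")
  samples <- qc$samples
  if (use_computed_pcs) {
    pcs <- compute_pcs(qc$dosage)
    keep <- setdiff(names(samples), paste0("PC", 1:10))
    samples <- dplyr::inner_join(samples[, keep], pcs, by = "sample_id")
  }
  list(dosage = qc$dosage, variants = variants, samples = samples,
       report = qc$report, kinship = cohort$kinship)
}

# burden association rows for one prepared cohort / gene set / threshold
cohort_burden_models <- function(prep, gene_set, maf_threshold, phenotypes,
                                 is_family = FALSE) {
  sel <- select_variants(prep$variants, gene_set,
                         selection_config(maf_threshold))
  if (nrow(sel) == 0) return(NULL)
  scores <- burden_score(prep$dosage, sel)
  scores <- residualize(scores, prep$samples)
  dat <- dplyr::inner_join(prep$samples,
                           scores[, c("sample_id", "residual")],
                           by = "sample_id")
  # a degenerate burden (e.g. no carriers in a small cohort) skips this
  # cohort's rows rather than aborting the whole study
  try_model <- function(expr) {
    tryCatch(expr, endoburden_error = function(e) {
      warn(sprintf("skipping one model: %s", conditionMessage(e)))
      NULL
    })
  }
  rows <- list()
  for (model in c("M0", "M1", "M2")) {
    if ("ad" %in% phenotypes) {
      rows[[length(rows) + 1L]] <- try_model(if (is_family) {
        glmm_burden_test(dat, prep$kinship, model = model)
      } else {
        logistic_burden_test(dat, model = model)
      })
    }
    if ("braak" %in% phenotypes && !all(is.na(dat$braak))) {
      rows[[length(rows) + 1L]] <- try_model(
        ordinal_burden_test(dat, model = model))
    }
    if ("aao" %in% phenotypes) {
      rows[[length(rows) + 1L]] <- try_model(
        cox_burden_test(dat, model = model))
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the staged burden study end to end
#'
#' Per cohort: QC, dual-source variant selection, burden scoring and
#' residualization, and the nested M0/M1/M2 models per phenotype (logistic
#' for AD, kinship mixed model in the family cohort, proportional odds for
#' Braak, Cox for age at onset). Best-model results are then combined
#' across cohorts by inverse-variance weighting and direction-aware Fisher,
#' with the Bonferroni family threshold `alpha / n_tests`.
#'
#' @param cfg A [study_config()].
#' @return List of class `endo_study`: `assoc` (per cohort/gene-set/
#'   threshold/model rows), `meta` (combined rows with significance flags),
#'   `qc_reports`, `gene_scan` (if requested), `config`.
#' @export
run_study <- function(cfg) {
  gene_sets <- cfg$gene_sets
  preps <- purrr::imap(cfg$cohorts, function(ch, nm) {
    prepare_cohort(ch, cfg$use_computed_pcs, is_family = nm == "family")
  })
  if (is.null(gene_sets)) {
    ch <- cfg$cohorts$discovery
    if (is.character(ch)) ch <- read_cohort(ch)
    gene_sets <- ch$gene_sets[!grepl("control", names(ch$gene_sets))]
  }
  n_tests <- cfg$n_tests %||% (length(gene_sets) * length(cfg$maf_thresholds))
  threshold <- bonferroni_threshold(cfg$alpha, n_tests)

  grid <- tidyr::expand_grid(gene_set = names(gene_sets),
                             maf = cfg$maf_thresholds)
  assoc <- purrr::pmap(grid, function(gene_set, maf) {
    purrr::imap(preps, function(prep, nm) {
      rows <- cohort_burden_models(prep, gene_sets[[gene_set]], maf,
                                   cfg$phenotypes, is_family = nm == "family")
      if (is.null(rows)) return(NULL)
      dplyr::mutate(rows, cohort = nm, gene_set = gene_set,
                    maf_threshold = maf, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  cohort_order <- names(cfg$cohorts)
  meta <- assoc |>
    dplyr::group_by(.data$gene_set, .data$maf_threshold, .data$phenotype) |>
    dplyr::group_modify(function(df, key) {
      best <- df |>
        dplyr::group_by(.data$cohort) |>
        dplyr::group_modify(~ select_best_model(.x)) |>
        dplyr::ungroup() |>
        dplyr::arrange(match(.data$cohort, cohort_order))
      if (nrow(best) < 2) return(tibble::tibble())
      ivw <- inverse_variance_meta(best)
      fis <- directional_fisher(best)
      tibble::tibble(method = c("inverse_variance", "directional_fisher"),
                     estimate = c(ivw$estimate, NA), se = c(ivw$se, NA),
                     p = c(ivw$p, fis$p), k = nrow(best))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p < threshold)

  out <- list(assoc = assoc, meta = meta,
              qc_reports = purrr::map(preps, "report"),
              bonferroni = threshold, config = cfg)
  if (cfg$run_gene_scan) {
    prep <- preps$discovery
    dat <- prep$samples
    null <- fit_null(dat, "status", model_covariates("M2"), "binary")
    sel <- select_variants(prep$variants,
                           gene_sets[[1]],
                           selection_config(cfg$maf_thresholds[1]))
    out$gene_scan <- per_gene_scan(null, prep$dosage, sel, cfg$alpha)
  }
  structure(out, class = "endo_study")
}

#' Negative-control run on unrelated gene sets
#'
#' Runs the identical burden pipeline on user-supplied control gene sets
#' (e.g. BMI/height genes) and contrasts significance and directions with
#' the primary gene set.
#'
#' @param cfg A [study_config()].
#' @param control_sets Named list of control gene sets (non-empty).
#' @return `endo_study` whose `meta` table carries an `is_control` flag and
#'   a `contrast` tibble comparing primary vs control significance.
#' @export
negative_control_run <- function(cfg, control_sets) {
  if (!length(control_sets)) abort_endo("empty control gene-set list")
  primary <- run_study(cfg)
  cfg_ctrl <- cfg
  cfg_ctrl$gene_sets <- control_sets
  # judge the controls against the same family-wise threshold as the
  # primary gene sets
  cfg_ctrl$n_tests <- round(cfg$alpha / primary$bonferroni)
  ctrl <- run_study(cfg_ctrl)
  primary$meta$is_control <- FALSE
  ctrl$meta$is_control <- TRUE
  meta <- dplyr::bind_rows(primary$meta, ctrl$meta)
  contrast <- meta |>
    dplyr::group_by(.data$is_control) |>
    dplyr::summarise(n_significant = sum(.data$significant, na.rm = TRUE),
                     min_p = min(.data$p, na.rm = TRUE), .groups = "drop")
  structure(list(assoc = dplyr::bind_rows(primary$assoc, ctrl$assoc),
                 meta = meta, contrast = contrast,
                 bonferroni = primary$bonferroni, config = cfg),
            class = "endo_study")
}

#' Write an `endo_study` bundle to a directory
#'
#' @param study An `endo_study`.
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(study$assoc, file.path(dir, "assoc_results.tsv"))
  readr::write_tsv(study$meta, file.path(dir, "meta_results.tsv"))
  for (nm in names(study$qc_reports)) {
    write_qc_report(study$qc_reports[[nm]],
                    file.path(dir, sprintf("qc_report_%s.json", nm)))
  }
  if (!is.null(study$gene_scan)) {
    readr::write_tsv(study$gene_scan, file.path(dir, "single_gene_results.tsv"))
  }
  invisible(dir)
}
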