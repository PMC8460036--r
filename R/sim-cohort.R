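# Synthetic cohort generator: variant panel, HWE genotypes, phenotypes,
# families, expression. Every draw is reproducible from sim_config()$seed.

DELETERIOUS_CLASSES <- c("stop-gain", "stop-loss", "frameshift",
                         "splice-donor", "splice-acceptor")
CELL_TYPES <- c("Ex", "In", "Ast", "Oli", "Opc", "Mic")

#' Deterministic gene coordinates for the synthetic panel
#'
#' Lays `n_genes` genes round-robin over chromosomes 1-22 (no X, which the
#' analyses exclude) with 20 kb bodies spaced far enough apart that the
#' TSS +/- 20 kb cis windows never overlap.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with gene_id, chrom, body_start, body_end, tss (1-based).
#' @export
sim_gene_windows <- function(cfg) {
  g <- seq_len(cfg$n_genes)
  chrom <- (g - 1L) %% 22L + 1L
  slot <- (g - 1L) %/% 22L
  start <- 100000L + slot * 300000L
  tibble::tibble(
    gene_id = sprintf("G%04d", g),
    chrom = as.character(chrom),
    body_start = start,
    body_end = start + 19999L,
    tss = start
  )
}

#' Simulate the annotated variant panel
#'
#' Draws per-variant coordinates, consequence class, PolyPhen-style damaging
#' flag, scaled CADD score, true allele frequency from the configured
#' heavy-tailed spectrum, and external reference frequencies (1KG EUR,
#' gnomAD NFE) with partial coverage. A small fraction of variants is marked
#' non-PASS or multi-allelic so the QC chain has something to remove.
#'
#' @param cfg A [sim_config()].
#' @return Tibble, one row per variant (the annotation/variant table).
#' @export
simulate_variant_panel <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort_endo("`cfg` must be a sim_config")
  genes <- sim_gene_windows(cfg)
  n_var <- pmax(1L, rpois(cfg$n_genes, cfg$variants_per_gene))
  gene_idx <- rep(seq_len(cfg$n_genes), n_var)
  m <- length(gene_idx)

  # positions: body plus flank, deliberately a bit wider than the cis window
  pos <- genes$tss[gene_idx] +
    sample(-22000:22000, m, replace = TRUE)

  sp <- cfg$maf_spectrum
  af_singleton <- 1 / (2 * cfg$n_samples)
  is_singleton <- runif(m) < sp$singleton_mass
  af_beta <- rbeta(m, sp$shape1, sp$shape2)
  # reject mass above 0.5 (truncation); resample the handful that land there
  while (any(bad <- af_beta > 0.5)) {
    af_beta[bad] <- rbeta(sum(bad), sp$shape1, sp$shape2)
  }
  af_true <- ifelse(is_singleton, af_singleton, pmax(af_beta, 1e-6))

  deleterious <- runif(m) < cfg$frac_deleterious
  consequence <- character(m)
  consequence[deleterious] <- sample(
    c(DELETERIOUS_CLASSES, "missense-damaging"), sum(deleterious),
    replace = TRUE, prob = c(0.10, 0.03, 0.12, 0.05, 0.05, 0.65))
  consequence[!deleterious] <- sample(
    c("missense-benign", "synonymous"), sum(!deleterious),
    replace = TRUE, prob = c(0.45, 0.55))

  polyphen_damaging <- dplyr::case_when(
    consequence == "missense-damaging" ~ 1L,
    consequence == "missense-benign" ~ 0L,
    TRUE ~ NA_integer_
  )
  cadd_scaled <- ifelse(deleterious,
                        pmax(rnorm(m, 25, 8), 0),
                        pmax(rnorm(m, 5, 4), 0))

  covered <- runif(m) < cfg$frac_external_covered
  has_kg <- covered & runif(m) < 0.9
  has_gnomad <- covered & runif(m) < 0.9
  has_gnomad[covered & !has_kg & !has_gnomad] <- TRUE
  jitter_af <- function(af) pmin(af * exp(rnorm(length(af), 0, 0.3)), 0.5)
  af_kg <- ifelse(has_kg, jitter_af(af_true), NA_real_)
  af_gnomad <- ifelse(has_gnomad, jitter_af(af_true), NA_real_)
  # external databases occasionally record an observed frequency of zero;
  # a recorded zero counts as "present" for the rarity rule
  af_kg[has_kg & runif(m) < 0.02] <- 0
  af_gnomad[has_gnomad & runif(m) < 0.02] <- 0

  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  nonpass <- runif(m) < cfg$qc_fail_rates$nonpass
  multi <- runif(m) < cfg$qc_fail_rates$multiallelic

  panel <- tibble::tibble(
    variant_id = sprintf("v%05d", seq_len(m)),
    chrom = genes$chrom[gene_idx],
    pos = pos,
    ref = ref,
    alt = alt,
    gene_id = genes$gene_id[gene_idx],
    consequence = consequence,
    polyphen_damaging = polyphen_damaging,
    cadd_scaled = cadd_scaled,
    af_true = af_true,
    af_kg_eur = af_kg,
    af_gnomad_nfe = af_gnomad,
    filter = ifelse(nonpass, "VQSRTrancheSNP99.90to100.00", "PASS"),
    biallelic = !multi
  )
  dplyr::arrange(panel, as.integer(.data$chrom), .data$pos)
}

#' Simulate genotype dosages and genotype-quality values
#'
#' Dosages are drawn binomial(2, AF) independently per sample, i.e. exactly
#' under Hardy-Weinberg equilibrium, matching the HWE filtering assumption of
#' the QC module. Missing entries and sub-threshold GQ values are injected at
#' the configured rates.
#'
#' @param panel Variant table from [simulate_variant_panel()].
#' @param cfg A [sim_config()].
#' @param sample_ids Optional sample id vector (defaults to `S0001`...).
#' @return List with `dosage` (samples x variants matrix, NA = missing) and
#'   `gq` (integer matrix of genotype qualities).
#' @export
simulate_genotypes <- function(panel, cfg, sample_ids = NULL) {
  if (nrow(panel) == 0L) abort_endo("variant panel is empty")
  n <- cfg$n_samples
  m <- nrow(panel)
  sample_ids <- sample_ids %||% sprintf("S%04d", seq_len(n))
  dosage <- matrix(
    rbinom(n * m, 2L, rep(panel$af_true, each = n)),
    nrow = n, ncol = m, dimnames = list(sample_ids, panel$variant_id))
  gq <- matrix(21L + as.integer(runif(n * m) * 79), nrow = n, ncol = m,
               dimnames = list(sample_ids, panel$variant_id))
  low <- runif(n * m) < cfg$low_gq_rate
  gq[low] <- as.integer(runif(sum(low)) * 21)
  if (cfg$missingness_rate > 0) {
    dosage[runif(n * m) < cfg$missingness_rate] <- NA_integer_
  }
  list(dosage = dosage, gq = gq)
}

# the true burden used by the phenotype model: fraction of minor alleles over
# truly-deleterious, truly-rare variants in the causal gene set, z-scored
true_burden <- function(dosage, panel, gene_set, maf = 0.01,
                        allow_empty = FALSE) {
  causal <- panel$variant_id[
    (panel$consequence %in% DELETERIOUS_CLASSES |
       panel$consequence == "missense-damaging") &
      panel$af_true < maf & panel$gene_id %in% gene_set]
  if (!length(causal)) {
    if (allow_empty) {
      z <- rep(0, nrow(dosage))
      return(list(raw = z, z = z, causal_variants = character(0)))
    }
    abort_endo("gene set contains no causal variants")
  }
  g <- dosage[, causal, drop = FALSE]
  raw <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  raw[is.nan(raw)] <- 0
  s <- sd(raw)
  z <- if (s > 0) (raw - mean(raw)) / s else raw * 0
  list(raw = raw, z = z, causal_variants = causal)
}

# shared phenotype draw: status, Braak, event time, covariates
draw_phenotypes <- function(burden_z, cfg, sample_ids, family_id = NA_character_) {
  n <- length(burden_z)
  eff <- cfg$covariate_effects
  age <- round(pmin(pmax(rnorm(n, 75, 8), 55), 100))
  sex <- rbinom(n, 1L, 0.5)
  center <- sample(c("A", "B", "C"), n, replace = TRUE)
  apoe_e2 <- rbinom(n, 2L, 0.07)
  apoe_e4 <- rbinom(n, 2L, 0.2)
  pcs <- matrix(rnorm(n * 10L), n, 10L,
                dimnames = list(NULL, paste0("PC", 1:10)))

  eta <- cfg$prevalence_intercept + cfg$burden_logOR * burden_z +
    eff$age * (age - 75) + eff$sex * sex +
    eff$center * (as.integer(factor(center, c("A", "B", "C"))) - 2L) +
    eff$apoe_e2 * apoe_e2 + eff$apoe_e4 * apoe_e4
  case <- rbinom(n, 1L, plogis(eta))
  status <- ifelse(case == 1L, "case", "control")
  status[runif(n) < cfg$mci_rate] <- "MCI"

  latent <- cfg$burden_logOR * burden_z + stats::rlogis(n)
  braak <- findInterval(latent, cfg$braak_cutpoints)

  rate0 <- 0.05
  t_event <- rexp(n, rate0 * exp(cfg$hazard_logHR * burden_z))
  censor_at <- stats::qexp(1 - cfg$censor_rate, rate0)
  event_flag <- as.integer(t_event <= censor_at)
  event_time <- 65 + pmin(t_event, censor_at)

  tibble::tibble(
    sample_id = sample_ids, status = status, sex = sex, age = age,
    center = center, apoe_e2 = apoe_e2, apoe_e4 = apoe_e4,
    braak = as.integer(braak), family_id = family_id,
    event_time = event_time, event_flag = event_flag
  ) |>
    dplyr::bind_cols(tibble::as_tibble(pcs))
}

#' Simulate phenotypes and covariates from genotypes
#'
#' Case/control status follows a logistic model on the z-scored true gene-set
#' burden plus covariate effects; Braak stages come from a proportional-odds
#' latent logistic variable with the configured cutpoints (skewed toward
#' stages V-VI by default); onset/death times follow an exponential
#' proportional-hazards model with administrative censoring. The genome-wide
#' rare-variant count per sample is emitted and is, under the null,
#' independent of status.
#'
#' @param geno Genotype list from [simulate_genotypes()] (or dosage matrix).
#' @param panel Variant table.
#' @param gene_set Character vector of causal gene ids.
#' @param cfg A [sim_config()].
#' @return List with `samples` (phenotype/covariate tibble) and `truth`
#'   (per-sample true burden and generating parameters; never consumed by
#'   the analysis modules).
#' @export
simulate_phenotypes <- function(geno, panel, gene_set, cfg) {
  dosage <- if (is.list(geno)) geno$dosage else geno
  if (!any(gene_set %in% panel$gene_id)) {
    abort_endo("gene set shares no genes with the variant panel")
  }
  tb <- true_burden(dosage, panel, gene_set)
  samples <- draw_phenotypes(tb$z, cfg, rownames(dosage))

  rare <- panel$variant_id[panel$af_true < 0.01]
  n_rare_panel <- rowSums(dosage[, rare, drop = FALSE] > 0, na.rm = TRUE)
  samples$n_rare_total <- as.integer(n_rare_panel + rpois(nrow(samples), 1000))

  truth <- list(
    burden_raw = setNames(tb$raw, rownames(dosage)),
    burden_z = setNames(tb$z, rownames(dosage)),
    causal_variants = tb$causal_variants,
    causal_genes = intersect(gene_set, panel$gene_id),
    params = cfg[c("burden_logOR", "prevalence_intercept", "hazard_logHR",
                   "censor_rate", "braak_cutpoints")]
  )
  list(samples = samples, truth = truth)
}

#' Simulate nuclear families with Mendelian transmission
#'
#' Parents are drawn from the panel allele frequencies; each child receives
#' one allele per parent per variant. Expected kinship entries are 0.5 on the
#' diagonal, 0.25 for parent-offspring and full siblings, 0 across families.
#'
#' @param cfg A [sim_config()].
#' @param panel Variant table.
#' @return List with `dosage`, `gq`, `kinship` (square matrix over family
#'   sample ids), and `samples` (phenotypes incl. `family_id`).
#' @export
simulate_families <- function(cfg, panel) {
  nf <- cfg$n_families
  k <- cfg$sibship_size
  if (nf == 0L) return(NULL)
  m <- nrow(panel)
  fam_size <- 2L + k
  ids <- character(0)
  rows <- list()
  kin <- matrix(0, nf * fam_size, nf * fam_size)
  fam_labels <- character(nf * fam_size)
  for (f in seq_len(nf)) {
    fid <- sprintf("F%03d", f)
    # parental haplotypes as two Bernoulli(AF) draws per variant
    father <- rbinom(m, 1L, panel$af_true) + rbinom(m, 1L, panel$af_true)
    mother <- rbinom(m, 1L, panel$af_true) + rbinom(m, 1L, panel$af_true)
    members <- rbind(father, mother)
    if (k > 0) {
      kids <- t(vapply(seq_len(k), function(i) {
        rbinom(m, 1L, father / 2) + rbinom(m, 1L, mother / 2)
      }, numeric(m)))
      members <- rbind(members, kids)
    }
    member_ids <- sprintf("%s_%s", fid,
                          c("P1", "P2", if (k > 0) sprintf("C%d", seq_len(k))))
    rows[[f]] <- members
    ids <- c(ids, member_ids)
    off <- (f - 1L) * fam_size
    blk <- matrix(0, fam_size, fam_size)
    diag(blk) <- 0.5
    for (child in seq_len(k) + 2L) {
      blk[1L, child] <- blk[child, 1L] <- 0.25
      blk[2L, child] <- blk[child, 2L] <- 0.25
    }
    if (k > 1) {
      for (a in 3L:(fam_size - 1L)) for (b in (a + 1L):fam_size) {
        blk[a, b] <- blk[b, a] <- 0.25
      }
    }
    kin[off + seq_len(fam_size), off + seq_len(fam_size)] <- blk
    fam_labels[off + seq_len(fam_size)] <- fid
  }
  dosage <- do.call(rbind, rows)
  dimnames(dosage) <- list(ids, panel$variant_id)
  dimnames(kin) <- list(ids, ids)
  gq <- matrix(99L, nrow(dosage), ncol(dosage), dimnames = dimnames(dosage))

  tb <- true_burden(dosage, panel, unique(panel$gene_id), allow_empty = TRUE)
  samples <- draw_phenotypes(tb$z, cfg, ids, family_id = fam_labels)
  samples$n_rare_total <- as.integer(rpois(nrow(samples), 1000))
  list(dosage = dosage, gq = gq, kinship = kin, samples = samples,
       truth = list(burden_z = setNames(tb$z, ids)))
}

# compartment gene sets over the simulated genes; the union ("endo_system")
# is deduplicated, and two disjoint control sets are kept aside
make_gene_sets <- function(cfg) {
  genes <- sim_gene_windows(cfg)$gene_id
  n <- length(genes)
  n_path <- max(3L, floor(0.7 * n))
  pathway <- sample(genes, n_path)
  endosome <- sample(pathway, ceiling(0.6 * n_path))
  lysosome <- sample(pathway, ceiling(0.45 * n_path))
  tgn <- sample(pathway, max(1L, ceiling(0.15 * n_path)))
  rest <- setdiff(genes, pathway)
  sets <- list(
    endo_system = sort(unique(c(endosome, lysosome, tgn))),
    endosome = sort(endosome),
    lysosome = sort(lysosome),
    trans_golgi_network = sort(tgn)
  )
  if (length(rest) >= 4L) {
    half <- length(rest) %/% 2L
    sets$bmi_control <- sort(sample(rest, half))
    sets$height_control <- sort(setdiff(rest, sets$bmi_control))
  }
  sets
}

#' Simulate the complete synthetic cohort
#'
#' Runs the full generator under one seed: variant panel, HWE genotypes with
#' missingness and GQ, gene sets (a causal "endo_system" union of three
#' compartments plus disjoint control sets), phenotypes, families, and bulk
#' plus single-cell expression.
#'
#' @param cfg A [sim_config()].
#' @return List of class `endo_cohort`.
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  panel <- simulate_variant_panel(cfg)
  geno <- simulate_genotypes(panel, cfg)
  gene_sets <- make_gene_sets(cfg)
  ph <- simulate_phenotypes(geno, panel, gene_sets$endo_system, cfg)
  fam <- simulate_families(cfg, panel)
  expr <- simulate_expression(geno, panel, ph$samples, cfg)
  structure(
    list(panel = panel, dosage = geno$dosage, gq = geno$gq,
         samples = ph$samples, gene_sets = gene_sets,
         gene_windows = sim_gene_windows(cfg),
         families = fam, bulk = expr$bulk, sc = expr$sc,
         truth = c(ph$truth, expr$truth), config = cfg),
    class = "endo_cohort"
  )
}
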