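#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic-data generator into a validated list.
#' The defaults describe the study conditions the downstream analyses assume:
#' a case-control whole-genome cohort of European-like samples with rare
#' variants in Hardy-Weinberg equilibrium, a heavy-tailed minor-allele
#' frequency spectrum in which singleton-scale variants dominate (so both the
#' 0.1% and the 1% rarity thresholds bite), case status driven by the true
#' gene-set burden through a logistic model, Braak stages skewed toward V-VI
#' through a proportional-odds latent variable, exponential onset times under
#' proportional hazards, nuclear families with known kinship, and bulk plus
#' single-cell expression with cis rare-variant eGene effects.
#'
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output files.
#' @param n_samples Number of unrelated case-control samples.
#' @param n_genes Number of genes in the variant panel.
#' @param variants_per_gene Mean of the (zero-truncated) Poisson number of
#'   variants per gene.
#' @param maf_spectrum List with `shape1`, `shape2` (Beta law truncated to
#'   (0, 0.5]) and `singleton_mass`, the point mass placed at singleton-scale
#'   frequency `1/(2 * n_samples)`.
#' @param frac_deleterious Proportion of variants drawn from deleterious
#'   consequence classes.
#' @param frac_external_covered Proportion of variants carried in the external
#'   allele-frequency tables (1KG EUR / gnomAD NFE columns).
#' @param burden_logOR Log odds ratio of case status per standard deviation of
#'   true gene-set burden.
#' @param prevalence_intercept Intercept of the case-status logistic model.
#' @param covariate_effects Named list of log-odds effects for `age` (per
#'   year, centered), `sex`, `center`, `apoe_e2` and `apoe_e4` allele counts.
#' @param braak_cutpoints Six strictly increasing cutpoints of the latent
#'   logistic variable defining Braak stages 0..VI; the default places most
#'   mass on stages V and VI.
#' @param hazard_logHR Log hazard ratio of the event (onset/death) per SD of
#'   true burden.
#' @param censor_rate Target fraction of administratively censored samples.
#' @param mci_rate Fraction of samples relabelled MCI (excluded upstream of
#'   the binary models).
#' @param missingness_rate Per-entry genotype missingness rate.
#' @param low_gq_rate Rate of entries whose genotype quality falls below the
#'   GQ 21 masking threshold.
#' @param qc_fail_rates List with `nonpass` (fraction of variants failing the
#'   site filter) and `multiallelic` (fraction flagged multi-allelic).
#' @param n_families,sibship_size Number of two-parent families and children
#'   per family for the family cohort.
#' @param expression List of expression-generator knobs; see Details.
#'
#' @details The `expression` list accepts: `n_expr_genes` (bulk genes),
#' `frac_egene` (fraction of bulk genes given a cis rare-variant effect),
#' `egene_effect` (effect in residual-SD units per standardized carrier
#' burden), `bulk_case_shift` (case-minus-control shift on designated genes),
#' `n_sc_genes`, `n_cells_per_sample`, `case_shift_per_celltype` (named
#' vector over Ex/In/Ast/Oli/Opc/Mic applied to designated marker genes on
#' the log scale), `nb_size` (negative-binomial dispersion), and
#' `mito_shape1`/`mito_shape2` (Beta law of per-cell mitochondrial fraction,
#' spanning the 5% QC threshold).
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_samples = 200, n_genes = 20)
#' cfg$maf_spectrum$singleton_mass
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 3000L,
                       n_genes = 100L,
                       variants_per_gene = 8,
                       maf_spectrum = list(shape1 = 0.08, shape2 = 5,
                                           singleton_mass = 0.5),
                       frac_deleterious = 0.35,
                       frac_external_covered = 0.7,
                       burden_logOR = log(1.25),
                       prevalence_intercept = 0,
                       covariate_effects = list(age = 0.02, sex = 0.3,
                                                center = 0.1, apoe_e2 = -0.4,
                                                apoe_e4 = 1.0),
                       braak_cutpoints = qlogis(c(0.05, 0.10, 0.20, 0.30,
                                                  0.40, 0.65)),
                       hazard_logHR = log(1.3),
                       censor_rate = 0.3,
                       mci_rate = 0.05,
                       missingness_rate = 0.005,
                       low_gq_rate = 0.01,
                       qc_fail_rates = list(nonpass = 0.02,
                                            multiallelic = 0.01),
                       n_families = 40L,
                       sibship_size = 2L,
                       expression = list()) {
  assert_count(seed, "seed", positive = FALSE)
  assert_count(n_samples, "n_samples")
  assert_count(n_genes, "n_genes")
  if (!is.numeric(variants_per_gene) || variants_per_gene <= 0) {
    abort_endo("`variants_per_gene` must be positive",
               class = "endoburden_config_error")
  }
  assert_prob(frac_deleterious, "frac_deleterious")
  assert_prob(frac_external_covered, "frac_external_covered")
  assert_prob(censor_rate, "censor_rate")
  assert_prob(mci_rate, "mci_rate")
  assert_prob(missingness_rate, "missingness_rate")
  assert_prob(low_gq_rate, "low_gq_rate")
  assert_prob(maf_spectrum$singleton_mass, "maf_spectrum$singleton_mass")
  if (length(braak_cutpoints) != 6L || any(diff(braak_cutpoints) <= 0)) {
    abort_endo("`braak_cutpoints` must be 6 strictly increasing values",
               class = "endoburden_config_error")
  }
  assert_count(n_families, "n_families", positive = FALSE)
  assert_count(sibship_size, "sibship_size", positive = FALSE)

  expr_defaults <- list(
    n_expr_genes = 60L, frac_egene = 0.2, egene_effect = 1,
    bulk_case_shift = -0.5, n_sc_genes = 3000L, n_cells_per_sample = 60L,
    n_sc_samples = 48L,
    case_shift_per_celltype = c(Ex = 0.8, In = 0, Ast = 0, Oli = -0.8,
                                Opc = 0, Mic = 0),
    nb_size = 2, mito_shape1 = 2, mito_shape2 = 60
  )
  expression <- modifyList(expr_defaults, expression)

  structure(
    list(seed = as.integer(seed), n_samples = as.integer(n_samples),
         n_genes = as.integer(n_genes),
         variants_per_gene = variants_per_gene,
         maf_spectrum = maf_spectrum,
         frac_deleterious = frac_deleterious,
         frac_external_covered = frac_external_covered,
         burden_logOR = burden_logOR,
         prevalence_intercept = prevalence_intercept,
         covariate_effects = covariate_effects,
         braak_cutpoints = braak_cutpoints,
         hazard_logHR = hazard_logHR,
         censor_rate = censor_rate,
         mci_rate = mci_rate,
         missingness_rate = missingness_rate,
         low_gq_rate = low_gq_rate,
         qc_fail_rates = qc_fail_rates,
         n_families = as.integer(n_families),
         sibship_size = as.integer(sibship_size),
         expression = expression),
    class = "sim_config"
  )
}

#' Cumulative distribution of the simulated allele-frequency spectrum
#'
#' Closed-form CDF of the generator's minor-allele frequency law: a point
#' mass at the singleton-scale frequency mixed with a Beta distribution
#' truncated to (0, 0.5]. Used by tests to check the realized spectrum.
#'
#' @param q Frequency at which to evaluate the CDF.
#' @param cfg A [sim_config()].
#' @return P(AF <= q) under the configured spectrum.
#' @export
maf_spectrum_cdf <- function(q, cfg) {
  sp <- cfg$maf_spectrum
  af_singleton <- 1 / (2 * cfg$n_samples)
  trunc <- pbeta(0.5, sp$shape1, sp$shape2)
  beta_cdf <- pmin(pbeta(q, sp$shape1, sp$shape2) / trunc, 1)
  sp$singleton_mass * (q >= af_singleton) + (1 - sp$singleton_mass) * beta_cdf
}
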