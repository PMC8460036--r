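# Independent oracles used across tests.

# brute-force HWE exact test: enumerate all heterozygote counts compatible
# with the observed allele counts, using plain factorials (valid for n <= 50)
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)
  n_major <- 2 * n - n_minor
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  w <- vapply(hs, function(h) {
    2^h / (factorial(h) * factorial((n_minor - h) / 2) *
             factorial((n_major - h) / 2))
  }, numeric(1))
  pr <- w / sum(w)
  p_obs <- pr[hs == n_het]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# Efron partial log-likelihood for a single covariate, for grid-search
# verification of the Cox fit on tied data
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    d_set <- which(time == t & event == 1)
    risk <- which(time >= t)
    d <- length(d_set)
    s_risk <- sum(exp(beta * x[risk]))
    s_tie <- sum(exp(beta * x[d_set]))
    ll <- ll + beta * sum(x[d_set])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(s_risk - l / d * s_tie)
    }
  }
  ll
}

# small deterministic genotype matrix with dimnames
toy_dosage <- function(values, n_samples, n_variants,
                       sample_ids = sprintf("S%03d", seq_len(n_samples)),
                       variant_ids = sprintf("v%03d", seq_len(n_variants))) {
  matrix(values, n_samples, n_variants,
         dimnames = list(sample_ids, variant_ids))
}

# minimal variant table for selection tests
toy_variants <- function(...) {
  defaults <- list(variant_id = "v1", chrom = "1", pos = 1000L, ref = "A",
                   alt = "C", gene_id = "G1", consequence = "synonymous",
                   polyphen_damaging = NA_integer_, cadd_scaled = 5,
                   af_internal = 0.0001, af_kg_eur = NA_real_,
                   af_gnomad_nfe = NA_real_)
  args <- list(...)
  n <- max(c(1L, lengths(args)))
  out <- lapply(seq_len(n), function(i) {
    row <- defaults
    for (nm in names(args)) {
      row[[nm]] <- args[[nm]][[min(i, length(args[[nm]]))]]
    }
    tibble::as_tibble(row)
  })
  dat <- dplyr::bind_rows(out)
  if (!"variant_id" %in% names(args)) {
    dat$variant_id <- sprintf("v%d", seq_len(n))
  }
  dat
}

# phenotype/covariate frame for model tests: burden with a known effect on
# each outcome family
sim_model_frame <- function(n, beta_logit = 0, beta_ordinal = 0,
                            beta_hazard = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  burden <- rnorm(n)
  age <- round(rnorm(n, 75, 8))
  sex <- rbinom(n, 1, 0.5)
  center <- sample(c("A", "B"), n, replace = TRUE)
  apoe_e2 <- rbinom(n, 2, 0.07)
  apoe_e4 <- rbinom(n, 2, 0.2)
  pcs <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("PC", 1:10)))
  eta <- beta_logit * burden
  status <- ifelse(rbinom(n, 1, plogis(eta)) == 1, "case", "control")
  braak <- findInterval(beta_ordinal * burden + rlogis(n),
                        qlogis(c(0.05, 0.15, 0.3, 0.5, 0.7, 0.85)))
  t_ev <- rexp(n, 0.05 * exp(beta_hazard * burden))
  cens <- qexp(0.7, 0.05)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%04d", seq_len(n)),
                   residual = burden, status = status,
                   braak = as.integer(braak), age = age, sex = sex,
                   center = center, apoe_e2 = apoe_e2, apoe_e4 = apoe_e4,
                   event_time = pmin(t_ev, cens),
                   event_flag = as.integer(t_ev <= cens)),
    tibble::as_tibble(pcs))
}
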