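# QC chain: GQ masking, missingness filters, HWE, relatedness, PCA.

test_that("GQ masking uses a strict below-threshold rule", {
  d <- toy_dosage(c(0, 1, 2, 1), 2, 2)
  gq <- matrix(c(20L, 21L, 99L, 0L), 2, 2, dimnames = dimnames(d))
  masked <- mask_low_gq(d, gq, 21L)
  expect_true(is.na(masked[1, 1]))   # GQ 20 -> missing
  expect_equal(masked[2, 1], 1)      # GQ 21 kept
  expect_true(is.na(masked[2, 2]))   # GQ 0 -> missing
  expect_identical(mask_low_gq(d, gq, 0L), d)  # threshold 0 is identity
  expect_error(mask_low_gq(d, NULL), "GQ")
})

test_that("site filter removes non-PASS and multi-allelic records", {
  v <- toy_variants(variant_id = c("a", "b", "c"),
                    consequence = rep("synonymous", 3))
  v$filter <- c("PASS", "VQSRTrancheSNP99.90to100.00", "PASS")
  v$biallelic <- c(TRUE, TRUE, FALSE)
  d <- toy_dosage(0, 4, 3, variant_ids = c("a", "b", "c"))
  out <- filter_variants_basic(v, d)
  expect_equal(out$variants$variant_id, "a")
  expect_equal(colnames(out$dosage), "a")
  expect_equal(sum(out$report$n_removed), 2)
  # all-PASS biallelic input is untouched
  v2 <- v; v2$filter <- "PASS"; v2$biallelic <- TRUE
  expect_equal(nrow(filter_variants_basic(v2, d)$variants), 3)
})

test_that("missingness filters keep the boundary and drop beyond it", {
  # 100 variants; samples with exactly 5% and 6% missing
  d <- toy_dosage(0, 3, 100)
  d[2, 1:5] <- NA   # exactly 5%
  d[3, 1:6] <- NA   # 6%
  sm <- sample_missingness_filter(d, 0.05)
  expect_setequal(sm$keep, c("S001", "S002"))
  expect_equal(sm$report$n_removed, 1)

  # 100 samples; variants with exactly 2% and 3% missing
  d2 <- toy_dosage(0, 100, 3)
  d2[1:2, 2] <- NA  # exactly 2%
  d2[1:3, 3] <- NA  # 3%
  vm <- variant_missingness_filter(d2, 0.02)
  expect_setequal(vm$keep, c("v001", "v002"))
  # complete data passes untouched
  expect_length(variant_missingness_filter(toy_dosage(0, 10, 4))$keep, 4)
})

test_that("HWE exact test matches enumeration and its symmetries", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(57, 14, 50), hwe_oracle(57, 14, 50),
               tolerance = 1e-12)
  expect_lt(hwe_exact_test(57, 14, 50), 1e-15)   # extreme het deficit
  expect_identical(hwe_exact_test(57, 14, 50), hwe_exact_test(50, 14, 57))
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("HWE filter hits only rare variants and keeps the boundary", {
  set.seed(11)
  n <- 2000
  # v_rare: rare with gross HWE violation (het excess among carriers)
  rare <- c(rep(1, 30), rep(0, n - 30))
  # v_common: gross HWE violation (no heterozygotes) but common
  common <- c(rep(0, 1000), rep(2, 1000))
  d <- cbind(v_rare = sample(rare), v_common = sample(common))
  rownames(d) <- sprintf("S%04d", 1:n)
  samples <- tibble::tibble(sample_id = rownames(d), status = "control")
  p_rare <- hwe_exact_test(n - 30, 30, 0)
  res <- hwe_filter(d, samples, cutoff = 0.001)
  p_common <- hwe_exact_test(1000, 0, 1000)
  expect_lt(p_common, 0.001)
  if (p_rare < 0.001) {
    expect_false("v_rare" %in% res$keep)
  }
  expect_true("v_common" %in% res$keep)   # non-rare untouched
  # boundary: p exactly at the cutoff is retained (strict inequality)
  res2 <- hwe_filter(d, samples, cutoff = p_rare)
  expect_true("v_rare" %in% res2$keep)
  expect_error(hwe_filter(d, tibble::tibble(sample_id = rownames(d),
                                            status = "case")),
               "control")
})

test_that("re-running the QC chain on retained data is a no-op", {
  co <- cached_cohort()
  qc1 <- run_qc(co)
  co2 <- list(panel = qc1$variants, dosage = qc1$dosage,
              gq = co$gq[rownames(qc1$dosage), colnames(qc1$dosage)],
              samples = qc1$samples)
  qc2 <- run_qc(co2)
  expect_identical(dim(qc2$dosage), dim(qc1$dosage))
  expect_equal(sum(qc2$report$n_removed), 0)
  # report records the canonical filter order
  expect_equal(qc1$report$step[c(1, 3, 4, 5, 6)],
               c("site_filter", "gq_mask", "sample_missingness",
                 "variant_missingness", "hwe_controls"))
})

test_that("relatedness recovers duplicates, parent-offspring and unrelateds", {
  cfg <- sim_config(seed = 31, n_samples = 100, n_genes = 150,
                    variants_per_gene = 12, n_families = 40, sibship_size = 1,
                    maf_spectrum = list(shape1 = 2, shape2 = 5,
                                        singleton_mass = 0))
  set.seed(31)
  panel <- simulate_variant_panel(cfg)
  fam <- simulate_families(cfg, panel)
  dup <- rbind(fam$dosage, DUP_F001_P1 = fam$dosage["F001_P1", ])
  rel <- estimate_relatedness(dup, maf_min = 0.05)
  pr <- rel$pairs
  expect_equal(nrow(pr), choose(nrow(dup), 2))

  pair_of <- function(a, b) {
    pr$pi_hat[(pr$id1 == a & pr$id2 == b) | (pr$id1 == b & pr$id2 == a)]
  }
  expect_gte(pair_of("F001_P1", "DUP_F001_P1"), 0.95)

  fam_of <- function(x) substr(x, 1, 4)
  po <- pr[fam_of(pr$id1) == fam_of(pr$id2) &
             grepl("_P", pr$id1) & grepl("_C", pr$id2), ]
  expect_gte(nrow(po), 50)
  expect_true(all(po$pi_hat > 0.3 & po$pi_hat < 0.7))
  # kinship (pi_hat / 2) close to the 0.25 Mendelian expectation on average
  expect_lt(abs(mean(po$pi_hat) / 2 - 0.25), 0.03)

  unrel <- pr[fam_of(pr$id1) != fam_of(pr$id2) & !grepl("DUP", pr$id2), ]
  expect_lt(abs(mean(unrel$pi_hat) / 2), 0.02)
  expect_lt(quantile(unrel$pi_hat, 0.99), 0.185)
})

test_that("few usable variants triggers the recorded warning", {
  set.seed(32)
  d <- toy_dosage(rbinom(50 * 20, 2, 0.3), 50, 20)
  rel <- estimate_relatedness(d)
  expect_match(rel$warnings, "usable common variants")
})

test_that("pruning keeps one sample per relatedness cluster", {
  pairs <- tibble::tibble(
    id1 = c("A", "A", "D"), id2 = c("B", "C", "E"),
    pi_hat = c(0.5, 0.3, 0.95))
  ids <- c("A", "B", "C", "D", "E", "F")
  kept <- prune_related(pairs, ids)
  expect_true("F" %in% kept)                       # unrelated untouched
  expect_length(intersect(kept, c("A", "B", "C")), 1)  # trio -> one kept
  expect_length(intersect(kept, c("D", "E")), 1)       # duplicate -> one kept
  # lowest missing rate wins, ties by id order
  mr <- c(A = 0.02, B = 0.001, C = 0.01, D = 0, E = 0, F = 0)
  kept2 <- prune_related(pairs, ids, missing_rate = mr)
  expect_true("B" %in% kept2)
  expect_true("D" %in% kept2)
  expect_identical(prune_related(pairs[0, ], ids), ids)
})

test_that("PCs separate simulated subpopulations and are orthonormal", {
  set.seed(33)
  n <- 120; m <- 300
  af1 <- runif(m, 0.1, 0.5)
  af2 <- pmin(pmax(af1 + sample(c(-1, 1), m, TRUE) * 0.3, 0.02), 0.95)
  g <- rbind(
    matrix(rbinom(n / 2 * m, 2, rep(af1, each = n / 2)), n / 2, m),
    matrix(rbinom(n / 2 * m, 2, rep(af2, each = n / 2)), n / 2, m))
  dimnames(g) <- list(sprintf("S%03d", 1:n), sprintf("v%03d", 1:m))
  pcs <- compute_pcs(g, k = 10)
  grp <- rep(c(0, 1), each = n / 2)
  expect_gt(abs(cor(pcs$PC1, grp)), 0.9)
  u <- as.matrix(pcs[, -1])
  expect_lt(max(abs(crossprod(u) - diag(10))), 1e-8)
  # identical rows (zero-variance columns) do not produce NaNs
  g2 <- toy_dosage(1, 20, 30)
  g2[, 1:10] <- rbinom(20 * 10, 2, 0.4)
  expect_warning(pcs2 <- compute_pcs(g2, k = 15), "rank")
  expect_false(anyNA(pcs2))
})
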