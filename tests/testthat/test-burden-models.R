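# Burden scoring, residualization, and the nested association models.

test_that("burden score implements the observed-denominator fraction", {
  d <- toy_dosage(c(0, 1, 2), 3, 1)
  d <- cbind(d, v002 = c(0, NA, 0), v003 = c(0, 1, 2))
  # sample 1: (0+0+0)/(2*3); sample 2: (1+1)/(2*2)=0.5 (missing excluded);
  # sample 3: (2+0+2)/(2*3)
  sc <- burden_score(d, c("v001", "v002", "v003"))
  expect_equal(sc$raw, c(0, 0.5, 4 / 6))
  # single-sample cross-check of the (1, missing, 2) example
  d2 <- toy_dosage(c(1, NA, 2), 1, 3)
  expect_equal(burden_score(d2, colnames(d2))$raw, 3 / 4)
  # all-reference sample scores 0; weights scale numerator and denominator
  sel <- tibble::tibble(variant_id = c("v001", "v003"), weight = c(2, 1))
  sc2 <- burden_score(d, sel)
  expect_equal(sc2$raw[1], 0)
  expect_equal(sc2$raw[3], (2 * 2 + 1 * 2) / (2 * 3))
})

test_that("burden score is invariant to ordering and zero-weight variants", {
  set.seed(41)
  d <- toy_dosage(rbinom(60, 2, 0.2), 12, 5)
  sel <- tibble::tibble(variant_id = colnames(d), weight = c(1, 2, 1, 1, 3))
  a <- burden_score(d, sel)
  b <- burden_score(d, sel[sample(5), ])
  expect_equal(a$raw, b$raw)
  sel0 <- dplyr::bind_rows(sel, tibble::tibble(variant_id = "v003",
                                               weight = 0))
  expect_equal(burden_score(d, sel0)$raw, a$raw)
})

test_that("all-missing samples are flagged, not scored", {
  d <- toy_dosage(c(NA, 0, NA, 1), 2, 2)
  sc <- burden_score(d, colnames(d))
  expect_true(sc$flagged[1])
  expect_true(is.na(sc$raw[1]))
  expect_false(sc$flagged[2])
  expect_error(burden_score(d, tibble::tibble(variant_id = character(0),
                                              weight = numeric(0))),
               "no selected")
})

test_that("residualization is exact OLS with the documented properties", {
  set.seed(42)
  n <- 200
  cov <- tibble::tibble(sample_id = sprintf("S%03d", 1:n),
                        n_rare_total = rpois(n, 900))
  pcs <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("PC", 1:10)))
  cov <- dplyr::bind_cols(cov, tibble::as_tibble(pcs))
  scores <- tibble::tibble(sample_id = cov$sample_id,
                           raw = rnorm(n, 0.002, 5e-4))
  out <- residualize(scores, cov, standardize = FALSE)
  expect_lt(abs(mean(out$residual)), 1e-10)
  for (cc in c("n_rare_total", paste0("PC", 1:10))) {
    expect_lt(abs(cor(out$residual, cov[[cc]])), 1e-8)
  }
  # score that is a linear function of the covariate residualizes to ~0
  scores2 <- scores
  scores2$raw <- 0.1 + 3e-6 * cov$n_rare_total
  out2 <- residualize(scores2, cov, standardize = FALSE)
  expect_lt(max(abs(out2$residual)), 1e-8)
  # collinear covariates are dropped with a warning
  cov3 <- cov
  cov3$PC10 <- cov3$PC1
  expect_warning(residualize(scores, cov3), "collinear")
  # standardized residuals keep the properties at unit scale
  out3 <- residualize(scores, cov)
  expect_equal(sd(out3$residual), 1)
  expect_lt(abs(mean(out3$residual)), 1e-10)
})

test_that("two-category proportional odds equals logistic regression", {
  set.seed(43)
  dat <- sim_model_frame(400, beta_ordinal = 0.4)
  dat$braak <- as.integer(dat$braak >= 3)   # collapse to 2 categories
  olr <- ordinal_burden_test(dat, "M1")
  glm_fit <- glm(braak ~ residual + center + PC1 + PC2 + PC3 + PC4 + PC5 +
                   PC6 + PC7 + PC8 + PC9 + PC10 + age + sex,
                 data = dat, family = binomial())
  expect_equal(olr$estimate, unname(coef(glm_fit)["residual"]),
               tolerance = 1e-6)
})

test_that("Cox fit matches a grid-search Efron oracle on tied data", {
  # deliberately tied event times
  time <- c(1, 1, 1, 2, 2, 3, 3, 3, 4, 5, 5, 6)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 0, 1)
  x <- c(0.5, 1.2, -0.3, 0.1, 2.0, -1.0, 0.7, 0.3, -0.5, 1.5, 0.0, -2.0)
  dat <- tibble::tibble(sample_id = as.character(1:12), residual = x,
                        event_time = time, event_flag = event)
  fit <- cox_burden_test(dat, covariates = character(0))
  beta_grid <- optimize(function(b) efron_loglik(b, time, event, x),
                        c(-3, 3), maximum = TRUE)$maximum
  expect_equal(fit$estimate, beta_grid, tolerance = 1e-4)
})

test_that("association models report direction consistently under flips", {
  set.seed(44)
  dat <- sim_model_frame(600, beta_logit = 0.5, beta_ordinal = 0.5,
                         beta_hazard = 0.5)
  lg <- logistic_burden_test(dat, "M1")
  dat_f <- dat
  dat_f$status <- ifelse(dat$status == "case", "control", "case")
  lg_f <- logistic_burden_test(dat_f, "M1")
  expect_equal(lg$estimate, -lg_f$estimate, tolerance = 1e-4)

  ol <- ordinal_burden_test(dat, "M1")
  dat_r <- dat
  dat_r$braak <- 6L - dat$braak
  ol_r <- ordinal_burden_test(dat_r, "M1")
  expect_equal(ol$estimate, -ol_r$estimate, tolerance = 1e-4)

  cx <- cox_burden_test(dat, "M1")
  dat_n <- dat
  dat_n$residual <- -dat$residual
  cx_n <- cox_burden_test(dat_n, "M1")
  expect_equal(cx$estimate, -cx_n$estimate, tolerance = 1e-8)
  expect_true(cx$ratio > 1)
})

test_that("covariate sets nest exactly as specified", {
  expect_setequal(model_covariates("M0"), c("center", paste0("PC", 1:10)))
  expect_setequal(setdiff(model_covariates("M1"), model_covariates("M0")),
                  c("age", "sex"))
  expect_setequal(setdiff(model_covariates("M2"), model_covariates("M1")),
                  c("apoe_e2", "apoe_e4"))
  expect_false("age" %in% model_covariates("M2", time_to_event = TRUE))
})

test_that("degenerate inputs raise the documented errors", {
  dat <- sim_model_frame(100, seed = 45)
  dat$residual <- 0
  expect_error(logistic_burden_test(dat, "M0"), "no variation")
  dat2 <- sim_model_frame(100, seed = 46)
  dat2$braak <- 3L
  expect_error(ordinal_burden_test(dat2, "M0"), "fewer than 2")
  dat3 <- sim_model_frame(100, seed = 47)
  dat3$event_flag <- 0L
  expect_error(cox_burden_test(dat3, "M0"), "no events")
})

test_that("separation is flagged and falls back to a likelihood-ratio p", {
  set.seed(48)
  n <- 60
  dat <- sim_model_frame(n)
  dat$residual <- ifelse(dat$status == "case", abs(rnorm(n)) + 1,
                         -abs(rnorm(n)) - 1)
  res <- suppressWarnings(logistic_burden_test(dat, "M0",
                                               covariates = character(0)))
  expect_true(res$flagged)
  expect_lt(res$p, 1e-6)
})

test_that("kinship mixed model reduces to plain logistic at zero kinship", {
  set.seed(49)
  dat <- sim_model_frame(300, beta_logit = 0.4)
  k0 <- matrix(0, 300, 300, dimnames = list(dat$sample_id, dat$sample_id))
  mm <- glmm_burden_test(dat, k0, "M1")
  lg <- logistic_burden_test(dat, "M1")
  expect_equal(mm$estimate, lg$estimate, tolerance = 1e-4)
  expect_equal(mm$se, lg$se, tolerance = 1e-3)
})

test_that("kinship mixed model tracks the plain fit on family data", {
  cfg <- sim_config(seed = 51, n_samples = 100, n_genes = 60,
                    variants_per_gene = 10, n_families = 80,
                    sibship_size = 2, burden_logOR = log(1.4),
                    mci_rate = 0)
  set.seed(51)
  panel <- simulate_variant_panel(cfg)
  fam <- simulate_families(cfg, panel)
  dat <- fam$samples
  dat$residual <- fam$truth$burden_z[dat$sample_id]
  mm <- glmm_burden_test(dat, fam$kinship, "M1")
  lg <- logistic_burden_test(dat, "M1")
  # family structure shifts the estimate only modestly
  expect_lt(abs(mm$estimate - lg$estimate), 0.2)
  expect_equal(sign(mm$estimate), sign(lg$estimate))
  # non-PSD kinship is repaired with a warning
  bad <- fam$kinship
  bad[1, 2] <- bad[2, 1] <- 5
  expect_warning(glmm_burden_test(dat, bad, "M0"), "positive semi-definite")
})
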