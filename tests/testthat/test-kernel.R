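# Kernel association tests: reductions, invariances, optimal combination,
# score-pooled meta.

make_binary_null <- function(n, seed = 1, covars = TRUE) {
  set.seed(seed)
  dat <- tibble::tibble(sample_id = sprintf("S%04d", 1:n),
                        y = rbinom(n, 1, 0.45),
                        x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  fit_null(dat, "y", if (covars) c("x1", "x2") else character(0), "binary")
}

rand_geno <- function(n, m, maf, seed) {
  set.seed(seed)
  matrix(rbinom(n * m, 2, rep(maf, length.out = m)[rep(1:m, each = n)]),
         n, m, dimnames = list(sprintf("S%04d", 1:n), sprintf("g%02d", 1:m)))
}

test_that("single-variant and burden reductions match score-test closed forms", {
  n <- 400
  null <- make_binary_null(n, seed = 61)
  dat <- data.frame(y = null$fit$y, null$x[, -1])

  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  g1 <- rand_geno(n, 1, 0.05, 62)
  kt <- kernel_test(null, g1, weights = 1, rho = 0)
  f0 <- glm(y ~ x1 + x2, data = cbind(dat, g = g1[, 1]), family = binomial(),
            control = ctrl)
  f1 <- glm(y ~ x1 + x2 + g, data = cbind(dat, g = g1[, 1]),
            family = binomial(), control = ctrl)
  p_rao <- stats::anova(f0, f1, test = "Rao")[2, "Pr(>Chi)"]
  expect_equal(kt$p, p_rao, tolerance = 1e-6)

  g4 <- rand_geno(n, 4, c(0.02, 0.05, 0.01, 0.03), 63)
  w <- c(1, 2, 0.5, 1.5)
  ktb <- kernel_test(null, g4, weights = w, rho = 1)
  b <- as.vector(g4 %*% w)
  f0 <- glm(y ~ x1 + x2, data = cbind(dat, b = b), family = binomial(),
            control = ctrl)
  f1 <- glm(y ~ x1 + x2 + b, data = cbind(dat, b = b), family = binomial(),
            control = ctrl)
  p_rao_b <- stats::anova(f0, f1, test = "Rao")[2, "Pr(>Chi)"]
  expect_equal(ktb$p, p_rao_b, tolerance = 1e-6)
})

test_that("analytic p agrees with a permutation oracle at n = 60", {
  n <- 60
  set.seed(64)
  dat <- tibble::tibble(sample_id = sprintf("S%04d", 1:n),
                        y = rbinom(n, 1, 0.5))
  null <- fit_null(dat, "y", character(0), "binary")
  g <- rand_geno(n, 3, 0.1, 65)
  res <- kernel_test(null, g, rho = 0)
  res_exact <- kernel_test(null, g, rho = 0, exact = TRUE)

  w <- dbeta(pmin(colMeans(g) / 2, 1 - colMeans(g) / 2), 1, 25)
  a <- sweep(g, 2, w, "*")
  n_perm <- 100000
  set.seed(66)
  perm_q <- vapply(seq_len(n_perm), function(i) {
    sum(crossprod(a, sample(null$resid))^2)
  }, numeric(1))
  p_perm <- (1 + sum(perm_q >= res$Q)) / (n_perm + 1)
  band <- 2.58 * sqrt(p_perm * (1 - p_perm) / n_perm)
  # the exact characteristic-function inversion sits inside the MC band
  expect_lt(abs(res_exact$p - p_perm), band + 0.001)
  # the four-moment approximation is bounded by the oracle
  expect_lt(abs(res$p - p_perm), 0.02)
})

test_that("Q is invariant to variant order and all-reference variants", {
  n <- 300
  null <- make_binary_null(n, seed = 67)
  g <- rand_geno(n, 5, 0.04, 68)
  w <- rep(1, 5)
  q1 <- kernel_test(null, g, weights = w, rho = 0)
  q2 <- kernel_test(null, g[, c(3, 1, 5, 2, 4)], weights = w, rho = 0)
  expect_equal(q1$Q, q2$Q)
  expect_equal(q1$p, q2$p, tolerance = 1e-10)
  g0 <- cbind(g, zero = 0L)
  q3 <- kernel_test(null, g0, weights = rep(1, 6), rho = 0)
  expect_equal(q3$Q, q1$Q)
  expect_equal(q3$n_variants, 5L)
})

test_that("continuous-trait p is invariant to location-scale changes of y", {
  n <- 250
  set.seed(69)
  dat <- tibble::tibble(sample_id = sprintf("S%04d", 1:n),
                        expr = rnorm(n, 10, 2), x1 = rnorm(n))
  g <- rand_geno(n, 4, 0.05, 70)
  n1 <- fit_null(dat, "expr", "x1", "continuous")
  p1 <- kernel_test(n1, g, rho = 0)
  dat2 <- dat
  dat2$expr <- 7 * dat$expr - 100
  n2 <- fit_null(dat2, "expr", "x1", "continuous")
  p2 <- kernel_test(n2, g, rho = 0)
  expect_equal(p2$Q / p1$Q, 49, tolerance = 1e-9)
  expect_equal(p1$p, p2$p, tolerance = 1e-9)
})

test_that("optimal test finds burden-like and dispersed signals", {
  n <- 500
  g <- rand_geno(n, 10, 0.05, 71)
  set.seed(72)
  # unidirectional equal effects: burden kernel should win
  y_uni <- rbinom(n, 1, plogis(-0.5 + 0.5 * rowSums(g)))
  dat <- tibble::tibble(sample_id = rownames(g), y = y_uni)
  null_u <- fit_null(dat, "y", character(0), "binary")
  res_u <- optimal_kernel_test(null_u, g)
  # mixed-sign effects: the variance-component end should win
  beta <- rep(c(1.3, -1.3), 5)
  y_mix <- rbinom(n, 1, plogis(as.vector(g %*% beta)))
  dat$y <- y_mix
  null_m <- fit_null(dat, "y", character(0), "binary")
  res_m <- optimal_kernel_test(null_m, g)
  expect_gte(res_u$rho, 0.25)
  expect_lte(res_m$rho, 0.04)
  expect_gt(res_u$rho, res_m$rho)

  # Bonferroni sanity bound over the grid
  per_rho <- vapply(endoburden:::KERNEL_RHO_GRID, function(r) {
    kernel_test(null_m, g, rho = r)$p
  }, numeric(1))
  expect_lte(res_m$p, min(per_rho) * length(per_rho) + 1e-12)
  # single-variant gene degenerates to the plain kernel test
  res1 <- optimal_kernel_test(null_m, g[, 1, drop = FALSE])
  expect_equal(res1$p, kernel_test(null_m, g[, 1, drop = FALSE], rho = 0)$p)
})

test_that("monomorphic genes are skipped with a reason", {
  null <- make_binary_null(100, seed = 73)
  g <- toy_dosage(0, 100, 3)
  res <- kernel_test(null, g)
  expect_true(is.na(res$p))
  expect_equal(res$skipped, "monomorphic")
})

test_that("score-pooled meta doubles information and drops empty cohorts", {
  n <- 400
  g <- rand_geno(n, 6, 0.05, 74)
  set.seed(75)
  y <- rbinom(n, 1, plogis(-0.3 + 0.4 * rowSums(g)))
  dat <- tibble::tibble(sample_id = rownames(g), y = y)
  null <- fit_null(dat, "y", character(0), "binary")
  cmp <- kernel_score_components(null, g)
  single <- meta_kernel_test(list(cmp), rho = 0)
  doubled <- meta_kernel_test(list(cmp, cmp), rho = 0)
  expect_lt(doubled$p, single$p)       # true signal: doubling helps
  expect_equal(single$p, kernel_test(null, g, rho = 0)$p, tolerance = 1e-12)

  zero <- list(score = rep(0, length(cmp$score)),
               info = matrix(0, nrow(cmp$info), ncol(cmp$info)),
               variant_ids = cmp$variant_ids, n = 0L)
  with_zero <- meta_kernel_test(list(cmp, zero), rho = 0)
  expect_equal(with_zero$p, single$p, tolerance = 1e-10)
  expect_error(meta_kernel_test(list()), "no cohort")

  # optimal pooling also runs
  opt <- meta_kernel_test(list(cmp, cmp), rho = "optimal")
  expect_lt(opt$p, 1)
})

test_that("meta pooling of null cohorts keeps uniform p-values", {
  n <- 150
  pvals <- vapply(1:300, function(i) {
    g <- rand_geno(n, 4, 0.08, 7000 + i)
    set.seed(9000 + i)
    y <- rbinom(n, 1, 0.5)
    dat <- tibble::tibble(sample_id = rownames(g), y = y)
    null <- fit_null(dat, "y", character(0), "binary")
    g2 <- rand_geno(n, 4, 0.08, 8000 + i)
    set.seed(9500 + i)
    dat2 <- tibble::tibble(sample_id = rownames(g2), y = rbinom(n, 1, 0.5))
    null2 <- fit_null(dat2, "y", character(0), "binary")
    meta_kernel_test(list(kernel_score_components(null, g),
                          kernel_score_components(null2, g2)), rho = 0)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("per-gene scan applies the carrier floor and Bonferroni threshold", {
  co <- cached_cohort()
  qc <- run_qc(co)
  af <- compute_internal_af(qc$dosage)
  v <- dplyr::left_join(qc$variants, af, by = "variant_id")
  sel <- select_variants(v, co$gene_sets$endo_system, selection_config(0.01))
  dat <- qc$samples
  null <- fit_null(dat, "status", model_covariates("M2"), "binary")
  scan <- per_gene_scan(null, qc$dosage, sel, alpha = 0.05)
  expect_true(all(!is.na(scan$p)))
  expect_equal(attr(scan, "bonferroni"),
               0.05 / attr(scan, "n_genes_tested"))
  # genes below the carrier floor are absent
  carriers <- vapply(split(sel$variant_id, sel$gene_id), function(vv) {
    sum(rowSums(qc$dosage[, vv, drop = FALSE] > 0, na.rm = TRUE) > 0)
  }, numeric(1))
  expect_true(all(carriers[scan$gene_id] >= 2))
})
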