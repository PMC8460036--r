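# Variance-component kernel association tests for rare variants.
#
# The per-gene statistic is the quadratic form Q_rho = S' R_rho S where
# S = W G' r are weighted score contributions (r = working residuals of the
# null model), and R_rho = (1 - rho) I + rho 11' interpolates between the
# pure variance-component kernel (rho = 0) and the pure burden kernel
# (rho = 1). The null distribution is a mixture of chi-squares whose
# p-value is obtained by four-moment (Liu-type) matching, with exact
# characteristic-function inversion (Imhof) available behind a flag.

KERNEL_RHO_GRID <- c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)

#' Fit the null model for kernel tests
#'
#' GLM of the trait on the covariates only: binomial for binary traits,
#' Gaussian for continuous traits (residual variance estimated). Residuals
#' and the covariate projection are stored for the score tests.
#'
#' @param data Tibble holding the outcome and covariates.
#' @param outcome Outcome column; binary outcomes may be 0/1 or
#'   case/control strings.
#' @param covariates Covariate column names ("" gives intercept-only).
#' @param family `"binary"` or `"continuous"`.
#' @return Object of class `endo_null`.
#' @export
fit_null <- function(data, outcome, covariates = character(0),
                     family = c("binary", "continuous")) {
  family <- match.arg(family)
  y <- data[[outcome]]
  if (family == "binary" && !is.numeric(y)) {
    data <- data[y %in% c("case", "control"), , drop = FALSE]
    y <- as.integer(data[[outcome]] == "case")
  }
  keep <- vapply(covariates, function(cc) {
    v <- data[[cc]]
    !(is.character(v) || is.factor(v)) || length(unique(na.omit(v))) > 1
  }, logical(1))
  covariates <- covariates[keep]
  df <- data.frame(y = y, data[, covariates, drop = FALSE])
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fam <- if (family == "binary") binomial() else gaussian()
  fit <- glm(as.formula(paste("y ~", rhs)), data = df, family = fam,
             control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) abort_endo("null model did not converge")
  x <- model.matrix(fit)
  mu <- fitted(fit)
  if (family == "binary") {
    if (all(mu > 1 - 1e-10 | mu < 1e-10)) {
      abort_endo("null model is separated: fitted probabilities degenerate")
    }
    v <- mu * (1 - mu)
  } else {
    sigma2 <- sum((df$y - mu)^2) / (nrow(df) - ncol(x))
    v <- rep(sigma2, nrow(df))
  }
  ids <- if ("sample_id" %in% names(data)) data$sample_id[cc] else NULL
  structure(list(fit = fit, x = x, resid = df$y - mu, v = v,
                 family = family, n = nrow(df),
                 sample_rows = which(cc), sample_ids = ids),
            class = "endo_null")
}

#' @export
print.endo_null <- function(x, ...) {
  cat(sprintf("<endo_null> %s trait, n = %d, %d covariate df\n",
              x$family, x$n, ncol(x$x)))
  invisible(x)
}

# Beta(1,25) density weights at the folded internal MAF (the toolchain
# default when no weights are supplied)
beta_maf_weights <- function(g) {
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  dbeta(maf, 1, 25)
}

# score vector and its covariance for one gene's (weighted) genotypes;
# rows of g are aligned to the null model by sample id when both carry ids,
# otherwise by the rows the null fit retained
kernel_components <- function(null, g, weights = NULL) {
  if (is.null(dim(g))) g <- matrix(g, ncol = 1)
  if (is.null(colnames(g))) colnames(g) <- paste0("v", seq_len(ncol(g)))
  if (!is.null(null$sample_ids) && !is.null(rownames(g)) &&
      all(null$sample_ids %in% rownames(g))) {
    g <- g[null$sample_ids, , drop = FALSE]
  } else if (nrow(g) != null$n) {
    g <- g[null$sample_rows, , drop = FALSE]
  }
  # mean-impute missing genotypes before weighting
  if (anyNA(g)) {
    mu_g <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu_g[idx[, 2]]
  }
  poly <- apply(g, 2, sd) > 0
  if (!any(poly)) return(NULL)
  g <- g[, poly, drop = FALSE]
  w <- weights %||% beta_maf_weights(g)
  if (length(w) != ncol(g)) w <- w[poly]
  gw <- sweep(g, 2, w, "*")
  vx <- null$x * null$v
  xtvx_inv <- solve(crossprod(null$x, vx))
  gvx <- crossprod(gw, vx)                       # m x p
  phi <- crossprod(gw, gw * null$v) - gvx %*% xtvx_inv %*% t(gvx)
  list(score = as.vector(crossprod(gw, null$resid)), info = phi,
       m = ncol(g), variant_ids = colnames(g))
}

# Liu-type four-moment match (modified to also match kurtosis): returns the
# parameters of the approximating (non-central) chi-square
liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  list(l = l, delta = delta, mu_q = c1, sigma_q = sqrt(2 * c2))
}

liu_pvalue <- function(q, lambda) {
  pr <- liu_params(lambda)
  t_star <- (q - pr$mu_q) / pr$sigma_q
  q_norm <- t_star * sqrt(2 * (pr$l + 2 * pr$delta)) + pr$l + pr$delta
  pchisq(q_norm, df = pr$l, ncp = pr$delta, lower.tail = FALSE)
}

liu_quantile <- function(p_upper, lambda) {
  pr <- liu_params(lambda)
  q_norm <- qchisq(p_upper, df = pr$l, ncp = pr$delta, lower.tail = FALSE)
  (q_norm - pr$l - pr$delta) / sqrt(2 * (pr$l + 2 * pr$delta)) * pr$sigma_q +
    pr$mu_q
}

# Imhof characteristic-function inversion (exact up to quadrature error)
imhof_pvalue <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  res <- integrate(integrand, 0, Inf, subdivisions = 5000L,
                   rel.tol = 1e-7, abs.tol = 1e-11, stop.on.error = FALSE)
  min(max(0.5 + res$value / pi, 1e-14), 1)
}

# eigenvalues of R_rho^{1/2} Phi R_rho^{1/2}
rho_eigenvalues <- function(phi, rho) {
  m <- ncol(phi)
  if (rho >= 1) return(sum(phi))
  a <- sqrt(1 - rho)
  cc <- (sqrt(1 - rho + m * rho) - a) / m
  rh <- diag(a, m) + matrix(cc, m, m)
  k <- rh %*% phi %*% rh
  ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > max(ev) * 1e-10]
}

quadform_pvalue <- function(q, lambda, exact = FALSE) {
  if (length(lambda) == 1L) {
    return(pchisq(q / lambda, df = 1, lower.tail = FALSE))
  }
  if (exact) imhof_pvalue(q, lambda) else liu_pvalue(q, lambda)
}

kernel_p_from_components <- function(score, phi, rho, exact = FALSE) {
  q <- (1 - rho) * sum(score^2) + rho * sum(score)^2
  lambda <- rho_eigenvalues(phi, rho)
  list(q = q, p = quadform_pvalue(q, lambda, exact = exact))
}

#' Kernel (variance-component) association test for one gene
#'
#' @param null An `endo_null` from [fit_null()].
#' @param g Genotype dosage matrix (samples x variants) for the gene's
#'   selected variants; missing entries are mean-imputed, monomorphic
#'   columns dropped.
#' @param weights Per-variant weights; defaults to the Beta(1, 25) density
#'   at the internal minor-allele frequency.
#' @param rho Burden-kernel correlation in \[0, 1\]: 0 is the pure
#'   variance-component (SKAT) kernel, 1 the pure weighted-burden kernel.
#' @param exact Use characteristic-function inversion instead of the
#'   four-moment approximation.
#' @param gene_id Label carried into the result.
#' @return One-row tibble: gene_id, Q, p, rho, n_variants, n, method; a
#'   gene with no polymorphic variant returns p `NA` with a `skipped`
#'   reason.
#' @export
kernel_test <- function(null, g, weights = NULL, rho = 0, exact = FALSE,
                        gene_id = NA_character_) {
  comp <- kernel_components(null, g, weights)
  if (is.null(comp)) {
    return(tibble::tibble(gene_id = gene_id, Q = NA_real_, p = NA_real_,
                          rho = rho, n_variants = 0L, n = null$n,
                          method = "kernel", skipped = "monomorphic"))
  }
  res <- kernel_p_from_components(comp$score, comp$info, rho, exact = exact)
  tibble::tibble(gene_id = gene_id, Q = res$q, p = res$p, rho = rho,
                 n_variants = comp$m, n = null$n, method = "kernel",
                 skipped = NA_character_)
}

# SKAT-O small helpers ------------------------------------------------------

optimal_null_params <- function(phi) {
  m <- ncol(phi)
  one_phi <- as.vector(phi %*% rep(1, m))
  s_total <- sum(one_phi)
  szm <- s_total / m^2                       # sum(z_mean^2)
  cof1 <- m * one_phi / s_total
  phi2 <- phi - szm * tcrossprod(cof1)
  lambda <- eigen(phi2, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(abs(lambda)) * 1e-10]
  var_item <- 4 * szm * as.numeric(t(cof1) %*% phi2 %*% cof1)
  mu_q <- sum(lambda)
  var_q <- 2 * sum(lambda^2) + var_item
  df <- sum(lambda^2)^2 / sum(lambda^4)
  tau <- function(rho) (m^2 * rho + (1 - rho) * sum(cof1^2)) * szm
  list(lambda = lambda, mu_q = mu_q, var_q = var_q, df = df, tau = tau,
       m = m)
}

#' Optimal burden/kernel combination test (SKAT-O style)
#'
#' Computes the kernel p-value over the rho grid
#' `{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1}` and combines them through the
#' null distribution of the minimum p, evaluated by one-dimensional
#' integration over the shared burden component. The combined p is capped at
#' the Bonferroni bound `min p x grid size`.
#'
#' @inheritParams kernel_test
#' @param rho_grid Grid of rho values.
#' @return One-row tibble as [kernel_test()], with `rho` the grid optimum.
#' @export
optimal_kernel_test <- function(null, g, weights = NULL,
                                rho_grid = KERNEL_RHO_GRID,
                                gene_id = NA_character_) {
  comp <- kernel_components(null, g, weights)
  if (is.null(comp)) {
    return(tibble::tibble(gene_id = gene_id, Q = NA_real_, p = NA_real_,
                          rho = NA_real_, n_variants = 0L, n = null$n,
                          method = "optimal", skipped = "monomorphic"))
  }
  optimal_from_components(comp, rho_grid, gene_id, null$n)
}

optimal_from_components <- function(comp, rho_grid, gene_id, n) {
  if (comp$m == 1L) {
    res <- kernel_p_from_components(comp$score, comp$info, 0)
    return(tibble::tibble(gene_id = gene_id, Q = res$q, p = res$p,
                          rho = NA_real_, n_variants = 1L, n = n,
                          method = "optimal", skipped = NA_character_))
  }
  per_rho <- lapply(rho_grid, function(r) {
    kernel_p_from_components(comp$score, comp$info, r)
  })
  p_each <- vapply(per_rho, `[[`, numeric(1), "p")
  i_min <- which.min(p_each)
  p_min <- p_each[i_min]

  # integration grid substitutes 0.999 for rho = 1 (the burden end point is
  # singular in the conditional decomposition)
  grid2 <- ifelse(rho_grid >= 1, 0.999, rho_grid)
  par <- optimal_null_params(comp$info)
  qmin <- vapply(grid2, function(r) {
    liu_quantile(p_min, rho_eigenvalues(comp$info, r))
  }, numeric(1))
  taus <- vapply(grid2, par$tau, numeric(1))

  integrand <- function(x) {
    vapply(x, function(xx) {
      qq <- min((qmin - taus * xx) / (1 - grid2))
      z <- (qq - par$mu_q) / sqrt(par$var_q) * sqrt(2 * par$df) + par$df
      pchisq(z, df = par$df) * dchisq(xx, df = 1)
    }, numeric(1))
  }
  surv <- tryCatch(
    1 - integrate(integrand, 0, 40, subdivisions = 2000L,
                  rel.tol = 1e-8)$value,
    error = function(e) NA_real_)
  n_grid <- length(rho_grid)
  p <- if (is.na(surv) || surv <= 0) p_min * n_grid else surv
  p <- min(p, p_min * n_grid, 1)
  tibble::tibble(gene_id = gene_id,
                 Q = per_rho[[i_min]]$q, p = p, rho = rho_grid[i_min],
                 n_variants = comp$m, n = n, method = "optimal",
                 skipped = NA_character_)
}

#' Score components for meta-analysis pooling
#'
#' Per-cohort score vector and information matrix for one gene, the
#' sufficient statistics pooled by [meta_kernel_test()].
#'
#' @inheritParams kernel_test
#' @return List with `score`, `info`, `variant_ids`, `n`.
#' @export
kernel_score_components <- function(null, g, weights = NULL) {
  comp <- kernel_components(null, g, weights)
  if (is.null(comp)) return(NULL)
  list(score = comp$score, info = comp$info,
       variant_ids = comp$variant_ids, n = null$n)
}

#' Score-pooled kernel meta-analysis for one gene
#'
#' Homogeneous-effect pooling: per-cohort score vectors and information
#' matrices are aligned on the shared variant frame (variants absent from a
#' cohort contribute zero) and summed, then the kernel p-value is computed
#' from the pooled statistics.
#'
#' @param components List of per-cohort results from
#'   [kernel_score_components()] (NULL entries are dropped).
#' @param rho Fixed rho, or `"optimal"` for the grid-combined test.
#' @param gene_id Label carried into the result.
#' @return One-row tibble as [kernel_test()].
#' @export
meta_kernel_test <- function(components, rho = 0, gene_id = NA_character_) {
  components <- components[!vapply(components, is.null, logical(1))]
  if (!length(components)) abort_endo("no cohort contributes information")
  frames <- lapply(components, `[[`, "variant_ids")
  all_ids <- unique(unlist(frames))
  if (any(vapply(frames, function(f) !all(f %in% all_ids), logical(1)))) {
    abort_endo("variant coordinate frames do not match")
  }
  k <- length(all_ids)
  score <- rep(0, k)
  info <- matrix(0, k, k)
  n_tot <- 0L
  for (cmp in components) {
    idx <- match(cmp$variant_ids, all_ids)
    score[idx] <- score[idx] + cmp$score
    info[idx, idx] <- info[idx, idx] + cmp$info
    n_tot <- n_tot + cmp$n
  }
  comp <- list(score = score, info = info, m = k)
  if (identical(rho, "optimal")) {
    out <- optimal_from_components(comp, KERNEL_RHO_GRID, gene_id, n_tot)
    out$method <- "meta-optimal"
    return(out)
  }
  res <- kernel_p_from_components(score, info, rho)
  tibble::tibble(gene_id = gene_id, Q = res$q, p = res$p, rho = rho,
                 n_variants = k, n = n_tot, method = "meta-kernel",
                 skipped = NA_character_)
}

#' Per-gene kernel scan with Bonferroni threshold
#'
#' Runs the kernel test for every gene with at least one polymorphic
#' selected variant and at least `min_carriers` carriers, and attaches the
#' Bonferroni threshold alpha / (genes tested).
#'
#' @param null An `endo_null`.
#' @param dosage Samples x variants dosage matrix.
#' @param selected Selection tibble (`variant_id`, `gene_id`, `weight`).
#' @param alpha Family-wise alpha (default 0.05).
#' @param method `"optimal"` or `"skat"` (rho = 0).
#' @param min_carriers Minimum carriers for a gene to be tested (default 2).
#' @return Tibble of per-gene results; the threshold and number of genes
#'   tested are in attributes `bonferroni` and `n_genes_tested`.
#' @export
per_gene_scan <- function(null, dosage, selected, alpha = 0.05,
                          method = c("optimal", "skat"), min_carriers = 2L) {
  method <- match.arg(method)
  genes <- split(selected, selected$gene_id)
  rows <- purrr::map(genes, function(sel) {
    g <- dosage[, sel$variant_id, drop = FALSE]
    carriers <- sum(rowSums(g > 0, na.rm = TRUE) > 0)
    if (carriers < min_carriers) return(NULL)
    if (method == "optimal") {
      optimal_kernel_test(null, g, gene_id = sel$gene_id[1])
    } else {
      kernel_test(null, g, gene_id = sel$gene_id[1])
    }
  })
  out <- dplyr::bind_rows(rows)
  out <- out[!is.na(out$p), , drop = FALSE]
  attr(out, "n_genes_tested") <- nrow(out)
  attr(out, "bonferroni") <- bonferroni_threshold(alpha, max(nrow(out), 1L))
  out
}
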