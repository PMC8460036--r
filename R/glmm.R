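# Kinship-aware logistic mixed model, fitted by penalized quasi-likelihood
# with a single variance component. Deterministic and adequate at cohort
# scale; with a zero kinship matrix it reduces exactly to ordinary IRLS and
# so matches glm().

#' Logistic burden test with a kinship random effect
#'
#' Logistic mixed model with random-effect covariance `tau * (2 * kinship)`,
#' fitted by penalized quasi-likelihood: an IRLS outer loop whose working
#' linear mixed model is solved with the variance component estimated by
#' REML (profiled over `tau` each iteration). Wald SE/p from the fixed-
#' effects information at convergence. Non-PSD kinship matrices are repaired
#' to the nearest PSD matrix (eigenvalue clipping) with a warning.
#'
#' @inheritParams logistic_burden_test
#' @param kinship Square kinship matrix with sample-id dimnames.
#' @param max_iter,tol PQL outer-loop controls.
#' @return One-row association tibble (estimate = log OR), with `tau`
#'   attached as a column.
#' @export
glmm_burden_test <- function(data, kinship, model = "M2",
                             burden_col = "residual",
                             covariates = NULL,
                             phenotype = "ad",
                             max_iter = 50L, tol = 1e-7) {
  covariates <- covariates %||% model_covariates(model)
  dat <- data[data$status %in% c("case", "control"), , drop = FALSE]
  des <- build_design(dat, burden_col, covariates)
  des$df$y <- as.integer(dat$status == "case")
  cc <- complete.cases(des$df)
  des$df <- des$df[cc, , drop = FALSE]
  ids <- dat$sample_id[cc]
  check_burden_varies(des$df$burden)
  if (!all(ids %in% rownames(kinship))) {
    abort_endo("kinship matrix does not cover all samples")
  }
  sigma <- 2 * kinship[ids, ids]
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    warn("kinship matrix not positive semi-definite; clipping eigenvalues")
    sigma <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  }
  x <- model.matrix(as.formula(paste("~", des$formula_rhs)), des$df)
  y <- des$df$y
  n <- length(y)
  zero_sigma <- all(abs(sigma) < 1e-12)

  eta <- qlogis(pmin(pmax((y + 0.5) / 2, 0.02), 0.98))
  beta_old <- rep(Inf, ncol(x))
  tau <- 0
  cov_beta <- NULL
  for (it in seq_len(max_iter)) {
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    if (zero_sigma) {
      vinv <- diag(w)
      tau <- 0
    } else {
      reml <- function(tau) {
        v <- sigma * tau
        diag(v) <- diag(v) + 1 / w
        ch <- chol(v)
        vi_x <- backsolve(ch, forwardsolve(t(ch), x))
        vi_z <- backsolve(ch, forwardsolve(t(ch), z))
        xtvx <- crossprod(x, vi_x)
        b <- solve(xtvx, crossprod(x, vi_z))
        r <- z - x %*% b
        vi_r <- backsolve(ch, forwardsolve(t(ch), r))
        -(2 * sum(log(diag(ch))) + determinant(xtvx)$modulus[1] +
            sum(r * vi_r)) / 2
      }
      tau <- optimize(reml, c(1e-8, 5), maximum = TRUE)$maximum
      v <- sigma * tau
      diag(v) <- diag(v) + 1 / w
      vinv <- chol2inv(chol(v))
    }
    xtvx <- crossprod(x, vinv %*% x)
    cov_beta <- solve(xtvx)
    beta <- cov_beta %*% crossprod(x, vinv %*% z)
    resid <- z - x %*% beta
    b_hat <- if (zero_sigma) rep(0, n) else tau * sigma %*% (vinv %*% resid)
    eta <- as.vector(x %*% beta + b_hat)
    if (max(abs(beta - beta_old)) < tol) break
    beta_old <- beta
  }
  est <- beta[colnames(x) == "burden"]
  se <- sqrt(cov_beta[colnames(x) == "burden", colnames(x) == "burden"])
  out <- new_assoc_result(model, est, se, wald_p(est, se), n, phenotype,
                          "log_or")
  out$tau <- tau
  out
}
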