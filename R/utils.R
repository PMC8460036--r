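# internal helpers shared across modules

# stop with a consistent error class so callers can test on it
abort_endo <- function(msg, class = "endoburden_error") {
  rlang::abort(msg, class = class)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_endo(sprintf("`%s` must be a single proportion in [0, 1]", name))
  }
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    (x > 0 || (!positive && x >= 0))
  if (!ok) {
    abort_endo(sprintf("`%s` must be a %s integer",
                       name, if (positive) "positive" else "non-negative"),
               class = "endoburden_config_error")
  }
  invisible(as.integer(x))
}

# dosage matrices are base numeric matrices, samples x variants, NA = missing
assert_dosage <- function(geno) {
  if (!is.matrix(geno) || !is.numeric(geno)) {
    abort_endo("genotypes must be a numeric matrix (samples x variants)")
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    abort_endo("dosages must be 0, 1, 2 or NA")
  }
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    abort_endo("genotype matrix needs sample rownames and variant colnames")
  }
  invisible(geno)
}

# two-sided Wald p from estimate and SE
wald_p <- function(estimate, se) {
  2 * pnorm(-abs(estimate / se))
}

new_assoc_result <- function(model, estimate, se, p, n, phenotype,
                             effect = c("log_or", "log_hr")) {
  effect <- match.arg(effect)
  tibble::tibble(
    phenotype = phenotype,
    model     = model,
    estimate  = estimate,
    se        = se,
    ratio     = exp(estimate),
    p         = p,
    direction = sign(estimate),
    n         = as.integer(n),
    effect    = effect
  )
}
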