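# Shared fixture builders: everything is constructed in code at test time.

## A small well-formed summary-statistics data frame.
make_sumstats <- function(variant_id = c("rs1", "rs2", "rs3"),
                          effect_allele = c("A", "C", "T"),
                          other_allele = c("G", "T", "C"),
                          beta = c(0.10, -0.05, 0.20),
                          se = c(0.02, 0.03, 0.04),
                          eaf = c(0.30, 0.10, 0.45),
                          pos = c(1e6, 2e6, 3e6),
                          n = 2223) {
  k <- length(variant_id)
  data.frame(
    variant_id = variant_id, chrom = "1", pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se,
    pvalue = 2 * pnorm(-abs(beta / se)), n = n,
    stringsAsFactors = FALSE
  )
}

## Random harmonized-pairs table (already aligned) for estimator tests.
random_pairs <- function(k, beta_xy = 0.3, pleiotropy = 0) {
  xb <- runif(k, 0.1, 0.6)
  xse <- runif(k, 0.01, 0.05)
  ose <- runif(k, 0.02, 0.08)
  yb <- beta_xy * xb + rep_len(pleiotropy, k) + rnorm(k, 0, ose)
  data.frame(
    variant_id = sprintf("rs%03d", seq_len(k)),
    effect_allele = "A", other_allele = "G",
    exposure_beta = xb, exposure_se = xse, exposure_eaf = 0.3,
    outcome_beta = yb, outcome_se = ose, outcome_eaf = 0.3,
    action = "kept", stringsAsFactors = FALSE
  )
}

## Explicit pairs table from vectors.
pairs_from <- function(xb, ob, xse = rep(0.02, length(xb)),
                       ose = rep(0.02, length(ob))) {
  data.frame(
    variant_id = sprintf("rs%03d", seq_along(xb)),
    effect_allele = "A", other_allele = "G",
    exposure_beta = xb, exposure_se = xse, exposure_eaf = 0.3,
    outcome_beta = ob, outcome_se = ose, outcome_eaf = 0.3,
    action = "kept", stringsAsFactors = FALSE
  )
}

## Independent closed-form WLS oracle (normal equations, no lm):
## returns coefficients of y ~ [1] + x with weights w.
wls_oracle <- function(x, y, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  XtWX <- t(X) %*% (w * X)
  unname(drop(solve(XtWX, t(X) %*% (w * y))))
}
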