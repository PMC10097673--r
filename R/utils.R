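# Internal helpers shared across modules.

#' micromr: two-sample Mendelian randomization for gut microbial traits
#'
#' Summary-statistics harmonization, instrument grading, pleiotropy-robust
#' causal estimators, approximate-Bayes-factor colocalisation, an offline
#' pleiotropy screen, and a synthetic-data generator with known ground
#' truth, organised as a desk-scale pipeline for microbiome-to-disease
#' Mendelian randomization studies.
#'
#' @keywords internal
"_PACKAGE"

## Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Two-sided normal p-value for z = beta/se.
z_pvalue <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

stop_usage <- function(...) stop(..., call. = FALSE)

## Run `expr` with the RNG seeded to `seed` (if non-NULL), restoring the
## caller's RNG state afterwards so seeded bootstraps do not perturb
## surrounding simulations.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Draw one multivariate-normal vector N(mu, Sigma) from a pre-computed
## upper Cholesky factor (chol(Sigma)).
rmvnorm_chol <- function(mu, chol_upper) {
  drop(mu + crossprod(chol_upper, stats::rnorm(nrow(chol_upper))))
}
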