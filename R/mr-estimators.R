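# Causal estimators and diagnostics: Wald ratio, fixed-effects IVW,
# MR-Egger, weighted median, weighted mode, Cochran's Q, leave-one-out,
# and scale conversions to odds ratios.

#' @keywords internal
new_mr_estimate <- function(method, beta, se, n_snp,
                            pvalue = NULL, df = NULL,
                            exposure_unit = "per_SD", extras = list()) {
  ## p-values use the normal reference unless a t df is supplied
  ## (MR-Egger, where two parameters are estimated).
  if (is.null(pvalue)) {
    pvalue <- if (is.null(df)) z_pvalue(beta, se)
      else 2 * stats::pt(-abs(beta / se), df = df)
  }
  est <- c(list(method = method, beta = beta, se = se,
                ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                pvalue = pvalue, n_snp = n_snp,
                exposure_unit = exposure_unit),
           extras)
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  or <- to_odds_ratio(x)
  cat(sprintf(
    "<mr_estimate> %s (%d SNP%s, %s)\n  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n  OR = %.3f (%.3f, %.3f)\n",
    x$method, x$n_snp, if (x$n_snp > 1) "s" else "", x$exposure_unit,
    x$beta, x$se, x$ci_low, x$ci_high, x$pvalue,
    or[["or"]], or[["or_low"]], or[["or_high"]]))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  if (!is.null(x$q_stat))
    cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n",
                x$q_stat, x$q_df, x$q_p))
  invisible(x)
}

## Drop `dropped_*` rows and check the minimum pair count.
prepare_pairs <- function(pairs, min_n, caller) {
  pairs <- kept_pairs(pairs)
  if (nrow(pairs) < min_n)
    stop_usage(caller, " requires >= ", min_n, " non-dropped pairs (got ",
               nrow(pairs), ")")
  pairs
}

## Per-SNP ratio estimates and their first-order inverse-variance weights.
ratio_components <- function(pairs) {
  if (any(pairs$exposure_beta == 0))
    stop_usage("exposure beta of 0: ratio estimate undefined")
  list(ratio = pairs$outcome_beta / pairs$exposure_beta,
       se = pairs$outcome_se / abs(pairs$exposure_beta),
       w = pairs$exposure_beta^2 / pairs$outcome_se^2)
}

#' Wald ratio estimate from a single harmonized pair
#'
#' The single-SNP causal estimate: SNP-outcome beta divided by
#' SNP-exposure beta, with the first-order (delta-method) standard error
#' `outcome_se / |exposure_beta|` and a normal 95% CI.
#'
#' @param pairs Harmonized-pairs data frame containing exactly one
#'   non-dropped pair.
#' @param exposure_type `"continuous"` (per-SD estimate) or `"binary"`
#'   (per log-odds of presence; convert with [scale_binary_exposure()]).
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(pairs, exposure_type = c("continuous", "binary")) {
  exposure_type <- match.arg(exposure_type)
  pairs <- prepare_pairs(pairs, 1L, "wald_ratio")
  if (nrow(pairs) != 1L)
    stop_usage("wald_ratio takes exactly one pair; use mr_ivw for several")
  rc <- ratio_components(pairs)
  new_mr_estimate("wald_ratio", rc$ratio, rc$se, 1L,
                  exposure_unit = if (exposure_type == "binary")
                    "per_log_odds" else "per_SD")
}

#' Inverse-variance weighted estimate
#'
#' Fixed-effects IVW: the slope of a zero-intercept regression of outcome
#' betas on exposure betas with weights `1/outcome_se^2`, standard error
#' `sqrt(1 / sum(w x^2))`. Equivalently a weighted average of per-SNP Wald
#' ratios. An optional multiplicative random-effects inflation (scaling
#' the SE by `max(1, sqrt(Q / (k - 1)))`) is available but off by default.
#'
#' @param pairs Harmonized pairs (>= 2 non-dropped).
#' @param random_effects Inflate the SE under heterogeneity (default
#'   `FALSE`, i.e. fixed effects).
#' @inheritParams wald_ratio
#' @return An `mr_estimate` with Cochran's Q fields attached.
#' @export
mr_ivw <- function(pairs, random_effects = FALSE,
                   exposure_type = c("continuous", "binary")) {
  exposure_type <- match.arg(exposure_type)
  pairs <- prepare_pairs(pairs, 2L, "mr_ivw")
  x <- pairs$exposure_beta
  y <- pairs$outcome_beta
  w <- 1 / pairs$outcome_se^2
  beta <- sum(w * x * y) / sum(w * x^2)
  se <- sqrt(1 / sum(w * x^2))
  q <- cochrans_q_stat(pairs, beta)
  if (random_effects) se <- se * max(1, sqrt(q$q_stat / q$q_df))
  new_mr_estimate("ivw", beta, se, nrow(pairs),
                  exposure_unit = if (exposure_type == "binary")
                    "per_log_odds" else "per_SD",
                  extras = q)
}

#' MR-Egger regression
#'
#' Weighted (`1/outcome_se^2`) straight-line fit of outcome betas on
#' exposure betas with a free intercept. Exposure betas are oriented
#' non-negative first (flipping the matching outcome betas), which the
#' estimator requires for identification. The slope is the causal
#' estimate; the intercept with its standard error and two-sided p-value
#' (t reference, `k - 2` df) is the test for directional horizontal
#' pleiotropy.
#'
#' @param pairs Harmonized pairs (>= 3 non-dropped).
#' @inheritParams wald_ratio
#' @return An `mr_estimate` with `egger_intercept*` fields.
#' @export
mr_egger <- function(pairs, exposure_type = c("continuous", "binary")) {
  exposure_type <- match.arg(exposure_type)
  pairs <- prepare_pairs(pairs, 3L, "mr_egger")
  flip <- sign(pairs$exposure_beta)
  flip[flip == 0] <- 1
  x <- pairs$exposure_beta * flip
  y <- pairs$outcome_beta * flip
  w <- 1 / pairs$outcome_se^2
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)$coefficients
  df <- nrow(pairs) - 2L
  new_mr_estimate(
    "egger", sm["x", "Estimate"], sm["x", "Std. Error"], nrow(pairs),
    df = df,
    exposure_unit = if (exposure_type == "binary") "per_log_odds" else "per_SD",
    extras = list(
      egger_intercept = sm["(Intercept)", "Estimate"],
      egger_intercept_se = sm["(Intercept)", "Std. Error"],
      egger_intercept_p = 2 * stats::pt(
        -abs(sm["(Intercept)", "t value"]), df = df)
    )
  )
}

## Weighted-median point estimate on per-SNP ratios: the value at
## cumulative normalized weight 0.5, linearly interpolated.
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  b <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(cum)] <= 0.5) return(b[length(b)])
  below <- max(which(cum < 0.5))
  b[below] + (b[below + 1] - b[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

#' Weighted-median estimate
#'
#' Consistent when at least half the total instrument weight comes from
#' valid instruments. Per-SNP ratio estimates are ordered and the estimate
#' is the value at cumulative normalized inverse-variance weight 0.5 with
#' linear interpolation; with equal weights this is the sample median of
#' the ratios. The standard error comes from a seeded parametric bootstrap
#' (per-SNP betas resampled from `N(beta, se^2)`).
#'
#' @param pairs Harmonized pairs (>= 3 non-dropped).
#' @param n_boot Bootstrap draws for the SE (default 5000).
#' @param seed Seed for the bootstrap (RNG state is restored afterwards).
#' @inheritParams wald_ratio
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(pairs, n_boot = 5000, seed = NULL,
                            exposure_type = c("continuous", "binary")) {
  exposure_type <- match.arg(exposure_type)
  pairs <- prepare_pairs(pairs, 3L, "weighted_median")
  rc <- ratio_components(pairs)
  beta <- weighted_median_point(rc$ratio, rc$w)
  se <- bootstrap_se(pairs, n_boot, seed, function(p) {
    r <- ratio_components(p)
    weighted_median_point(r$ratio, r$w)
  })
  new_mr_estimate("weighted_median", beta, se, nrow(pairs),
                  exposure_unit = if (exposure_type == "binary")
                    "per_log_odds" else "per_SD")
}

## Modified Silverman bandwidth on the ratio estimates.
mode_bandwidth <- function(ratios, phi) {
  s <- stats::sd(ratios)
  m <- stats::mad(ratios)
  scale <- if (m > 0) min(s, m) else s
  phi * 0.9 * scale / length(ratios)^0.2
}

## Maximizer of the weighted gaussian kernel density over a fine grid.
weighted_mode_point <- function(ratios, weights, phi) {
  if (max(ratios) - min(ratios) < .Machine$double.eps^0.5)
    return(ratios[1])
  h <- mode_bandwidth(ratios, phi)
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 1024L)
  dens <- vapply(grid, function(g)
    sum(weights * stats::dnorm(g, mean = ratios, sd = h)), numeric(1))
  grid[which.max(dens)]
}

#' Weighted-mode estimate
#'
#' Clusters SNPs by similarity of their ratio estimates and returns the
#' effect of the largest (inverse-variance weighted) cluster: the
#' maximizer of a weighted gaussian kernel density over per-SNP ratios,
#' with bandwidth `phi` times a modified Silverman rule. SE by seeded
#' parametric bootstrap.
#'
#' @param pairs Harmonized pairs (>= 3 non-dropped).
#' @param phi Bandwidth inflation factor (default 1).
#' @inheritParams weighted_median
#' @return An `mr_estimate`.
#' @export
weighted_mode <- function(pairs, phi = 1, n_boot = 5000, seed = NULL,
                          exposure_type = c("continuous", "binary")) {
  exposure_type <- match.arg(exposure_type)
  pairs <- prepare_pairs(pairs, 3L, "weighted_mode")
  rc <- ratio_components(pairs)
  beta <- weighted_mode_point(rc$ratio, rc$w, phi)
  se <- bootstrap_se(pairs, n_boot, seed, function(p) {
    r <- ratio_components(p)
    weighted_mode_point(r$ratio, r$w, phi)
  })
  new_mr_estimate("weighted_mode", beta, se, nrow(pairs),
                  exposure_unit = if (exposure_type == "binary")
                    "per_log_odds" else "per_SD")
}

## Parametric bootstrap over per-SNP betas; returns the SD of the
## re-estimated statistic.
bootstrap_se <- function(pairs, n_boot, seed, statistic) {
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      b <- pairs
      b$exposure_beta <- stats::rnorm(nrow(b), pairs$exposure_beta,
                                      pairs$exposure_se)
      b$outcome_beta <- stats::rnorm(nrow(b), pairs$outcome_beta,
                                     pairs$outcome_se)
      statistic(b)
    }, numeric(1))
    stats::sd(reps)
  })
}

## Q statistic about a reference slope, first-order ratio weights.
cochrans_q_stat <- function(pairs, beta_ref) {
  rc <- ratio_components(pairs)
  q <- sum(rc$w * (rc$ratio - beta_ref)^2)
  df <- nrow(pairs) - 1L
  list(q_stat = q, q_df = df,
       q_p = stats::pchisq(q, df = df, lower.tail = FALSE))
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_i w_i (b_i - b_{ref})^2} over per-SNP ratio estimates
#' `b_i` with first-order inverse-variance weights
#' `w_i = exposure_beta^2 / outcome_se^2`, referred to a chi-square with
#' `k - 1` df.
#'
#' @param pairs Harmonized pairs (>= 2 non-dropped).
#' @param reference Reference estimate: an `mr_estimate` or a number;
#'   defaults to the fixed-effects IVW slope.
#' @return List with `q_stat`, `q_df`, `q_p`.
#' @export
cochrans_q <- function(pairs, reference = NULL) {
  pairs <- prepare_pairs(pairs, 2L, "cochrans_q")
  beta_ref <- if (is.null(reference)) mr_ivw(pairs)$beta
    else if (inherits(reference, "mr_estimate")) reference$beta
    else as.numeric(reference)
  cochrans_q_stat(pairs, beta_ref)
}

#' Leave-one-out analysis
#'
#' Repeats the IVW estimate omitting each SNP in turn (Wald ratio when
#' only one SNP remains), plus the all-SNP estimate, as a plot-ready
#' table.
#'
#' @param pairs Harmonized pairs (>= 3 non-dropped).
#' @return Data frame with one row per omitted variant plus a final
#'   `"(none)"` row for the full set.
#' @export
leave_one_out <- function(pairs) {
  pairs <- prepare_pairs(pairs, 3L, "leave_one_out")
  one <- function(p) {
    est <- if (nrow(p) == 1L) wald_ratio(p) else mr_ivw(p)
    data.frame(beta = est$beta, se = est$se, ci_low = est$ci_low,
               ci_high = est$ci_high, pvalue = est$pvalue,
               n_snp = est$n_snp)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i)
    cbind(omitted = pairs$variant_id[i], one(pairs[-i, , drop = FALSE])))
  rows <- c(rows, list(cbind(omitted = "(none)", one(pairs))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rescale a binary-exposure estimate to a doubling of liability
#'
#' Presence/absence exposures are estimated per unit of log-odds of
#' presence; multiplying beta and SE by `ln 2` re-expresses the effect per
#' approximate doubling of the genetic liability to presence, the unit
#' used for reporting P/A traits. CI and p-value are recomputed.
#'
#' @param est An `mr_estimate` with `exposure_unit = "per_log_odds"`.
#' @return The rescaled `mr_estimate`
#'   (`exposure_unit = "per_doubling_liability"`).
#' @export
scale_binary_exposure <- function(est) {
  if (!inherits(est, "mr_estimate")) stop_usage("est must be an mr_estimate")
  if (!identical(est$exposure_unit, "per_log_odds"))
    stop_usage("scale_binary_exposure applies only to binary (P/A) ",
               "exposures on the per-log-odds scale")
  est$beta <- est$beta * log(2)
  est$se <- est$se * log(2)
  est$ci_low <- est$beta - 1.96 * est$se
  est$ci_high <- est$beta + 1.96 * est$se
  est$pvalue <- z_pvalue(est$beta, est$se)
  est$exposure_unit <- "per_doubling_liability"
  est
}

#' Odds-ratio presentation of an estimate
#'
#' @param est An `mr_estimate` (outcome on the log-OR scale).
#' @return Named numeric vector `or`, `or_low`, `or_high`.
#' @export
to_odds_ratio <- function(est) {
  c(or = exp(est$beta), or_low = exp(est$ci_low), or_high = exp(est$ci_high))
}
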