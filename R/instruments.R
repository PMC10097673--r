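# Instrument selection and grading: p-value thresholds, cross-cohort
# fixed-effects meta-analysis with the "meta-supported" rule, directional
# consistency across cohorts, greedy LD clumping, variance explained on the
# observed and liability scales, F-statistics, and binary-outcome power.

#' Construct an instrument set
#'
#' Light container recording which variants instrument a trait, under what
#' selection threshold and mode.
#'
#' @param variant_ids Character vector (ordered).
#' @param trait_id Trait identifier (or `NA`).
#' @param selection_threshold P-value threshold that was applied.
#' @param selection_mode One of `"genome_wide"`, `"lenient_consistent"`,
#'   `"literature"`.
#' @return An object of class `instrument_set`.
#' @export
instrument_set <- function(variant_ids, trait_id = NA_character_,
                           selection_threshold = NA_real_,
                           selection_mode = c("genome_wide",
                                              "lenient_consistent",
                                              "literature")) {
  structure(
    list(trait_id = trait_id,
         variant_ids = as.character(variant_ids),
         selection_threshold = selection_threshold,
         selection_mode = match.arg(selection_mode),
         k = length(variant_ids)),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> trait=%s mode=%s threshold=%g k=%d\n",
              x$trait_id, x$selection_mode, x$selection_threshold, x$k))
  if (x$k) cat("  ", paste(utils::head(x$variant_ids, 10), collapse = ", "),
               if (x$k > 10) "..." else "", "\n")
  invisible(x)
}

#' Select instruments by p-value threshold
#'
#' Keeps variants with `pvalue` strictly below `threshold`, sorted by
#' ascending p-value with ties broken by variant id. The genome-wide
#' microbiome meta-analysis threshold used for the main analysis is
#' 2.5e-8; the lenient sensitivity threshold is 1e-5.
#'
#' @param assocs Summary-statistics data frame for a single trait.
#' @param threshold P-value threshold (strict `<`).
#' @param selection_mode Recorded on the returned set.
#' @return An [instrument_set()] (possibly empty).
#' @export
select_by_threshold <- function(assocs, threshold = 2.5e-8,
                                selection_mode = "genome_wide") {
  keep <- assocs[assocs$pvalue < threshold, , drop = FALSE]
  ord <- order(keep$pvalue, keep$variant_id)
  instrument_set(keep$variant_id[ord],
                 trait_id = if (!is.null(assocs$trait_id) && nrow(assocs))
                   assocs$trait_id[1] else NA_character_,
                 selection_threshold = threshold,
                 selection_mode = selection_mode)
}

#' Inverse-variance fixed-effects meta-analysis across cohorts
#'
#' Combines per-cohort betas for one variant with weights `1/se^2`. The
#' first cohort is the discovery cohort; the variant is "meta-supported"
#' when the meta-analysis p-value is smaller than the discovery p-value
#' (two-sided normal p from z = beta/se in both cases).
#'
#' @param betas,ses Numeric vectors, one entry per cohort (>= 2 cohorts),
#'   harmonized to a shared effect allele.
#' @return List with `beta`, `se`, `pvalue`, `meta_supported`.
#' @export
fixed_effects_meta <- function(betas, ses) {
  if (length(betas) < 2L || length(betas) != length(ses))
    stop_usage("fixed_effects_meta needs >= 2 cohorts with matching betas/ses")
  if (any(is.na(betas)) || any(is.na(ses)) || any(ses <= 0))
    stop_usage("betas/ses must be non-missing with positive ses")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  p <- z_pvalue(beta, se)
  list(beta = beta, se = se, pvalue = p,
       meta_supported = p < z_pvalue(betas[1], ses[1]))
}

#' Filter lenient instruments by cross-cohort directional consistency
#'
#' Keeps variants whose fixed-effects meta-analysis p-value is below the
#' lenient threshold and whose per-cohort effect estimates share one sign
#' in every cohort. Variants with a missing cohort beta are excluded with a
#' message.
#'
#' @param betas,ses Numeric matrices (variants x cohorts) with rownames set
#'   to variant ids; column 1 is the discovery cohort.
#' @param lenient_threshold Meta-analysis p-value ceiling (default 1e-5).
#' @param trait_id Recorded on the returned set.
#' @return An [instrument_set()] with mode `"lenient_consistent"`, ordered
#'   by ascending meta p-value (ties by variant id).
#' @export
directional_consistency_filter <- function(betas, ses,
                                           lenient_threshold = 1e-5,
                                           trait_id = NA_character_) {
  betas <- as.matrix(betas)
  ses <- as.matrix(ses)
  if (is.null(rownames(betas))) stop_usage("betas must have variant rownames")
  complete <- stats::complete.cases(betas) & stats::complete.cases(ses)
  if (any(!complete)) {
    message("excluding ", sum(!complete),
            " variant(s) with missing cohort estimates: ",
            paste(rownames(betas)[!complete], collapse = ", "))
  }
  ids <- character(0)
  metap <- numeric(0)
  for (i in which(complete)) {
    m <- fixed_effects_meta(betas[i, ], ses[i, ])
    consistent <- length(unique(sign(betas[i, ]))) == 1L &&
      all(sign(betas[i, ]) != 0)
    if (consistent && m$pvalue < lenient_threshold) {
      ids <- c(ids, rownames(betas)[i])
      metap <- c(metap, m$pvalue)
    }
  }
  ord <- order(metap, ids)
  instrument_set(ids[ord], trait_id = trait_id,
                 selection_threshold = lenient_threshold,
                 selection_mode = "lenient_consistent")
}

#' Greedy LD clumping
#'
#' Iterates variants in ascending p-value order (ties broken by variant id)
#' and keeps a variant iff its squared correlation with every
#' already-kept variant within `window_bp` base pairs is at most
#' `r2_threshold`. With `r2_threshold = 0.001` this reproduces the
#' stringent clumping used to pick approximately independent disease
#' instruments for reverse MR.
#'
#' @param assocs Summary-statistics data frame with `variant_id`, `pvalue`
#'   and (optionally) `pos`; without positions every pair is treated as
#'   within-window.
#' @param ld Square correlation matrix, unit diagonal, with
#'   dimnames matching `assocs$variant_id` (any order).
#' @param r2_threshold Maximum allowed squared correlation (default 0.001).
#' @param window_bp Window half-width in base pairs (default 10 Mb).
#' @return An [instrument_set()] of retained variants.
#' @export
greedy_clump <- function(assocs, ld, r2_threshold = 0.001,
                         window_bp = 1e7) {
  ld <- as.matrix(ld)
  if (nrow(ld) != ncol(ld) || nrow(ld) != nrow(assocs))
    stop_usage("ld must be square and match the number of associations")
  if (is.null(rownames(ld))) {
    rownames(ld) <- colnames(ld) <- assocs$variant_id
  }
  if (!setequal(rownames(ld), assocs$variant_id))
    stop_usage("ld dimnames must match assocs variant ids")
  if (max(abs(ld - t(ld))) > 1e-8 || max(abs(diag(ld) - 1)) > 1e-8)
    stop_usage("ld must be symmetric with unit diagonal")
  ord <- order(assocs$pvalue, assocs$variant_id)
  ids <- assocs$variant_id[ord]
  pos <- if (is.null(assocs$pos)) rep(0, nrow(assocs)) else assocs$pos[ord]
  kept <- integer(0)
  for (i in seq_along(ids)) {
    ok <- TRUE
    for (j in kept) {
      if (abs(pos[i] - pos[j]) <= window_bp &&
          ld[ids[i], ids[j]]^2 > r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  instrument_set(ids[kept],
                 trait_id = if (!is.null(assocs$trait_id) && nrow(assocs))
                   assocs$trait_id[1] else NA_character_,
                 selection_threshold = NA_real_,
                 selection_mode = "genome_wide")
}

#' Variance explained by a variant in a continuous trait
#'
#' Observed-scale R-squared from summary statistics:
#' \deqn{R^2 = \frac{2\beta^2 q}{2\beta^2 q + se^2 \cdot 2N \cdot q}}
#' with \eqn{q = MAF(1 - MAF)}. Algebraically this equals
#' \eqn{z^2 / (z^2 + N)} with \eqn{z = \beta/se}; the MAF cancels but is
#' validated because the printed formula requires it.
#'
#' @param beta,se Per-allele effect and its standard error.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param n GWAS sample size (>= 2).
#' @return R-squared in `[0, 1)`.
#' @export
r2_continuous <- function(beta, se, maf, n) {
  if (any(maf <= 0) || any(maf > 0.5)) stop_usage("maf must be in (0, 0.5]")
  if (any(se <= 0)) stop_usage("se must be positive")
  if (any(n < 2)) stop_usage("n must be >= 2")
  q <- maf * (1 - maf)
  num <- 2 * beta^2 * q
  num / (num + se^2 * 2 * n * q)
}

#' Liability-scale variance explained for a binary (P/A) trait
#'
#' Converts a per-allele log odds ratio for trait presence to the latent
#' liability scale via the logistic-to-probit factor \eqn{\pi/\sqrt 3},
#' then returns the genotypic variance share
#' \eqn{v / (v + 1)} with \eqn{v = 2\,eaf(1-eaf)\,\beta_{liab}^2}.
#' This is a closed-form approximation to the threshold-liability model;
#' accuracy degrades at extreme prevalence (the logistic and probit links
#' diverge in the tails), which is why `prevalence` is validated and
#' recorded even though it does not enter the formula.
#'
#' @param log_odds_ratio Per-allele log-OR for presence vs absence.
#' @param eaf Effect-allele frequency in (0, 1).
#' @param prevalence Fraction of individuals with the taxon present, in
#'   (0, 1).
#' @return Liability-scale R-squared in `[0, 1)`.
#' @export
r2_liability_from_lor <- function(log_odds_ratio, eaf, prevalence) {
  if (any(prevalence <= 0) || any(prevalence >= 1))
    stop_usage("prevalence must be in (0, 1)")
  if (any(eaf <= 0) || any(eaf >= 1)) stop_usage("eaf must be in (0, 1)")
  beta_liab <- log_odds_ratio / (pi / sqrt(3))
  v <- 2 * eaf * (1 - eaf) * beta_liab^2
  v / (v + 1)
}

#' First-stage F-statistic
#'
#' \deqn{F = \frac{R^2 (N - 1 - k)}{(1 - R^2) k}}
#' where `k` is the number of variants in the instrument. Values above ~10
#' conventionally indicate low weak-instrument bias.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n GWAS sample size (must exceed `k + 1`).
#' @param k Number of instrument variants (default 1).
#' @return Non-negative F-statistic.
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0) || any(r2 >= 1)) stop_usage("r2 must be in [0, 1)")
  if (any(n <= k + 1)) stop_usage("n must exceed k + 1")
  r2 * (n - 1 - k) / ((1 - r2) * k)
}

#' Power of a two-sample MR analysis with a binary outcome
#'
#' Asymptotic approximation for the power to detect an odds ratio
#' `odds_ratio` per SD of exposure with an instrument explaining `r2` of
#' exposure variance:
#' \deqn{power = \Phi\!\left(|\ln OR|\sqrt{N R^2 K (1-K)} - z_{1-\alpha/2}\right)}
#' with `N = n_case + n_control` and case fraction `K`.
#'
#' @param r2 Instrument variance explained in (0, 1).
#' @param odds_ratio Detectable OR per SD of exposure (> 0).
#' @param n_case,n_control Case and control counts.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
mr_power_binary <- function(r2, odds_ratio, n_case, n_control,
                            alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_usage("alpha must be in (0, 1)")
  if (any(r2 <= 0) || any(r2 >= 1)) stop_usage("r2 must be in (0, 1)")
  if (any(odds_ratio <= 0)) stop_usage("odds_ratio must be positive")
  n <- n_case + n_control
  k <- n_case / n
  stats::pnorm(abs(log(odds_ratio)) * sqrt(n * r2 * k * (1 - k)) -
                 stats::qnorm(1 - alpha / 2))
}
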