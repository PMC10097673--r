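# Approximate-Bayes-factor colocalisation of a microbial-trait region with
# a disease region: per-variant Wakefield ABFs and posterior probabilities
# of hypotheses H0-H4, with all accumulation in log space.

#' Colocalisation priors and effect-size hyperparameters
#'
#' `p1`/`p2` are the prior probabilities that a variant associates with
#' trait 1 / trait 2, `p12` that it associates with both (defaults 1e-4,
#' 1e-4, 1e-5). `prior_sd_quant` is the prior SD of effects on a
#' quantitative trait per SD of the trait (0.15, so `0.15 * sd_y`);
#' `prior_sd_cc` is the prior SD of log-OR effects on a case-control trait
#' (0.2).
#'
#' @param p1,p2,p12 Prior probabilities; must satisfy `0 < p12 < p1, p2 < 1`.
#' @param prior_sd_quant,prior_sd_cc Prior effect SDs.
#' @return A `coloc_config` list.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd_quant = 0.15, prior_sd_cc = 0.2) {
  if (!(p12 > 0 && p12 < p1 && p12 < p2 && p1 < 1 && p2 < 1))
    stop_usage("priors must satisfy 0 < p12 < p1, p2 < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 prior_sd_quant = prior_sd_quant,
                 prior_sd_cc = prior_sd_cc),
            class = "coloc_config")
}

#' Wakefield log approximate Bayes factor
#'
#' For a variant with estimate `beta` and standard error `se` and a
#' normal prior with SD `prior_sd` on the true effect, the log-ABF of
#' association versus no association is
#' \deqn{\tfrac12\left[\log(1 - r) + r z^2\right]}
#' with \eqn{z = \beta/se} and
#' \eqn{r = prior\_sd^2 / (prior\_sd^2 + se^2)}.
#'
#' @param beta,se Estimate and standard error (`se > 0`); vectorized.
#' @param prior_sd Prior SD of the true effect.
#' @return Log approximate Bayes factor(s).
#' @export
approximate_bayes_factor <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop_usage("se must be positive")
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log1p(-r) + r * z^2)
}

#' Extract a harmonized two-trait region around a lead variant
#'
#' Takes the intersection of variants present in both summary files within
#' `window_bp` of the lead variant's position (window boundaries inclusive
#' at exactly +/- `window_bp`), harmonizes trait 2 to trait 1's effect
#' alleles via [harmonize()], and drops (with a message) variants that do
#' not harmonize.
#'
#' @param trait1,trait2 Summary-statistics data frames with `pos` columns;
#'   trait 1 must contain the lead variant.
#' @param lead_variant_id Lead variant id.
#' @param window_bp Window half-width in base pairs (default 1e6).
#' @param trait1_type,trait2_type `"quant"` or `"cc"` for each trait.
#' @param sd_y SD of trait 1 when quantitative (1 for rank-normalized
#'   microbial abundances).
#' @param case_fraction Case fraction of a case-control trait (optional,
#'   recorded for reporting).
#' @return A `coloc_region` with aligned per-variant (beta, se) for both
#'   traits.
#' @export
extract_region <- function(trait1, trait2, lead_variant_id,
                           window_bp = 1e6,
                           trait1_type = c("quant", "cc"),
                           trait2_type = c("cc", "quant"),
                           sd_y = 1, case_fraction = NULL) {
  trait1_type <- match.arg(trait1_type)
  trait2_type <- match.arg(trait2_type)
  if (!lead_variant_id %in% trait1$variant_id)
    stop_usage("lead variant '", lead_variant_id, "' absent from trait 1")
  if (is.null(trait1$pos) || is.null(trait2$pos))
    stop_usage("both summary tables need a 'pos' column")
  lead_pos <- trait1$pos[match(lead_variant_id, trait1$variant_id)]
  t1 <- trait1[abs(trait1$pos - lead_pos) <= window_bp, , drop = FALSE]
  t2 <- trait2[trait2$variant_id %in% t1$variant_id, , drop = FALSE]
  if (nrow(t2) == 0L) stop_usage("no shared variants in the region")
  pairs <- harmonize(t1, t2)
  dropped <- pairs$action %in% DROPPED_ACTIONS
  if (any(dropped)) {
    message("dropping ", sum(dropped), " variant(s) during region ",
            "harmonization: ", paste(pairs$variant_id[dropped],
                                     collapse = ", "))
  }
  pairs <- pairs[!dropped, , drop = FALSE]
  if (nrow(pairs) == 0L) stop_usage("no harmonizable variants in the region")
  if (!lead_variant_id %in% pairs$variant_id)
    message("lead variant did not harmonize; region retained without it")
  pairs$pos <- t1$pos[match(pairs$variant_id, t1$variant_id)]
  pairs <- pairs[order(pairs$pos, pairs$variant_id), , drop = FALSE]
  structure(
    list(lead_variant_id = lead_variant_id,
         window_bp = window_bp,
         variants = data.frame(
           variant_id = pairs$variant_id,
           pos = pairs$pos,
           beta1 = pairs$exposure_beta, se1 = pairs$exposure_se,
           beta2 = pairs$outcome_beta, se2 = pairs$outcome_se,
           stringsAsFactors = FALSE),
         trait1_type = trait1_type, trait2_type = trait2_type,
         sd_y = sd_y, case_fraction = case_fraction),
    class = "coloc_region"
  )
}

region_prior_sd <- function(type, config, sd_y = 1) {
  if (type == "quant") config$prior_sd_quant * sd_y else config$prior_sd_cc
}

#' Enumerate colocalisation posteriors H0-H4
#'
#' Computes per-variant log-ABFs for each trait and the posterior
#' probability of each hypothesis: (H0) neither trait associated in the
#' region; (H1) only trait 1; (H2) only trait 2; (H3) both associated with
#' different causal variants; (H4) both associated with the same causal
#' variant. Hypothesis sums are accumulated in log space
#' (`S3 = S1*S2 - S4`, clamped at zero with a warning if round-off makes
#' it negative). The region is declared colocalized when
#' `pp[H4] >= h4_threshold` (default 0.80).
#'
#' @param region A `coloc_region` from [extract_region()] (or a compatible
#'   list with a `variants` data frame).
#' @param config A [coloc_config()].
#' @param h4_threshold Posterior-probability threshold for the
#'   colocalisation verdict.
#' @return A `coloc_result` with `pp` (named H0..H4, summing to 1),
#'   `n_variants`, the config used and the verdict.
#' @export
coloc_abf <- function(region, config = coloc_config(), h4_threshold = 0.80) {
  v <- region$variants
  if (is.null(v) || nrow(v) < 1L) stop_usage("region has no variants")
  sd1 <- region_prior_sd(region$trait1_type, config,
                         if (is.null(region$sd_y)) 1 else region$sd_y)
  sd2 <- region_prior_sd(region$trait2_type, config,
                         if (is.null(region$sd_y)) 1 else region$sd_y)
  l1 <- approximate_bayes_factor(v$beta1, v$se1, sd1)
  l2 <- approximate_bayes_factor(v$beta2, v$se2, sd2)
  ls1 <- logsumexp(l1)                # log S1
  ls2 <- logsumexp(l2)                # log S2
  ls4 <- logsumexp(l1 + l2)           # log S4
  ## log S3 = log(S1*S2 - S4), guarded against negative round-off.
  d <- ls4 - (ls1 + ls2)
  if (d >= 0) {
    if (d > 1e-9) warning("S1*S2 < S4 beyond round-off; clamping S3 to 0",
                          call. = FALSE)
    ls3 <- -Inf
  } else {
    ls3 <- ls1 + ls2 + log1p(-exp(d))
  }
  lpost <- c(
    H0 = 0,
    H1 = log(config$p1) + ls1,
    H2 = log(config$p2) + ls2,
    H3 = log(config$p1) + log(config$p2) + ls3,
    H4 = log(config$p12) + ls4
  )
  lz <- logsumexp(lpost)
  pp <- exp(lpost - lz)
  structure(
    list(pp = pp, n_variants = nrow(v), config = config,
         h4_threshold = h4_threshold,
         colocalized = unname(pp["H4"]) >= h4_threshold),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d variants, PP(H4) threshold %.2f\n",
              x$n_variants, x$h4_threshold))
  print(round(x$pp, 4))
  cat(if (x$colocalized) "verdict: colocalized\n"
      else "verdict: not colocalized\n")
  invisible(x)
}

#' Plot-ready regional association table
#'
#' One row per region variant with position and `-log10(p)` for both
#' traits (recomputed from z = beta/se) and a lead-variant flag;
#' optionally written as TSV.
#'
#' @param region A `coloc_region`.
#' @param path Optional output path.
#' @return The table, invisibly if written.
#' @export
regional_table <- function(region, path = NULL) {
  v <- region$variants
  nlp <- function(beta, se) {
    -(stats::pnorm(-abs(beta / se), log.p = TRUE) + log(2)) / log(10)
  }
  out <- data.frame(
    variant_id = v$variant_id,
    pos = v$pos,
    neglog10p_trait1 = nlp(v$beta1, v$se1),
    neglog10p_trait2 = nlp(v$beta2, v$se2),
    is_lead = v$variant_id == region$lead_variant_id,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
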