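# Fast closed-form summary-statistics backend: draws harmonized
# exposure/outcome pairs directly from their sampling distributions,
# bypassing individual-level simulation. Used for large replicate counts
# (parameter recovery, type-I error, reverse-MR sweeps) where the
# individual-level generator would be needlessly slow.

## Sampling standard errors implied by the design.
summary_se <- function(config) {
  q <- 2 * config$maf * (1 - config$maf)
  n_out <- config$n_case + config$n_control
  k <- config$n_case / n_out
  list(
    se_x = 1 / sqrt(config$n_exposure * q),       # SD-unit exposure scan
    se_y = 1 / sqrt(n_out * k * (1 - k) * q)       # logistic outcome scan
  )
}

#' Draw single-SNP harmonized pairs from the closed-form backend
#'
#' For a single-instrument design, the exposure scan estimate is
#' `N(beta_x, se_x^2)` with `beta_x = sqrt(target_r2 / 2pq)` (SD units)
#' and `se_x = 1/sqrt(n 2pq)`; the outcome scan estimate is
#' `N(beta_xy * beta_x + delta, se_y^2)` with the case-control
#' `se_y = 1/sqrt(N K (1-K) 2pq)` and `delta` any direct pleiotropic
#' effect. Each replicate yields one ready-to-use harmonized pair.
#'
#' When `config$n_cohorts > 1` the exposure estimate is the
#' inverse-variance fixed-effects meta-analysis of one draw per cohort
#' (each cohort scanning `n_exposure` individuals), mirroring the
#' pipeline's meta-supported instrument selection; the reported
#' `exposure_se` is the meta-analysis SE.
#'
#' @param n_rep Number of replicates.
#' @param config A [scenario_config()]; `scenario` decides which effects
#'   are non-zero.
#' @param seed Overrides `config$seed`; `NULL` continues the ambient RNG
#'   stream (single-stream replicate sweeps).
#' @return Data frame of `n_rep` harmonized pairs (one row each) with a
#'   `replicate` column; feed single rows to [wald_ratio()].
#' @export
simulate_wald_replicates <- function(n_rep, config, seed = config$seed) {
  ses <- summary_se(config)
  q <- 2 * config$maf * (1 - config$maf)
  beta_x <- if (config$scenario == "null" && config$target_r2 == 0) 0 else
    sqrt(config$target_r2 / q)
  bxy <- log(config$causal_or_per_sd)
  nc <- max(1L, config$n_cohorts)
  with_seed(seed, {
    if (nc > 1L) {
      draws <- matrix(stats::rnorm(n_rep * nc, beta_x, ses$se_x),
                      n_rep, nc)
      meta <- apply(draws, 1, function(b)
        unlist(fixed_effects_meta(b, rep(ses$se_x, nc))[c("beta", "se")]))
      xb <- meta["beta", ]
      se_x <- meta["se", ]
    } else {
      xb <- stats::rnorm(n_rep, beta_x, ses$se_x)
      se_x <- ses$se_x
    }
    yb <- stats::rnorm(n_rep, bxy * beta_x + config$pleiotropy_delta,
                       ses$se_y)
    data.frame(
      replicate = seq_len(n_rep),
      variant_id = "snp_01",
      effect_allele = "A", other_allele = "G",
      exposure_beta = xb, exposure_se = se_x,
      exposure_eaf = config$maf,
      outcome_beta = yb, outcome_se = ses$se_y,
      outcome_eaf = config$maf,
      action = "kept",
      stringsAsFactors = FALSE
    )
  })
}

#' Draw a multi-SNP harmonized instrument from the closed-form backend
#'
#' Generates `k` independent instruments whose true exposure effects are
#' spread around the single-SNP calibration, then outcome effects
#' `beta_xy * beta_x + pleiotropy + noise`. `pleiotropy` may be a scalar
#' (constant directional pleiotropy added to every SNP, the MR-Egger
#' intercept scenario) or a length-`k` vector (e.g. large effects for an
#' invalid subset).
#'
#' @param k Number of instruments.
#' @param config A [scenario_config()].
#' @param beta_xy True causal effect (defaults to
#'   `log(config$causal_or_per_sd)`).
#' @param pleiotropy Direct outcome effect(s) (default
#'   `config$pleiotropy_delta`).
#' @param seed Overrides `config$seed`.
#' @return Harmonized-pairs data frame with `k` rows.
#' @export
simulate_multisnp_pairs <- function(k, config,
                                    beta_xy = log(config$causal_or_per_sd),
                                    pleiotropy = config$pleiotropy_delta,
                                    seed = config$seed) {
  ses <- summary_se(config)
  q <- 2 * config$maf * (1 - config$maf)
  base <- sqrt(config$target_r2 / q)
  pleiotropy <- rep_len(pleiotropy, k)
  with_seed(seed, {
    ## true per-SNP exposure effects: spread of instrument strengths
    bx <- base * stats::runif(k, 0.6, 1.4)
    xb <- stats::rnorm(k, bx, ses$se_x)
    yb <- stats::rnorm(k, beta_xy * bx + pleiotropy, ses$se_y)
    data.frame(
      variant_id = sprintf("snp_%02d", seq_len(k)),
      effect_allele = "A", other_allele = "G",
      exposure_beta = xb, exposure_se = ses$se_x,
      exposure_eaf = config$maf,
      outcome_beta = yb, outcome_se = ses$se_y,
      outcome_eaf = config$maf,
      action = "kept",
      stringsAsFactors = FALSE
    )
  })
}

#' Closed-form reverse-MR study
#'
#' Emulates reverse MR with the disease as exposure: `k` approximately
#' independent disease instruments with log-OR effects `b_d` and
#' case-control scan errors; the microbial-trait associations of those
#' SNPs are `gamma * b_d` plus noise at the microbiome-cohort scan error
#' (n = 2223), where `gamma` is the causal effect of disease liability on
#' the trait. `gamma = 0` (any forward scenario) encodes no reverse
#' effect; the reverse-causal scenario uses `config$reverse_effect`.
#'
#' @param k Number of disease instruments (default 30, matching the
#'   site-specific clumped instrument counts).
#' @param config A [scenario_config()].
#' @param seed Overrides `config$seed`.
#' @return Harmonized-pairs data frame (disease as exposure, trait as
#'   outcome) ready for [mr_ivw()].
#' @export
simulate_reverse_pairs <- function(k = 30, config, seed = config$seed) {
  q <- 2 * config$maf * (1 - config$maf)
  n_out <- config$n_case + config$n_control
  kk <- config$n_case / n_out
  se_d <- 1 / sqrt(n_out * kk * (1 - kk) * q)   # disease scan (exposure here)
  se_t <- 1 / sqrt(2223 * q)                    # trait scan in FGFP
  gamma <- if (config$scenario == "reverse_causal") config$reverse_effect
    else 0
  with_seed(seed, {
    ## true disease log-ORs: genome-wide significant scale (z ~ 7-12)
    bd <- stats::runif(k, 7, 12) * se_d * sample(c(-1, 1), k, replace = TRUE)
    xb <- stats::rnorm(k, bd, se_d)
    yb <- stats::rnorm(k, gamma * bd, se_t)
    data.frame(
      variant_id = sprintf("crc_snp_%02d", seq_len(k)),
      effect_allele = "A", other_allele = "G",
      exposure_beta = xb, exposure_se = se_d,
      exposure_eaf = config$maf,
      outcome_beta = yb, outcome_se = se_t,
      outcome_eaf = config$maf,
      action = "kept",
      stringsAsFactors = FALSE
    )
  })
}
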