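# Synthetic-data generation with known ground truth: genotypes under
# Hardy-Weinberg with block LD, hurdle microbial traits (presence/absence
# plus zero-truncated rank-normalized abundance), case-control outcomes,
# per-cohort association scans, regional datasets for colocalisation, and
# catalogue fixtures for the pleiotropy screen.

#' Scenario configuration for synthetic datasets
#'
#' A fully specified synthetic world. Defaults emulate the study's stated
#' conditions at desk scale: single-SNP instruments explaining ~1% of
#' trait variance, three cohorts sharing the true effect, a causal odds
#' ratio of 1.4 per SD of abundance, an outcome case fraction of 0.46
#' (55,168 cases / 120,328 total, scaled down), hurdle traits with
#' presence prevalence 0.6, and ~200-variant regions for colocalisation.
#'
#' @param scenario One of `"null"`, `"forward_causal"`, `"pleiotropic"`,
#'   `"reverse_causal"`, `"shared_causal_region"`,
#'   `"distinct_causal_region"`.
#' @param seed Integer seed; mandatory, every draw flows from it.
#' @param n_individuals Individuals per cohort (default 10000).
#' @param n_cohorts Number of cohorts (default 3; cohort 1 is discovery).
#' @param n_variants Variants in genotype scans (default 20).
#' @param maf Minor allele frequency, recycled across variants
#'   (default 0.3).
#' @param target_r2 Variance in the exposure explained by the instrument
#'   (default 0.01).
#' @param causal_or_per_sd True OR on the outcome per SD of exposure
#'   (default 1.4 in causal scenarios, 1 under the null).
#' @param pleiotropy_delta Direct effect of the instrument on the outcome
#'   log-odds, bypassing the exposure (default 0; only the pleiotropic
#'   scenario sets it).
#' @param reverse_effect Effect of the disease genetic score on the trait
#'   (SD per unit log-odds; reverse_causal scenario only, default 0.1).
#' @param measure `"AB"` (abundance) or `"PA"` (presence/absence hurdle).
#' @param prevalence Presence prevalence for PA traits (default 0.6).
#' @param case_fraction Outcome case fraction (default 0.46).
#' @param ld_block_size,ld_rho LD block size and within-block genotype
#'   correlation for scans (defaults 1 and 0: independent variants).
#' @param n_region_variants,region_z,region_block_size,region_rho
#'   Regional-dataset geometry: variant count (200), causal z-score (8),
#'   LD block size (10) and within-block correlation (0.8).
#' @param n_exposure,n_case,n_control Summary-backend sample sizes
#'   (defaults 10000 exposure; 55168 / 65160 outcome).
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("null", "forward_causal",
                                         "pleiotropic", "reverse_causal",
                                         "shared_causal_region",
                                         "distinct_causal_region"),
                            seed,
                            n_individuals = 10000, n_cohorts = 3,
                            n_variants = 20, maf = 0.3,
                            target_r2 = 0.01,
                            causal_or_per_sd = NULL,
                            pleiotropy_delta = NULL,
                            reverse_effect = NULL,
                            measure = c("AB", "PA"),
                            prevalence = 0.6, case_fraction = 0.46,
                            ld_block_size = 1, ld_rho = 0,
                            n_region_variants = 200, region_z = 8,
                            region_block_size = 10, region_rho = 0.8,
                            n_exposure = 10000,
                            n_case = 55168, n_control = 65160) {
  scenario <- match.arg(scenario)
  measure <- match.arg(measure)
  if (missing(seed) || is.null(seed)) stop_usage("seed is mandatory")
  ## Scenario determines which effects are non-zero.
  if (is.null(causal_or_per_sd))
    causal_or_per_sd <- if (scenario %in% c("forward_causal", "pleiotropic"))
      1.4 else 1
  if (is.null(pleiotropy_delta))
    pleiotropy_delta <- if (scenario == "pleiotropic") 0.05 else 0
  if (is.null(reverse_effect))
    reverse_effect <- if (scenario == "reverse_causal") 0.1 else 0
  probs <- c(maf = maf, prevalence = prevalence,
             case_fraction = case_fraction)
  if (any(probs <= 0) || any(probs >= 1))
    stop_usage("maf, prevalence and case_fraction must be in (0, 1)")
  if (target_r2 <= 0 || target_r2 >= 1)
    stop_usage("target_r2 must be in (0, 1)")
  structure(
    list(scenario = scenario, seed = as.integer(seed),
         n_individuals = n_individuals, n_cohorts = n_cohorts,
         n_variants = n_variants, maf = maf, target_r2 = target_r2,
         causal_or_per_sd = causal_or_per_sd,
         pleiotropy_delta = pleiotropy_delta,
         reverse_effect = reverse_effect,
         measure = measure, prevalence = prevalence,
         case_fraction = case_fraction,
         ld_block_size = ld_block_size, ld_rho = ld_rho,
         n_region_variants = n_region_variants, region_z = region_z,
         region_block_size = region_block_size, region_rho = region_rho,
         n_exposure = n_exposure, n_case = n_case, n_control = n_control),
    class = "scenario_config"
  )
}

#' Blom rank-normal transform
#'
#' Maps values through `qnorm((rank - 3/8) / (n + 1/4))`; ties broken by
#' stable (first-occurrence) order.
#'
#' @param x Numeric vector without missing values.
#' @return Transformed vector with the same length.
#' @export
rank_normal <- function(x) {
  r <- rank(x, ties.method = "first")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Simulate genotypes with block LD
#'
#' Draws Hardy-Weinberg genotypes (0/1/2). Within an LD block each allele
#' copy either copies the block's lead variant (probability `ld_rho`) or
#' is drawn fresh, so the expected within-block genotype correlation is
#' `ld_rho` exactly when MAFs match within the block.
#'
#' @param n Individuals.
#' @param maf Minor allele frequency (scalar or per-variant vector).
#' @param n_variants Number of variants (defaults to `length(maf)`).
#' @param ld_block_size Variants per LD block (1 = independent).
#' @param ld_rho Within-block allele copying probability.
#' @param seed Optional seed (RNG state restored afterwards).
#' @return Integer matrix `n x n_variants` with columns `snp_01`, ...
#' @export
simulate_genotypes <- function(n, maf, n_variants = length(maf),
                               ld_block_size = 1, ld_rho = 0,
                               seed = NULL) {
  maf <- rep_len(maf, n_variants)
  with_seed(seed, {
    draw_alleles <- function() {
      a <- matrix(0L, n, n_variants)
      block_start <- seq(1L, n_variants, by = ld_block_size)
      for (s in block_start) {
        idx <- s:min(s + ld_block_size - 1L, n_variants)
        lead <- stats::rbinom(n, 1L, maf[s])
        a[, idx[1]] <- lead
        for (j in idx[-1]) {
          copy <- stats::rbinom(n, 1L, ld_rho)
          a[, j] <- ifelse(copy == 1L, lead, stats::rbinom(n, 1L, maf[j]))
        }
      }
      a
    }
    g <- draw_alleles() + draw_alleles()
    colnames(g) <- sprintf("snp_%02d", seq_len(n_variants))
    g
  })
}

## Per-allele log-OR for a PA trait hitting a target liability-scale r2.
pa_lor_for_r2 <- function(target_r2, maf) {
  q <- 2 * maf * (1 - maf)
  beta_liab <- sqrt(target_r2 / ((1 - target_r2) * q))
  beta_liab * pi / sqrt(3)
}

#' Simulate a hurdle microbial trait
#'
#' The instrument is the first genotype column. For an abundance (AB)
#' trait: a linear genotype effect calibrated so the realized variance
#' explained matches `target_r2`, gaussian noise, then a Blom rank-normal
#' transform (so the scan operates in SD units). For a presence/absence
#' (PA) trait: a logistic model on genotype whose intercept is solved
#' numerically to hit the configured prevalence and whose per-allele
#' log-OR is calibrated (through the liability approximation) to
#' `target_r2`; a zero-truncated rank-normalized abundance is generated
#' among the present.
#'
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param config A [scenario_config()].
#' @param extra_liability Optional per-individual shift of the trait (used
#'   by the reverse-causal scenario where disease liability feeds back
#'   into the trait).
#' @return List with `value` (the analysed phenotype: rank-normal
#'   abundance for AB, 0/1 presence for PA), `present`, `abundance`,
#'   `measure`, and the true instrument effect used.
#' @export
simulate_microbial_trait <- function(genotypes, config,
                                     extra_liability = NULL) {
  g <- genotypes[, 1]
  n <- length(g)
  p <- mean(g) / 2
  q <- 2 * p * (1 - p)
  shift <- if (is.null(extra_liability)) 0 else extra_liability
  if (config$measure == "AB") {
    beta_g <- if (config$target_r2 > 0 && config$scenario != "null")
      sqrt(config$target_r2 / q) else 0
    noise_sd <- sqrt(max(1 - beta_g^2 * q, 0.1))
    raw <- beta_g * g + shift + stats::rnorm(n, 0, noise_sd)
    value <- rank_normal(raw)
    list(value = value, present = rep(1L, n), abundance = value,
         measure = "AB", instrument_beta = beta_g)
  } else {
    lor <- if (config$scenario != "null")
      pa_lor_for_r2(config$target_r2, p) else 0
    lin <- lor * (g - 2 * p) + shift
    alpha <- stats::uniroot(
      function(a) mean(stats::plogis(a + lin)) - config$prevalence,
      interval = c(-20, 20))$root
    present <- stats::rbinom(n, 1L, stats::plogis(alpha + lin))
    abundance <- rep(NA_real_, n)
    idx <- present == 1L
    if (any(idx)) {
      raw <- 0.1 * g[idx] + stats::rnorm(sum(idx))
      abundance[idx] <- rank_normal(raw)
    }
    list(value = present, present = present, abundance = abundance,
         measure = "PA", instrument_beta = lor)
  }
}

#' Simulate a case-control outcome
#'
#' Logistic disease model on the exposure (and, in the pleiotropic
#' scenario, a direct genotype effect that bypasses it):
#' `logit P(case) = alpha + ln(causal_or_per_sd) * trait +
#' pleiotropy_delta * g`, with the intercept solved to hit the configured
#' case fraction. In the reverse-causal scenario the outcome depends on
#' genotype only (the trait is generated downstream of disease
#' liability).
#'
#' @param genotypes Genotype matrix (instrument in column 1).
#' @param trait Trait list from [simulate_microbial_trait()] (ignored in
#'   the reverse-causal scenario).
#' @param config A [scenario_config()].
#' @return List with `case` (0/1 vector) and `genetic_liability` (the
#'   genotype-driven part of the linear predictor).
#' @export
simulate_outcome <- function(genotypes, trait, config) {
  g <- genotypes[, 1]
  n <- nrow(genotypes)
  if (config$scenario == "reverse_causal") {
    ## Disease is genotype-driven; trait response is generated elsewhere.
    p <- mean(g) / 2
    gamma <- sqrt(config$target_r2 / (2 * p * (1 - p)))
    lin <- gamma * (g - 2 * p)
  } else {
    x <- if (trait$measure == "AB") trait$value else
      trait$value - mean(trait$value)
    lin <- log(config$causal_or_per_sd) * x + config$pleiotropy_delta * g
  }
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + lin)) - config$case_fraction,
    interval = c(-20, 20))$root
  case <- stats::rbinom(n, 1L, stats::plogis(alpha + lin))
  glia <- if (config$scenario == "reverse_causal") lin else
    config$pleiotropy_delta * g
  list(case = case, genetic_liability = glia)
}

#' Per-variant association scan
#'
#' Univariate linear regression for continuous phenotypes (closed-form,
#' identical to `lm`) and univariate logistic regression (`glm`) for
#' binary phenotypes, one model per variant, emitting the same table
#' dialect [read_sumstats()] consumes. Monomorphic variants are flagged
#' with missing betas.
#'
#' @param genotypes Genotype matrix (columns are variants).
#' @param phenotype Numeric (continuous) or 0/1 (binary) vector.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param trait_id Trait label stamped on every row.
#' @param pos Optional base-pair positions (default 1e6 spacing).
#' @return Summary-statistics data frame (alleles fixed at A effect /
#'   G other; `eaf` is the frequency of the counted allele).
#' @export
run_association_scan <- function(genotypes, phenotype,
                                 trait_type = c("continuous", "binary"),
                                 trait_id = "trait", pos = NULL) {
  trait_type <- match.arg(trait_type)
  m <- ncol(genotypes)
  n <- nrow(genotypes)
  if (length(phenotype) != n) stop_usage("phenotype/genotype length mismatch")
  if (is.null(pos)) pos <- seq_len(m) * 1e6
  beta <- se <- pval <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    if (stats::var(g) == 0) next   # monomorphic: leave missing
    if (trait_type == "continuous") {
      gc <- g - mean(g)
      sxx <- sum(gc^2)
      b <- sum(gc * phenotype) / sxx
      resid <- phenotype - mean(phenotype) - b * gc
      s2 <- sum(resid^2) / (n - 2)
      beta[j] <- b
      se[j] <- sqrt(s2 / sxx)
      pval[j] <- 2 * stats::pt(-abs(b / se[j]), df = n - 2)
    } else {
      fit <- suppressWarnings(
        stats::glm(phenotype ~ g, family = stats::binomial()))
      cf <- summary(fit)$coefficients
      if ("g" %in% rownames(cf)) {
        beta[j] <- cf["g", "Estimate"]
        se[j] <- cf["g", "Std. Error"]
        pval[j] <- cf["g", "Pr(>|z|)"]
      }
    }
  }
  out <- data.frame(
    variant_id = colnames(genotypes),
    chrom = "1",
    pos = pos,
    effect_allele = "A", other_allele = "G",
    eaf = colMeans(genotypes) / 2,
    beta = beta, se = se,
    pvalue = pmax(pval, .Machine$double.xmin),
    n = n,
    trait_id = trait_id, trait_type = trait_type,
    stringsAsFactors = FALSE
  )
  if (trait_type == "binary") {
    out$n_case <- sum(phenotype == 1)
    out$n_control <- sum(phenotype == 0)
  }
  rownames(out) <- NULL
  out
}

#' Simulate a multi-cohort exposure/outcome study at the individual level
#'
#' End-to-end generative run for one scenario: genotypes, the hurdle
#' trait and the case-control outcome per cohort, then association scans,
#' exercising the exact scale conventions (SD units for AB, log-OR for PA
#' and the outcome) the real pipeline consumes.
#'
#' @param config A [scenario_config()].
#' @return List with per-cohort `exposure` and `outcome` summary tables
#'   (first cohort is discovery) and the `truth` record.
#' @export
simulate_cohort_study <- function(config) {
  with_seed(config$seed, {
    cohorts <- lapply(seq_len(config$n_cohorts), function(ci) {
      g <- simulate_genotypes(config$n_individuals, config$maf,
                              config$n_variants,
                              config$ld_block_size, config$ld_rho)
      if (config$scenario == "reverse_causal") {
        out <- simulate_outcome(g, NULL, config)
        trait <- simulate_microbial_trait(
          g, config,
          extra_liability = config$reverse_effect * out$genetic_liability)
      } else {
        trait <- simulate_microbial_trait(g, config)
        out <- simulate_outcome(g, trait, config)
      }
      list(
        exposure = run_association_scan(
          g, trait$value,
          if (config$measure == "AB") "continuous" else "binary",
          trait_id = paste0("microbial_", tolower(config$measure))),
        outcome = run_association_scan(g, out$case, "binary",
                                       trait_id = "crc")
      )
    })
    list(
      exposure = lapply(cohorts, `[[`, "exposure"),
      outcome = lapply(cohorts, `[[`, "outcome"),
      truth = list(scenario = config$scenario,
                   causal_logor = log(config$causal_or_per_sd),
                   pleiotropy_delta = config$pleiotropy_delta,
                   reverse_effect = config$reverse_effect)
    )
  })
}

## Block compound-symmetry LD correlation matrix.
block_ld_matrix <- function(m, block_size, rho) {
  r <- diag(m)
  starts <- seq(1L, m, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, m)
    r[idx, idx] <- rho
    diag(r)[idx] <- 1
  }
  r
}

#' Simulate a regional dataset for colocalisation
#'
#' Closed-form regional summary statistics for two traits under a shared
#' LD structure: true z-scores place the causal variant(s) according to
#' the scenario (`shared_causal_region`: one variant causal for both
#' traits at `region_z`; `distinct_causal_region`: different causal
#' variants in LD-independent blocks; `null`: none), observed z-scores
#' are `R z_true + e`, `e ~ N(0, R)`. Trait 1 emulates the microbiome
#' discovery cohort (n = 2223, quantitative); trait 2 the case-control
#' disease meta-analysis.
#'
#' @param config A [scenario_config()] with a region scenario (or `null`).
#' @param seed Overrides `config$seed` (useful for replicate sweeps).
#' @return List with `trait1`, `trait2` summary data frames, the LD
#'   matrix `ld`, `lead_variant_id` and a ground-truth record.
#' @export
make_regional_dataset <- function(config, seed = config$seed) {
  if (!config$scenario %in% c("shared_causal_region",
                              "distinct_causal_region", "null"))
    stop_usage("config scenario must be a region scenario or 'null'")
  m <- config$n_region_variants
  with_seed(seed, {
    r <- block_ld_matrix(m, config$region_block_size, config$region_rho)
    ch <- chol(r)
    z1 <- z2 <- rep(0, m)
    causal1 <- causal2 <- NA_integer_
    if (config$scenario == "shared_causal_region") {
      causal1 <- causal2 <- m %/% 2L
      z1[causal1] <- config$region_z
      z2[causal2] <- config$region_z
    } else if (config$scenario == "distinct_causal_region") {
      causal1 <- m %/% 4L
      causal2 <- (3L * m) %/% 4L
      z1[causal1] <- config$region_z
      z2[causal2] <- config$region_z
    }
    zhat1 <- rmvnorm_chol(drop(r %*% z1), ch)
    zhat2 <- rmvnorm_chol(drop(r %*% z2), ch)
    q <- 2 * config$maf * (1 - config$maf)
    se1 <- rep(1 / sqrt(2223 * q), m)
    n_out <- config$n_case + config$n_control
    k_out <- config$n_case / n_out
    se2 <- rep(1 / sqrt(n_out * k_out * (1 - k_out) * q), m)
    pos <- 4e6 + seq_len(m) * 1e4   # 10 kb spacing, ~2 Mb span
    ids <- sprintf("rs%05d", seq_len(m))
    mk <- function(zhat, se, trait_id, trait_type) {
      df <- data.frame(
        variant_id = ids, chrom = "1", pos = pos,
        effect_allele = "A", other_allele = "G",
        eaf = config$maf, beta = zhat * se, se = se,
        pvalue = pmax(2 * stats::pnorm(-abs(zhat)), .Machine$double.xmin),
        n = if (trait_type == "binary") n_out else 2223,
        trait_id = trait_id, trait_type = trait_type,
        stringsAsFactors = FALSE)
      df
    }
    lead <- ids[if (is.na(causal1)) which.max(abs(zhat1)) else causal1]
    list(
      trait1 = mk(zhat1, se1, "microbial_trait", "continuous"),
      trait2 = mk(zhat2, se2, "crc", "binary"),
      ld = structure(r, dimnames = list(ids, ids)),
      lead_variant_id = lead,
      truth = list(scenario = config$scenario,
                   causal1 = if (is.na(causal1)) NA else ids[causal1],
                   causal2 = if (is.na(causal2)) NA else ids[causal2])
    )
  })
}

#' Build a deterministic association-catalogue fixture
#'
#' Emits a catalogue with a requested number of sub-threshold rows per
#' trait class for one variant (p-values geometrically spaced below the
#' threshold) plus optional above-threshold filler, so screen counts are
#' known by construction.
#'
#' @param variant_id Variant the rows refer to.
#' @param counts Named integer vector over trait classes (defaults to the
#'   composition observed for the abundant-*Bifidobacterium* instrument:
#'   51 complex traits, 103 eQTs, 6 metabolites, 59 mQTs, 1 protein).
#' @param threshold Screening threshold the rows must sit below.
#' @param n_above Above-threshold filler rows (class `other`).
#' @param path Optional TSV output path.
#' @return Catalogue data frame (written to `path` when given).
#' @export
make_catalogue_fixture <- function(variant_id = "rs4988235",
                                   counts = c(complex_trait = 51, eQT = 103,
                                              metabolite = 6, mQT = 59,
                                              protein = 1),
                                   threshold = 1e-4, n_above = 5,
                                   path = NULL) {
  stopifnot(all(names(counts) %in% CATALOGUE_CLASSES))
  rows <- lapply(names(counts), function(cl) {
    k <- counts[[cl]]
    if (k == 0) return(NULL)
    data.frame(
      variant_id = variant_id,
      trait_name = sprintf("%s_%03d", cl, seq_len(k)),
      trait_class = cl,
      ## geometric spacing strictly below the threshold
      pvalue = threshold * 10^(-seq_len(k) / k - 0.01),
      source = "synthetic_catalogue",
      stringsAsFactors = FALSE)
  })
  if (n_above > 0) {
    rows <- c(rows, list(data.frame(
      variant_id = variant_id,
      trait_name = sprintf("null_trait_%03d", seq_len(n_above)),
      trait_class = "other",
      pvalue = seq(0.05, 0.95, length.out = n_above),
      source = "synthetic_catalogue",
      stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(0), trait_name = character(0),
                      trait_class = character(0), pvalue = numeric(0),
                      source = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (!is.null(path)) write_catalogue(out, path)
  out
}
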