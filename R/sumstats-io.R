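# Reading, validating and writing GWAS summary statistics, and harmonizing
# exposure/outcome association pairs to a shared effect allele.

VALID_ALLELES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

## Fixed column order of the harmonized-pairs table.
HARMONIZED_COLUMNS <- c(
  "variant_id", "effect_allele", "other_allele",
  "exposure_beta", "exposure_se", "exposure_eaf",
  "outcome_beta", "outcome_se", "outcome_eaf", "action"
)

DROPPED_ACTIONS <- c("dropped_palindromic_ambiguous", "dropped_allele_mismatch")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited file with a header row into a validated
#' variant-association data frame. Column names in the file are mapped onto
#' the canonical fields via `column_map`, so bespoke layouts (both source
#' GWASs here use their own dialects) can be ingested without rewriting the
#' file. Rows failing validation (non-positive standard error, invalid
#' alleles, out-of-range frequency or p-value) are skipped with a warning
#' that reports the offending line numbers.
#'
#' Canonical fields: `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, `n_case`,
#' `n_control`, `trait_id`, `trait_type`. Mandatory: `variant_id`,
#' `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical field names to
#'   column names in the file, e.g. `c(variant_id = "SNP", beta = "b")`.
#'   Fields not named are looked up under their canonical name.
#' @param trait_id,trait_type Optional trait annotation applied to every row
#'   (`trait_type` one of `"continuous"`, `"binary"`).
#' @param sep Field separator (default tab).
#' @return A `data.frame` with one validated row per variant; alleles are
#'   upper-cased. Attribute `n_skipped` records the number of rows dropped.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = NULL,
                          trait_type = NULL, sep = "\t") {
  if (!file.exists(path)) stop_usage("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  mandatory <- c("variant_id", "effect_allele", "other_allele",
                 "beta", "se", "pvalue")
  optional <- c("chrom", "pos", "eaf", "n", "n_case", "n_control")
  resolve <- function(field) {
    nm <- if (!is.null(column_map) && field %in% names(column_map))
      column_map[[field]] else field
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }
  for (field in mandatory) {
    if (is.null(resolve(field)))
      stop_usage("mandatory column for field '", field, "' not found in ", path)
  }
  out <- data.frame(
    variant_id = as.character(resolve("variant_id")),
    effect_allele = toupper(as.character(resolve("effect_allele"))),
    other_allele = toupper(as.character(resolve("other_allele"))),
    beta = as.numeric(resolve("beta")),
    se = as.numeric(resolve("se")),
    pvalue = as.numeric(resolve("pvalue")),
    stringsAsFactors = FALSE
  )
  for (field in optional) {
    v <- resolve(field)
    if (!is.null(v)) {
      out[[field]] <- if (field == "chrom") as.character(v) else as.numeric(v)
    }
  }
  ok <- validate_sumstat_rows(out)
  if (any(!ok)) {
    warning(sum(!ok), " row(s) failed validation and were skipped (lines ",
            paste(which(!ok) + 1L, collapse = ", "), ") in ", path,
            call. = FALSE)
  }
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(trait_id)) out$trait_id <- trait_id
  if (!is.null(trait_type)) {
    out$trait_type <- match.arg(trait_type, c("continuous", "binary"))
  }
  attr(out, "n_skipped") <- sum(!ok)
  out
}

validate_sumstat_rows <- function(x) {
  ok <- !is.na(x$variant_id) & nzchar(x$variant_id) &
    x$effect_allele %in% VALID_ALLELES &
    x$other_allele %in% VALID_ALLELES &
    x$effect_allele != x$other_allele &
    !is.na(x$beta) &
    !is.na(x$se) & x$se > 0 &
    !is.na(x$pvalue) & x$pvalue > 0 & x$pvalue <= 1
  if (!is.null(x$eaf)) ok <- ok & (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1))
  if (!is.null(x$n)) ok <- ok & (is.na(x$n) | x$n >= 2)
  ok
}

#' Write a summary-statistics table
#'
#' Tab-delimited counterpart of [read_sumstats()]; round-trips all columns.
#'
#' @param x Data frame of variant associations.
#' @param path Output path.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Is a variant palindromic?
#'
#' A variant is palindromic (strand-ambiguous) when its two alleles are an
#' A/T or C/G combination, so the strand cannot be resolved from the allele
#' labels alone.
#'
#' @param effect_allele,other_allele Character vectors of single-base
#'   alleles.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele)
  b <- toupper(other_allele)
  if (!all(a %in% VALID_ALLELES) || !all(b %in% VALID_ALLELES))
    stop_usage("alleles must be one of A, C, G, T")
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize exposure and outcome associations to a shared effect allele
#'
#' Aligns per-variant outcome associations to the exposure's effect allele.
#' Non-palindromic variants are matched directly, with allele-role swap
#' (outcome beta negated, frequency reflected), or after strand
#' complementing. Palindromic variants (A/T, C/G) cannot be resolved from
#' allele labels; allele frequency is used instead: if the minor allele
#' frequency exceeds `palindromic_maf_limit` in either dataset (or a
#' frequency is missing) the variant is non-inferable and dropped,
#' otherwise the outcome is oriented so both effect-allele frequencies fall
#' on the same side of 0.5. Irreconcilable allele pairs are dropped.
#'
#' @param exposure,outcome Summary-statistics data frames (as from
#'   [read_sumstats()]); matched on `variant_id`. When both have exactly one
#'   row the variant ids must agree.
#' @param palindromic_maf_limit Minor-allele-frequency ceiling above which a
#'   palindromic variant is considered ambiguous (default 0.42).
#' @return Data frame of harmonized pairs with columns
#'   `variant_id, effect_allele, other_allele, exposure_beta, exposure_se,
#'   exposure_eaf, outcome_beta, outcome_se, outcome_eaf, action`. Rows with
#'   an action starting `dropped_` must be excluded from estimation (see
#'   [kept_pairs()]).
#' @export
harmonize <- function(exposure, outcome, palindromic_maf_limit = 0.42) {
  if (nrow(exposure) == 1L && nrow(outcome) == 1L &&
      exposure$variant_id != outcome$variant_id) {
    stop_usage("variant_id mismatch: '", exposure$variant_id, "' vs '",
               outcome$variant_id, "'")
  }
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  n <- length(shared)
  ex_eaf <- if (is.null(ex$eaf)) rep(NA_real_, n) else ex$eaf
  ou_eaf <- if (is.null(ou$eaf)) rep(NA_real_, n) else ou$eaf
  res <- data.frame(
    variant_id = shared,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    exposure_beta = ex$beta, exposure_se = ex$se, exposure_eaf = ex_eaf,
    outcome_beta = ou$beta, outcome_se = ou$se, outcome_eaf = ou_eaf,
    action = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    h <- harmonize_one(
      ex$effect_allele[i], ex$other_allele[i], ex_eaf[i],
      ou$effect_allele[i], ou$other_allele[i], ou$beta[i], ou_eaf[i],
      palindromic_maf_limit
    )
    res$outcome_beta[i] <- h$beta
    res$outcome_eaf[i] <- h$eaf
    res$action[i] <- h$action
  }
  rownames(res) <- NULL
  res
}

## Single-pair harmonization kernel; returns the re-oriented outcome beta
## and eaf plus the action taken.
harmonize_one <- function(ea_x, oa_x, eaf_x, ea_y, oa_y, beta_y, eaf_y,
                          maf_limit) {
  if (is_palindromic(ea_x, oa_x)) {
    ## Allele labels carry no strand information: resolve via frequency.
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x)))
      return(list(beta = beta_y, eaf = eaf_y,
                  action = "dropped_allele_mismatch"))
    if (is.na(eaf_x) || is.na(eaf_y))
      return(list(beta = beta_y, eaf = eaf_y,
                  action = "dropped_palindromic_ambiguous"))
    maf_x <- min(eaf_x, 1 - eaf_x)
    maf_y <- min(eaf_y, 1 - eaf_y)
    if (maf_x > maf_limit || maf_y > maf_limit)
      return(list(beta = beta_y, eaf = eaf_y,
                  action = "dropped_palindromic_ambiguous"))
    ## Frequencies in both datasets refer to the same allele iff they fall
    ## on the same side of 0.5; discordance implies the outcome is reported
    ## for the opposite allele.
    concordant <- (eaf_x < 0.5) == (eaf_y < 0.5)
    if (concordant)
      return(list(beta = beta_y, eaf = eaf_y, action = "palindromic_inferred"))
    return(list(beta = -beta_y, eaf = 1 - eaf_y,
                action = "palindromic_inferred"))
  }
  if (ea_y == ea_x && oa_y == oa_x)
    return(list(beta = beta_y, eaf = eaf_y, action = "kept"))
  if (ea_y == oa_x && oa_y == ea_x)
    return(list(beta = -beta_y, eaf = if (is.na(eaf_y)) NA_real_ else 1 - eaf_y,
                action = "outcome_sign_flipped"))
  cea <- COMPLEMENT[[ea_y]]
  coa <- COMPLEMENT[[oa_y]]
  if (cea == ea_x && coa == oa_x)
    return(list(beta = beta_y, eaf = eaf_y, action = "strand_flipped"))
  if (cea == oa_x && coa == ea_x)
    return(list(beta = -beta_y, eaf = if (is.na(eaf_y)) NA_real_ else 1 - eaf_y,
                action = "outcome_sign_flipped"))
  list(beta = beta_y, eaf = eaf_y, action = "dropped_allele_mismatch")
}

#' Non-dropped harmonized pairs
#'
#' @param pairs Harmonized-pairs data frame from [harmonize()].
#' @return The subset of rows whose action does not start with `dropped`.
#' @export
kept_pairs <- function(pairs) {
  pairs[!pairs$action %in% DROPPED_ACTIONS, , drop = FALSE]
}

#' Write / read a harmonized-pairs table
#'
#' Tab-delimited, fixed column order (`variant_id, effect_allele,
#' other_allele, exposure_beta, exposure_se, exposure_eaf, outcome_beta,
#' outcome_se, outcome_eaf, action`).
#'
#' @param pairs Harmonized-pairs data frame.
#' @param path Output (or input) path.
#' @export
write_harmonized <- function(pairs, path) {
  cols <- intersect(HARMONIZED_COLUMNS, names(pairs))
  utils::write.table(pairs[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_harmonized
#' @export
read_harmonized <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
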