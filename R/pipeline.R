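# Orchestration of the full study design: forward MR per trait and
# outcome site, the sensitivity battery (lenient multi-SNP estimators,
# colocalisation, pleiotropy screen, heterogeneity and leave-one-out),
# reverse MR, and report generation.

#' Assemble an analysis plan
#'
#' Bundles everything one study run needs. Exposure entries are lists
#' with `trait_id`, `measure` (`"AB"` or `"PA"`), `sumstats` (data frame
#' or TSV path) and optionally `instruments` (explicit variant ids; when
#' absent, [select_by_threshold()] at `instrument_threshold` is used) and
#' `lenient_pairs` (a pre-harmonized multi-SNP pairs table per outcome
#' site for the pleiotropy-robust battery). Outcomes are a named list of
#' summary tables (or paths), one per site.
#'
#' @param exposures List of exposure entries (see Details).
#' @param outcomes Named list of outcome summary tables; names are site
#'   labels, e.g. `overall`, `distal`, `proximal`, `colon`, `rectal`.
#' @param seed Integer seed (mandatory: bootstraps depend on it).
#' @param instrument_threshold Forward-selection p-value threshold
#'   (default 2.5e-8).
#' @param flag_p Forward p-value below which a trait enters the
#'   sensitivity battery (default 0.05).
#' @param catalogue Optional association catalogue (data frame or path)
#'   for the pleiotropy screen.
#' @param regional Optional named list (by trait id) of regional datasets
#'   (as from [make_regional_dataset()]) for colocalisation.
#' @param reverse Optional reverse-MR input: list with `exposure` (disease
#'   summary table restricted to candidate instruments), `ld` (square
#'   correlation matrix), `outcomes` (named list of microbial-trait
#'   summary tables), and optionally `clump_r2` (default 0.001) and
#'   `threshold` (default 5e-8).
#' @param n_boot Bootstrap draws for median/mode SEs (default 5000).
#' @return An `analysis_plan` list.
#' @export
analysis_plan <- function(exposures, outcomes, seed,
                          instrument_threshold = 2.5e-8,
                          flag_p = 0.05,
                          catalogue = NULL, regional = NULL,
                          reverse = NULL, n_boot = 5000) {
  if (missing(seed) || is.null(seed)) stop_usage("seed is mandatory")
  if (length(exposures) < 1L || length(outcomes) < 1L)
    stop_usage("need at least one exposure and one outcome")
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes))))
    stop_usage("outcomes must be a named list of site tables")
  structure(
    list(exposures = exposures, outcomes = outcomes,
         seed = as.integer(seed),
         instrument_threshold = instrument_threshold,
         flag_p = flag_p, catalogue = catalogue, regional = regional,
         reverse = reverse, n_boot = n_boot),
    class = "analysis_plan"
  )
}

resolve_sumstats <- function(x, ...) {
  if (is.character(x)) read_sumstats(x, ...) else x
}

## One forward estimate row; the estimator is chosen by instrument count.
estimate_row <- function(pairs, trait_id, measure, site, n_boot, seed) {
  kept <- kept_pairs(pairs)
  exposure_type <- if (measure == "PA") "binary" else "continuous"
  if (nrow(kept) == 0L) {
    return(data.frame(trait_id = trait_id, measure = measure, site = site,
                      method = NA_character_, n_snp = 0L,
                      beta = NA_real_, se = NA_real_, or = NA_real_,
                      or_low = NA_real_, or_high = NA_real_,
                      pvalue = NA_real_, q_stat = NA_real_, q_p = NA_real_,
                      status = "no_instrument",
                      stringsAsFactors = FALSE))
  }
  est <- if (nrow(kept) == 1L) wald_ratio(kept, exposure_type)
    else mr_ivw(kept, exposure_type = exposure_type)
  if (measure == "PA") est <- scale_binary_exposure(est)
  or <- to_odds_ratio(est)
  data.frame(trait_id = trait_id, measure = measure, site = site,
             method = est$method, n_snp = est$n_snp,
             beta = est$beta, se = est$se,
             or = or[["or"]], or_low = or[["or_low"]],
             or_high = or[["or_high"]], pvalue = est$pvalue,
             q_stat = if (is.null(est$q_stat)) NA_real_ else est$q_stat,
             q_p = if (is.null(est$q_p)) NA_real_ else est$q_p,
             status = "ok", stringsAsFactors = FALSE)
}

#' Run the forward MR analyses
#'
#' Per exposure and outcome site: instrument selection, harmonization,
#' Wald ratio (single SNP) or fixed-effects IVW (multiple SNPs), with
#' presence/absence exposures rescaled to a doubling of liability. Every
#' exposure-by-site combination appears in the output with a status; no
#' trait is silently dropped.
#'
#' @param plan An [analysis_plan()].
#' @return Data frame of result rows (one per exposure x site).
#' @export
run_forward <- function(plan) {
  rows <- list()
  for (exp in plan$exposures) {
    sumstats <- resolve_sumstats(exp$sumstats)
    ids <- if (!is.null(exp$instruments)) exp$instruments
      else select_by_threshold(sumstats, plan$instrument_threshold)$variant_ids
    inst <- sumstats[sumstats$variant_id %in% ids, , drop = FALSE]
    for (site in names(plan$outcomes)) {
      outcome <- resolve_sumstats(plan$outcomes[[site]])
      pairs <- if (nrow(inst)) harmonize(inst, outcome) else
        data.frame(variant_id = character(0), action = character(0))
      rows[[length(rows) + 1L]] <- estimate_row(
        pairs, exp$trait_id, exp$measure, site, plan$n_boot, plan$seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Pleiotropy-robust battery on one multi-SNP pairs table.
robust_battery <- function(pairs, trait_id, site, exposure_type,
                           n_boot, seed) {
  kept <- kept_pairs(pairs)
  ests <- list(
    mr_ivw(kept, exposure_type = exposure_type),
    mr_egger(kept, exposure_type = exposure_type),
    weighted_median(kept, n_boot = n_boot, seed = seed,
                    exposure_type = exposure_type),
    weighted_mode(kept, n_boot = n_boot, seed = seed + 1L,
                  exposure_type = exposure_type)
  )
  do.call(rbind, lapply(ests, function(e) {
    if (identical(e$exposure_unit, "per_log_odds"))
      e <- scale_binary_exposure(e)
    or <- to_odds_ratio(e)
    data.frame(trait_id = trait_id, site = site, method = e$method,
               n_snp = e$n_snp, beta = e$beta, se = e$se,
               or = or[["or"]], or_low = or[["or_low"]],
               or_high = or[["or_high"]], pvalue = e$pvalue,
               egger_intercept = if (is.null(e$egger_intercept)) NA_real_
                 else e$egger_intercept,
               egger_intercept_p = if (is.null(e$egger_intercept_p)) NA_real_
                 else e$egger_intercept_p,
               stringsAsFactors = FALSE)
  }))
}

#' Run the sensitivity battery
#'
#' For every trait whose forward result reaches `plan$flag_p` at any
#' site: the lenient multi-SNP multi-estimator table (IVW, MR-Egger,
#' weighted median, weighted mode) with Cochran's Q and leave-one-out,
#' colocalisation when regional data are available (skipped with a
#' warning otherwise), and the catalogue pleiotropy screen when a
#' catalogue is supplied.
#'
#' @param plan An [analysis_plan()].
#' @param forward Result table from [run_forward()].
#' @return List with `flagged`, `robust`, `heterogeneity`,
#'   `leave_one_out`, `coloc`, `screen` components (empty when
#'   inapplicable).
#' @export
run_sensitivity <- function(plan, forward) {
  ok <- forward$status == "ok" & !is.na(forward$pvalue)
  flagged <- unique(forward$trait_id[ok & forward$pvalue < plan$flag_p])
  out <- list(flagged = flagged, robust = NULL, heterogeneity = NULL,
              leave_one_out = NULL, coloc = list(), screen = list())
  exps <- plan$exposures[vapply(plan$exposures,
                                function(e) e$trait_id %in% flagged,
                                logical(1))]
  for (exp in exps) {
    exposure_type <- if (exp$measure == "PA") "binary" else "continuous"
    if (!is.null(exp$lenient_pairs)) {
      for (site in names(exp$lenient_pairs)) {
        pairs <- kept_pairs(exp$lenient_pairs[[site]])
        if (nrow(pairs) >= 3L) {
          out$robust <- rbind(out$robust, robust_battery(
            pairs, exp$trait_id, site, exposure_type,
            plan$n_boot, plan$seed))
          q <- cochrans_q(pairs)
          out$heterogeneity <- rbind(out$heterogeneity, data.frame(
            trait_id = exp$trait_id, site = site, q_stat = q$q_stat,
            q_df = q$q_df, q_p = q$q_p, stringsAsFactors = FALSE))
          loo <- leave_one_out(pairs)
          loo$trait_id <- exp$trait_id
          loo$site <- site
          out$leave_one_out <- rbind(out$leave_one_out, loo)
        }
      }
    }
    if (!is.null(plan$regional) && exp$trait_id %in% names(plan$regional)) {
      reg <- plan$regional[[exp$trait_id]]
      region <- extract_region(reg$trait1, reg$trait2, reg$lead_variant_id,
                               trait1_type = if (exp$measure == "PA")
                                 "cc" else "quant")
      out$coloc[[exp$trait_id]] <- coloc_abf(region)
    } else if (!is.null(plan$regional)) {
      warning("no regional data for flagged trait ", exp$trait_id,
              "; colocalisation skipped", call. = FALSE)
    }
    if (!is.null(plan$catalogue)) {
      catalogue <- if (is.character(plan$catalogue))
        load_catalogue(plan$catalogue) else plan$catalogue
      ids <- if (!is.null(exp$instruments)) exp$instruments
        else select_by_threshold(resolve_sumstats(exp$sumstats),
                                 plan$instrument_threshold)$variant_ids
      for (id in ids)
        out$screen[[paste(exp$trait_id, id, sep = ":")]] <-
          screen_variant(id, catalogue)
    }
  }
  out
}

#' Run reverse MR (disease as exposure)
#'
#' Clumps the disease instruments at `clump_r2` (default 0.001) via
#' [greedy_clump()], harmonizes each microbial-trait outcome to them, and
#' applies IVW plus the robust estimators.
#'
#' @param plan An [analysis_plan()] with a `reverse` component.
#' @return Data frame of reverse-MR rows (one per trait x method).
#' @export
run_reverse <- function(plan) {
  rev <- plan$reverse
  if (is.null(rev)) stop_usage("plan has no reverse-MR inputs")
  exposure <- resolve_sumstats(rev$exposure)
  threshold <- if (is.null(rev$threshold)) 5e-8 else rev$threshold
  clump_r2 <- if (is.null(rev$clump_r2)) 0.001 else rev$clump_r2
  cand <- exposure[exposure$pvalue < threshold, , drop = FALSE]
  clumped <- greedy_clump(cand, rev$ld[cand$variant_id, cand$variant_id,
                                       drop = FALSE],
                          r2_threshold = clump_r2)
  inst <- exposure[exposure$variant_id %in% clumped$variant_ids, ,
                   drop = FALSE]
  rows <- NULL
  for (trait in names(rev$outcomes)) {
    outcome <- resolve_sumstats(rev$outcomes[[trait]])
    pairs <- kept_pairs(harmonize(inst, outcome))
    if (nrow(pairs) < 2L) {
      rows <- rbind(rows, data.frame(
        trait_id = trait, site = "reverse", method = NA_character_,
        n_snp = nrow(pairs), beta = NA_real_, se = NA_real_,
        or = NA_real_, or_low = NA_real_, or_high = NA_real_,
        pvalue = NA_real_, egger_intercept = NA_real_,
        egger_intercept_p = NA_real_, status = "no_instrument",
        stringsAsFactors = FALSE))
      next
    }
    batt <- robust_battery(pairs, trait, "reverse", "continuous",
                           plan$n_boot, plan$seed)
    batt$status <- "ok"
    rows <- rbind(rows, batt)
  }
  rownames(rows) <- NULL
  rows
}

#' Write the report bundle
#'
#' Writes result tables as TSV plus a JSON manifest carrying the package
#' version, seed, a hash of the result content and row counts, so a rerun
#' with the same configuration is verifiably identical.
#'
#' @param results Named list of data frames (e.g. `forward`, `reverse`)
#'   and/or nested sensitivity output.
#' @param dir Output directory (created if needed).
#' @param seed Seed used for the run (recorded in the manifest).
#' @return Invisibly, the manifest list.
#' @export
write_report <- function(results, dir, seed = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- Filter(is.data.frame, results)
  counts <- list()
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts[[nm]] <- nrow(tables[[nm]])
  }
  ## content hash: md5 of the serialized tables (written canonically)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(tables, tmp, digits = 10)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    package = "micromr",
    version = as.character(utils::packageVersion("micromr")),
    seed = seed,
    content_md5 = hash,
    tables = counts,
    created = "run-time"   # deliberately constant: manifests diff clean
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
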