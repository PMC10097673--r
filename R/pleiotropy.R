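# Offline horizontal-pleiotropy screen: look up instrument variants in a
# local association catalogue (a PhenoScanner/OpenGWAS-style dump) at a
# multiple-testing threshold and classify the hits.

CATALOGUE_CLASSES <- c("complex_trait", "eQT", "metabolite", "mQT",
                       "protein", "other")

#' Load an association catalogue
#'
#' Reads a tab-delimited catalogue with columns `variant_id`, `trait_name`,
#' `trait_class`, `pvalue`, `source`. Rows with a p-value outside (0, 1]
#' are skipped with a warning; unknown trait classes are mapped to
#' `"other"`.
#'
#' @param path Catalogue TSV path.
#' @return Data frame of validated entries.
#' @export
load_catalogue <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  need <- c("variant_id", "trait_name", "trait_class", "pvalue", "source")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop_usage("catalogue missing column(s): ", paste(missing, collapse = ", "))
  x$pvalue <- as.numeric(x$pvalue)
  ok <- !is.na(x$pvalue) & x$pvalue > 0 & x$pvalue <= 1
  if (any(!ok)) {
    warning(sum(!ok), " catalogue row(s) with invalid p-values skipped ",
            "(lines ", paste(which(!ok) + 1L, collapse = ", "), ")",
            call. = FALSE)
    x <- x[ok, , drop = FALSE]
  }
  x$trait_class[!x$trait_class %in% CATALOGUE_CLASSES] <- "other"
  rownames(x) <- NULL
  x
}

#' Write an association catalogue
#'
#' @param x Catalogue data frame.
#' @param path Output path.
#' @export
write_catalogue <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Screen an instrument variant for reported associations
#'
#' Counts catalogue entries for the variant with `pvalue` strictly below
#' `threshold`, grouped by trait class. A variant absent from the
#' catalogue yields an empty report (all counts zero), not an error. The
#' verdict is `"high_pleiotropy_concern"` when the number of complex-trait
#' hits exceeds `high_concern_cutoff`; this cutoff is an explicit knob
#' because the underlying judgement is qualitative.
#'
#' @param variant_id Variant to screen.
#' @param catalogue Data frame from [load_catalogue()].
#' @param threshold P-value threshold (default 1e-4, a 10% Bonferroni
#'   correction for 1000 catalogue results; see [derive_threshold()]).
#' @param high_concern_cutoff Complex-trait hit count above which the
#'   verdict flips (default 10).
#' @return A `screen_report` list: `variant_id`, `threshold`, per-class
#'   `counts`, `flagged` (the sub-threshold entries), `verdict`.
#' @export
screen_variant <- function(variant_id, catalogue, threshold = 1e-4,
                           high_concern_cutoff = 10) {
  hits <- catalogue[catalogue$variant_id == variant_id &
                      catalogue$pvalue < threshold, , drop = FALSE]
  counts <- vapply(CATALOGUE_CLASSES,
                   function(cl) sum(hits$trait_class == cl), integer(1))
  structure(
    list(variant_id = variant_id,
         threshold = threshold,
         counts = counts,
         flagged = hits[order(hits$pvalue, hits$trait_name), , drop = FALSE],
         verdict = if (counts[["complex_trait"]] > high_concern_cutoff)
           "high_pleiotropy_concern" else "low_pleiotropy_concern"),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %s at p < %g: %d association(s)\n",
              x$variant_id, x$threshold, sum(x$counts)))
  print(x$counts)
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

#' Multiple-testing threshold for the catalogue screen
#'
#' A fractional Bonferroni correction: `fraction / n_results`. The default
#' (10% over the 1000 results a catalogue query returns) gives the 1e-4
#' screening threshold; the discount acknowledges that catalogue traits
#' are heavily correlated.
#'
#' @param n_results Number of catalogue results corrected over
#'   (default 1000).
#' @param fraction Family-wise error budget (default 0.10).
#' @return P-value threshold.
#' @export
derive_threshold <- function(n_results = 1000, fraction = 0.10) {
  if (n_results < 1) stop_usage("n_results must be >= 1")
  fraction / n_results
}

#' Write a screen report
#'
#' TSV of flagged entries plus a JSON sidecar with counts and verdict.
#'
#' @param report A `screen_report`.
#' @param path Output TSV path (`.json` sidecar written alongside).
#' @export
write_screen_report <- function(report, path) {
  utils::write.table(report$flagged, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(variant_id = report$variant_id, threshold = report$threshold,
         counts = as.list(report$counts), verdict = report$verdict),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
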