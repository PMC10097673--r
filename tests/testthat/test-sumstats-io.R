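# Summary-statistics I/O and harmonization.

test_that("read_sumstats validates rows, maps columns and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  x <- make_sumstats()
  write_sumstats(x, path)
  y <- read_sumstats(path)
  expect_equal(nrow(y), 3)
  expect_equal(y$beta, x$beta)
  expect_equal(y$variant_id, x$variant_id)

  # bespoke column names via the map
  z <- x
  names(z)[names(z) == "variant_id"] <- "SNP"
  names(z)[names(z) == "beta"] <- "b"
  write_sumstats(z, path)
  y2 <- read_sumstats(path, column_map = c(variant_id = "SNP", beta = "b"))
  expect_equal(y2$beta, x$beta)

  # se = 0 row is skipped with a warning carrying the line number
  bad <- x
  bad$se[2] <- 0
  write_sumstats(bad, path)
  expect_warning(y3 <- read_sumstats(path), "lines 3")
  expect_equal(nrow(y3), 2)
  expect_false("rs2" %in% y3$variant_id)

  # missing mandatory column is a configuration error
  write_sumstats(x[, setdiff(names(x), "se")], path)
  expect_error(read_sumstats(path), "mandatory")
})

test_that("is_palindromic follows the A/T, C/G rule", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_equal(is_palindromic(c("a", "C", "T"), c("t", "G", "G")),
               c(TRUE, TRUE, FALSE))
  expect_error(is_palindromic("A", "N"), "alleles")
})

test_that("harmonize covers every action class", {
  exposure <- make_sumstats(
    variant_id = c("rs_keep", "rs_swap", "rs_strand", "rs_strand_swap",
                   "rs_pal_drop", "rs_pal_flip", "rs_pal_same",
                   "rs_mismatch"),
    effect_allele = c("A", "A", "A", "A", "A", "A", "C", "A"),
    other_allele  = c("G", "G", "G", "G", "T", "T", "G", "G"),
    beta = rep(0.1, 8), se = rep(0.02, 8),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.45, 0.10, 0.20, 0.3),
    pos = seq_len(8) * 1e6
  )
  outcome <- make_sumstats(
    variant_id = exposure$variant_id,
    effect_allele = c("A", "G", "T", "C", "A", "A", "C", "A"),
    other_allele  = c("G", "A", "C", "T", "T", "T", "G", "C"),
    beta = rep(0.05, 8), se = rep(0.01, 8),
    eaf = c(0.3, 0.7, 0.3, 0.7, 0.45, 0.88, 0.25, 0.3),
    pos = seq_len(8) * 1e6
  )
  h <- harmonize(exposure, outcome)
  act <- setNames(h$action, h$variant_id)
  expect_equal(act[["rs_keep"]], "kept")
  expect_equal(act[["rs_swap"]], "outcome_sign_flipped")
  expect_equal(act[["rs_strand"]], "strand_flipped")
  expect_equal(act[["rs_strand_swap"]], "outcome_sign_flipped")
  expect_equal(act[["rs_pal_drop"]], "dropped_palindromic_ambiguous")
  expect_equal(act[["rs_pal_flip"]], "palindromic_inferred")
  expect_equal(act[["rs_pal_same"]], "palindromic_inferred")
  expect_equal(act[["rs_mismatch"]], "dropped_allele_mismatch")

  # sign rule: swapped alleles negate the outcome beta and reflect eaf
  expect_equal(h$outcome_beta[h$variant_id == "rs_swap"], -0.05)
  expect_equal(h$outcome_eaf[h$variant_id == "rs_swap"], 0.3)
  # discordant palindromic frequency: flip applied
  expect_equal(h$outcome_beta[h$variant_id == "rs_pal_flip"], -0.05)
  expect_equal(h$outcome_eaf[h$variant_id == "rs_pal_flip"], 0.12)
  # concordant palindromic: no flip
  expect_equal(h$outcome_beta[h$variant_id == "rs_pal_same"], 0.05)

  # single-pair id mismatch is a usage error
  expect_error(harmonize(exposure[1, ], outcome[2, ]), "mismatch")
})

test_that("missing eaf on a palindromic variant drops it", {
  exposure <- make_sumstats(variant_id = "rs_pal", effect_allele = "A",
                            other_allele = "T", beta = 0.1, se = 0.02,
                            eaf = NA, pos = 1e6)
  outcome <- make_sumstats(variant_id = "rs_pal", effect_allele = "A",
                           other_allele = "T", beta = 0.05, se = 0.01,
                           eaf = 0.2, pos = 1e6)
  h <- harmonize(exposure, outcome)
  expect_equal(h$action, "dropped_palindromic_ambiguous")
})

test_that("harmonization properties hold over random instances", {
  set.seed(41)
  alleles <- c("A", "C", "G", "T")
  for (rep in 1:25) {
    k <- 30
    ea <- sample(alleles, k, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")
    eaf_x <- runif(k, 0.02, 0.98)
    eaf_y <- pmin(pmax(eaf_x + rnorm(k, 0, 0.03), 0.01), 0.99)
    exposure <- make_sumstats(sprintf("rs%03d", 1:k), ea, oa,
                              beta = rnorm(k, 0, 0.2),
                              se = runif(k, 0.01, 0.05),
                              eaf = eaf_x, pos = (1:k) * 1e5)
    flip <- runif(k) < 0.5
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    strand <- runif(k) < 0.5
    ea_y <- ifelse(flip, oa, ea)
    oa_y <- ifelse(flip, ea, oa)
    ea_y <- ifelse(strand, comp[ea_y], ea_y)
    oa_y <- ifelse(strand, comp[oa_y], oa_y)
    outcome <- make_sumstats(sprintf("rs%03d", 1:k), ea_y, oa_y,
                             beta = rnorm(k, 0, 0.1) * ifelse(flip, -1, 1),
                             se = runif(k, 0.01, 0.05),
                             eaf = ifelse(flip, 1 - eaf_y, eaf_y),
                             pos = (1:k) * 1e5)
    h <- harmonize(exposure, outcome)

    # non-dropped pairs carry the exposure's alleles
    kept <- kept_pairs(h)
    expect_equal(kept$effect_allele,
                 exposure$effect_allele[match(kept$variant_id,
                                              exposure$variant_id)])

    # count contract: palindromic drops = palindromic with MAF > 0.42 in
    # either dataset (missing eaf also non-inferable; none here)
    pal <- is_palindromic(ea, oa)
    maf_x <- pmin(eaf_x, 1 - eaf_x)
    eaf_y_oriented <- ifelse(flip, 1 - eaf_y, eaf_y)
    maf_y <- pmin(eaf_y_oriented, 1 - eaf_y_oriented)
    expect_equal(sum(h$action == "dropped_palindromic_ambiguous"),
                 sum(pal & (maf_x > 0.42 | maf_y > 0.42)))

    # idempotence: re-harmonizing survivors changes no values; all
    # non-palindromic survivors come back "kept" and none are dropped
    as_sumstats <- function(p, side) {
      data.frame(variant_id = p$variant_id,
                 effect_allele = p$effect_allele,
                 other_allele = p$other_allele,
                 eaf = p[[paste0(side, "_eaf")]],
                 beta = p[[paste0(side, "_beta")]],
                 se = p[[paste0(side, "_se")]],
                 pvalue = 0.5, stringsAsFactors = FALSE)
    }
    h2 <- harmonize(as_sumstats(kept, "exposure"),
                    as_sumstats(kept, "outcome"))
    expect_equal(h2$outcome_beta, kept$outcome_beta)
    expect_equal(h2$outcome_eaf, kept$outcome_eaf)
    pal2 <- is_palindromic(h2$effect_allele, h2$other_allele)
    expect_true(all(h2$action[!pal2] == "kept"))
    expect_true(all(h2$action[pal2] == "palindromic_inferred"))
  }
})

test_that("relabelling the outcome file leaves causal estimates unchanged", {
  set.seed(42)
  exposure <- make_sumstats(sprintf("rs%d", 1:5),
                            effect_allele = c("A", "C", "G", "T", "A"),
                            other_allele = c("G", "A", "T", "C", "C"),
                            beta = runif(5, 0.2, 0.5),
                            se = runif(5, 0.01, 0.03),
                            eaf = runif(5, 0.1, 0.4), pos = (1:5) * 1e6)
  outcome <- exposure
  outcome$beta <- 0.3 * exposure$beta + rnorm(5, 0, 0.02)
  outcome$se <- runif(5, 0.01, 0.03)
  # flipped representation of the identical outcome data
  flipped <- outcome
  flipped$effect_allele <- outcome$other_allele
  flipped$other_allele <- outcome$effect_allele
  flipped$beta <- -outcome$beta
  flipped$eaf <- 1 - outcome$eaf
  est1 <- mr_ivw(kept_pairs(harmonize(exposure, outcome)))
  est2 <- mr_ivw(kept_pairs(harmonize(exposure, flipped)))
  expect_equal(est1$beta, est2$beta, tolerance = 1e-12)
  expect_equal(est1$se, est2$se, tolerance = 1e-12)
})

test_that("write_harmonized fixes column order and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  p <- random_pairs(3)
  p$action[3] <- "dropped_allele_mismatch"
  write_harmonized(p, path)
  r <- read_harmonized(path)
  expect_equal(names(r), micromr:::HARMONIZED_COLUMNS)
  expect_equal(nrow(r), 3)
  expect_equal(sum(startsWith(r$action, "dropped")), 1)
  expect_equal(r$outcome_beta, p$outcome_beta)

  # empty collection: header-only file
  write_harmonized(p[0, ], path)
  expect_equal(nrow(read_harmonized(path)), 0)
  expect_equal(length(readLines(path)), 1)
})
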