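# Causal estimators and diagnostics.

test_that("wald_ratio computes the ratio and delta-method se", {
  p <- pairs_from(0.5, 0.1, ose = 0.02)
  est <- wald_ratio(p)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.04)
  expect_equal(est$ci_low, 0.2 - 1.96 * 0.04, tolerance = 1e-12)

  expect_equal(wald_ratio(pairs_from(0.5, 0))$beta, 0)
  expect_error(wald_ratio(pairs_from(0, 0.1)), "undefined")
  expect_error(wald_ratio(random_pairs(2)), "exactly one")
  # dropped pairs are excluded before estimation
  p2 <- rbind(p, p)
  p2$action[2] <- "dropped_allele_mismatch"
  expect_equal(wald_ratio(p2)$beta, 0.2)
})

test_that("mr_ivw matches the hand case and degenerates to Wald", {
  p <- pairs_from(c(0.5, 0.5), c(0.1, 0.2), ose = c(0.02, 0.02))
  expect_equal(mr_ivw(p)$beta, 0.3, tolerance = 1e-12)

  one <- pairs_from(0.4, 0.12, ose = 0.03)
  same <- rbind(one, one, one)
  same$variant_id <- paste0("rs", 1:3)
  expect_equal(mr_ivw(same)$beta, wald_ratio(one)$beta, tolerance = 1e-12)
  expect_error(mr_ivw(one), ">= 2")
})

test_that("IVW and Egger equal independent WLS oracles on random data", {
  set.seed(23)
  for (rep in 1:100) {
    p <- random_pairs(sample(3:12, 1), beta_xy = runif(1, -0.5, 0.5))
    w <- 1 / p$outcome_se^2
    ivw <- mr_ivw(p)
    expect_equal(ivw$beta,
                 wls_oracle(p$exposure_beta, p$outcome_beta, w,
                            intercept = FALSE),
                 tolerance = 1e-10)
    expect_equal(ivw$se, sqrt(1 / sum(w * p$exposure_beta^2)),
                 tolerance = 1e-10)
    eg <- mr_egger(p)
    cf <- wls_oracle(p$exposure_beta, p$outcome_beta, w)
    expect_equal(eg$beta, cf[2], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(eg$egger_intercept, cf[1], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("Egger fits collinear data exactly and recovers pleiotropy", {
  p <- pairs_from(c(0.2, 0.4, 0.6, 0.8), 0.3 * c(0.2, 0.4, 0.6, 0.8))
  eg <- suppressWarnings(mr_egger(p))   # lm warns on a perfect fit
  expect_equal(eg$beta, 0.3, tolerance = 1e-10)
  expect_equal(eg$egger_intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(random_pairs(2)), ">= 3")

  # constant directional pleiotropy delta (InSIDE holds): the intercept
  # estimates delta and the slope the true effect, on average
  set.seed(29)
  delta <- 0.03
  sl <- it <- numeric(300)
  for (i in 1:300) {
    p <- random_pairs(10, beta_xy = 0.3, pleiotropy = delta)
    eg <- mr_egger(p)
    sl[i] <- eg$beta
    it[i] <- eg$egger_intercept
  }
  expect_lt(abs(mean(it) - delta), 3 * sd(it) / sqrt(300))
  expect_lt(abs(mean(sl) - 0.3), 3 * sd(sl) / sqrt(300))
})

test_that("weighted median reduces to the sample median and interpolates", {
  p <- pairs_from(c(1, 1, 1), c(0.1, 0.2, 0.9))
  wm <- weighted_median(p, n_boot = 200, seed = 1)
  expect_equal(wm$beta, 0.2)

  # hand evaluation of the cumulative-weight interpolation rule:
  # weights ~ {0.5, 0.5, eps} on ratios {0.1, 0.2, 0.9}
  eps <- 1e-3
  w <- c(0.5, 0.5, eps) / (1 + eps)
  # ratio weights are exposure_beta^2 / outcome_se^2; build se to match
  ose <- sqrt(1 / c(0.5, 0.5, eps))
  p2 <- pairs_from(c(1, 1, 1), c(0.1, 0.2, 0.9), ose = ose)
  wm2 <- weighted_median(p2, n_boot = 200, seed = 1)
  cum <- cumsum(w) - w / 2
  want <- 0.1 + (0.2 - 0.1) * (0.5 - cum[1]) / (cum[2] - cum[1])
  expect_equal(wm2$beta, want, tolerance = 1e-12)
  expect_gt(wm2$beta, 0.1)
  expect_lt(wm2$beta, 0.2)

  # equal weights equal the sample median on random odd-sized sets
  set.seed(31)
  for (i in 1:20) {
    k <- sample(c(3, 5, 7, 9), 1)
    p3 <- pairs_from(rep(1, k), rnorm(k))
    expect_equal(weighted_median(p3, n_boot = 50, seed = 2)$beta,
                 median(p3$outcome_beta), tolerance = 1e-12)
  }
})

test_that("weighted median resists 50% invalid instruments where IVW fails", {
  set.seed(37)
  wm_err <- ivw_err <- numeric(120)
  for (i in 1:120) {
    # 6 valid / 3 invalid instruments with equal weights: the valid
    # majority holds > half the weight (the median's premise) while the
    # invalid SNPs carry large directional pleiotropy
    pleio <- c(rep(0, 6), rep(0.3, 3))
    p <- pairs_from(rep(0.5, 9), 0.3 * 0.5 + pleio + rnorm(9, 0, 0.02))
    wm_err[i] <- weighted_median(p, n_boot = 2, seed = 3)$beta - 0.3
    ivw_err[i] <- mr_ivw(p)$beta - 0.3
  }
  expect_lt(abs(mean(wm_err)), abs(mean(ivw_err)))
  expect_gt(mean(ivw_err), 0.15)         # IVW clearly biased upward
  expect_lt(abs(mean(wm_err)), 0.05)     # median stays near the truth
})

test_that("weighted mode finds the dominant cluster", {
  p <- pairs_from(rep(1, 4), rep(0.42, 4))
  expect_equal(weighted_mode(p, n_boot = 2, seed = 1)$beta, 0.42)

  # grid-search density oracle on {0.20, 0.21, 0.90}
  p2 <- pairs_from(c(1, 1, 1), c(0.20, 0.21, 0.90))
  wm <- weighted_mode(p2, n_boot = 2, seed = 1)
  expect_lt(abs(wm$beta - 0.205), 0.02)

  # doubling phi moves the estimate continuously, not in jumps
  phis <- seq(0.8, 2, by = 0.1)
  est <- vapply(phis, function(ph)
    weighted_mode(p2, phi = ph, n_boot = 2, seed = 1)$beta, numeric(1))
  expect_true(all(abs(diff(est)) < 0.1))
})

test_that("cochrans_q matches direct summation and the df contract", {
  p <- pairs_from(c(0.5, 0.5), c(0.1, 0.1))
  q0 <- cochrans_q(p)
  expect_equal(q0$q_stat, 0, tolerance = 1e-12)
  expect_equal(q0$q_p, 1)

  set.seed(41)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    p <- random_pairs(k)
    ref <- mr_ivw(p)
    q <- cochrans_q(p, ref)
    b <- p$outcome_beta / p$exposure_beta
    w <- p$exposure_beta^2 / p$outcome_se^2
    expect_equal(q$q_stat, sum(w * (b - ref$beta)^2), tolerance = 1e-10)
    expect_equal(q$q_df, k - 1L)
  }
})

test_that("leave_one_out has the right shape and behaviour", {
  p <- random_pairs(3)
  loo <- leave_one_out(p)
  expect_equal(nrow(loo), 4)
  expect_equal(loo$omitted, c(p$variant_id, "(none)"))

  # homogeneous pairs: every row identical
  hom <- pairs_from(c(0.3, 0.4, 0.5), 0.2 * c(0.3, 0.4, 0.5))
  lh <- leave_one_out(hom)
  expect_equal(max(lh$beta) - min(lh$beta), 0, tolerance = 1e-12)

  # omitting an outlying null-effect SNP moves the estimate toward the
  # IVW of the remaining consistent SNPs
  mix <- pairs_from(c(0.5, 0.5, 0.5, 0.5), c(0.15, 0.15, 0.15, 0))
  lm_ <- leave_one_out(mix)
  full <- lm_$beta[lm_$omitted == "(none)"]
  wo_null <- lm_$beta[lm_$omitted == "rs004"]
  expect_gt(wo_null, full)
  expect_equal(wo_null, 0.3, tolerance = 1e-12)
})

test_that("estimators are equivariant under joint sign flips", {
  set.seed(43)
  p <- random_pairs(7, beta_xy = 0.25)
  flip <- p
  flip$exposure_beta <- -p$exposure_beta
  flip$outcome_beta <- -p$outcome_beta
  expect_equal(mr_ivw(flip)$beta, mr_ivw(p)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(flip)$beta, mr_egger(p)$beta, tolerance = 1e-10)
  expect_equal(weighted_median(flip, n_boot = 2, seed = 5)$beta,
               weighted_median(p, n_boot = 2, seed = 5)$beta,
               tolerance = 1e-12)
  expect_equal(weighted_mode(flip, n_boot = 2, seed = 5)$beta,
               weighted_mode(p, n_boot = 2, seed = 5)$beta,
               tolerance = 1e-9)
})

test_that("binary-exposure scaling and odds-ratio conversion", {
  p <- pairs_from(0.5, 0.1111 * 0.5, ose = 0.05)
  est <- wald_ratio(p, exposure_type = "binary")
  expect_equal(est$exposure_unit, "per_log_odds")
  sc <- scale_binary_exposure(est)
  expect_equal(sc$beta, 0.1111 * log(2), tolerance = 1e-10)
  expect_equal(unname(to_odds_ratio(sc)["or"]), exp(0.1111 * log(2)),
               tolerance = 1e-10)
  expect_equal(sc$exposure_unit, "per_doubling_liability")
  # continuous estimates refuse the conversion
  expect_error(scale_binary_exposure(wald_ratio(p)), "binary")

  # OR presentation: beta 0, se 0.1 -> 1.00 (0.82, 1.22)
  est0 <- micromr:::new_mr_estimate("wald_ratio", 0, 0.1, 1L)
  or <- to_odds_ratio(est0)
  expect_equal(unname(or), c(1, exp(-0.196), exp(0.196)), tolerance = 1e-9)
  expect_equal(round(unname(or), 2), c(1.00, 0.82, 1.22))
  # inverse identity
  est1 <- micromr:::new_mr_estimate("ivw", log(1.41), 0.1, 2L)
  expect_equal(unname(to_odds_ratio(est1)["or"]), 1.41, tolerance = 1e-12)
})
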