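test_that("the Wald ratio follows the delta rule and its sign convention", {
  d <- tibble::tibble(beta_exp = 1, se_exp = 0.05, beta_out = 0.5, se_out = 0.1)
  r <- mr_wald_ratio(d)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1)
  d0 <- dplyr::mutate(d, beta_out = 0)
  expect_equal(mr_wald_ratio(d0)$beta, 0)
  expect_equal(mr_wald_ratio(d0)$pval, 1)
  dneg <- tibble::tibble(beta_exp = -0.2, se_exp = 0.02, beta_out = 0.4, se_out = 0.1)
  expect_equal(sign(mr_wald_ratio(dneg)$beta), -1)
  expect_error(mr_wald_ratio(dplyr::mutate(d, beta_exp = 0)), "nonzero")
})

test_that("IVW equals the equal-information average on the two-point case", {
  d <- tibble::tibble(beta_exp = c(1, 1), se_exp = 0.05,
                      beta_out = c(0.5, 0.5), se_out = c(0.1, 0.1))
  r <- mr_ivw(d, mode = "fixed")
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1 / sqrt(2))
  expect_lt(r$ci_low, r$beta)
  expect_gt(r$ci_high, r$beta)
})

test_that("IVW fixed matches the WLS-through-origin oracle on 100 random sets", {
  for (seed in 1:100) {
    d <- make_harmonized(k = sample(3:15, 1), beta = runif(1, -0.5, 0.5),
                         seed = seed)
    r <- mr_ivw(d, mode = "fixed")
    expect_equal(r$beta, oracle_wls_origin(d$beta_exp, d$beta_out, d$se_out),
                 tolerance = 1e-10)
  }
})

test_that("random-effects IVW floors the dispersion scale at one", {
  # homogeneous data: Q below its df, random must equal fixed
  d <- tibble::tibble(beta_exp = c(1, 1, 1), se_exp = 0.01,
                      beta_out = c(0.500, 0.501, 0.499), se_out = 0.1)
  rf <- mr_ivw(d, mode = "fixed")
  rr <- mr_ivw(d, mode = "random")
  expect_lt(rf$q_stat, 2)
  expect_equal(rr$se, rf$se)
  expect_equal(rr$beta, rf$beta)
  # heterogeneous data: random inflates and auto switches
  dh <- make_harmonized(k = 10, beta = 0.3, seed = 1)
  dh$beta_out <- dh$beta_out + rep(c(-0.5, 0.5), 5)
  rh <- mr_ivw(dh, mode = "auto")
  expect_equal(rh$method, "ivw_random")
  expect_lt(rh$q_pval, 0.05)
  expect_gt(rh$se, mr_ivw(dh, mode = "fixed")$se)
})

test_that("MR-Egger recovers an exact linear law and reduces to OLS with equal weights", {
  bx <- seq(0.05, 0.30, length.out = 6)
  d <- tibble::tibble(beta_exp = bx, se_exp = 0.01,
                      beta_out = 0.1 + 0.3 * bx, se_out = 0.05)
  r <- mr_egger(d)
  expect_equal(r$beta, 0.3, tolerance = 1e-12)
  expect_equal(r$egger_intercept, 0.1, tolerance = 1e-12)
  expect_equal(r$q_stat, 0, tolerance = 1e-20)

  d2 <- make_harmonized(k = 8, beta = 0.2, seed = 7)
  d2$se_out <- 0.05     # equal weights
  r2 <- mr_egger(d2)
  ols <- lm(beta_out ~ beta_exp, data = d2)
  expect_equal(r2$beta, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(r2$egger_intercept, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_error(mr_egger(d2[1:2, ]), "at least 3")
})

test_that("Egger with the intercept constrained to zero is IVW", {
  d <- make_harmonized(k = 9, beta = 0.25, seed = 13)
  # oracle: the same weighted regression without intercept
  slope0 <- oracle_wls_origin(d$beta_exp, d$beta_out, d$se_out)
  expect_equal(mr_ivw(d, mode = "fixed")$beta, slope0, tolerance = 1e-12)
})

test_that("Egger orientation makes the fit invariant to exposure sign flips", {
  d <- make_harmonized(k = 8, beta = 0.2, seed = 3)
  flipped <- d
  flip <- c(1, 3, 5)
  flipped$beta_exp[flip] <- -flipped$beta_exp[flip]
  flipped$beta_out[flip] <- -flipped$beta_out[flip]
  expect_equal(mr_egger(flipped)$beta, mr_egger(d)$beta)
  expect_equal(mr_egger(flipped)$egger_intercept, mr_egger(d)$egger_intercept)
})

test_that("the weighted median interpolates correctly and matches the knot oracle", {
  # equal weights, ratios 1,2,3 -> the middle ratio
  d <- tibble::tibble(beta_exp = c(1, 1, 1), se_exp = 0.01,
                      beta_out = c(1, 2, 3), se_out = 1)
  r <- mr_weighted_median(d, n_boot = 50, seed = 1)
  expect_equal(r$beta, 2)

  for (seed in 1:25) {
    d <- make_harmonized(k = sample(3:12, 1), beta = runif(1, -0.4, 0.4),
                         seed = 200 + seed)
    est <- mr_weighted_median(d, n_boot = 2, seed = 1)$beta
    ref <- oracle_weighted_median(d$beta_out / d$beta_exp,
                                  (d$beta_exp / d$se_out)^2)
    expect_equal(est, ref)
  }
})

test_that("the weighted median is scale-invariant in the weights and reproducible", {
  d <- make_harmonized(k = 7, beta = 0.3, seed = 5)
  a <- mr_weighted_median(d, n_boot = 100, seed = 42)
  d2 <- dplyr::mutate(d, se_out = se_out / sqrt(2))  # doubles every weight
  b <- mr_weighted_median(d2, n_boot = 100, seed = 42)
  expect_equal(a$beta, b$beta)
  # same seed, same bootstrap SE
  expect_identical(a$se, mr_weighted_median(d, n_boot = 100, seed = 42)$se)
  # zero-exposure records are excluded with a warning
  dz <- d
  dz$beta_exp[1] <- 0
  expect_warning(rz <- mr_weighted_median(dz, n_boot = 10, seed = 1), "beta_exp = 0")
  expect_equal(rz$k, 6)
})

test_that("Cochran's Q matches hand arithmetic and is order-invariant", {
  d <- tibble::tibble(beta_exp = c(1, 1), se_exp = 0.01,
                      beta_out = c(0.4, 0.6), se_out = c(0.1, 0.1))
  q <- cochran_q(d, beta_ref = 0.5)
  expect_equal(q$q_stat, 2)           # 100*0.01 + 100*0.01
  expect_equal(q$df, 1)
  # exact ratios -> zero heterogeneity
  d2 <- tibble::tibble(beta_exp = c(1, 2, 3), se_exp = 0.01,
                       beta_out = c(0.5, 1.0, 1.5), se_out = 0.1)
  q2 <- cochran_q(d2, beta_ref = 0.5)
  expect_equal(q2$q_stat, 0)
  expect_equal(q2$i2, 0)
  d3 <- make_harmonized(k = 9, beta = 0.2, seed = 77)
  expect_equal(cochran_q(d3, 0.2)$q_stat,
               cochran_q(d3[sample(9), ], 0.2)$q_stat)
})

test_that("tidy and glance return one-row broom-style summaries", {
  d <- make_harmonized(k = 6, beta = 0.3, seed = 8)
  r <- mr_egger(d)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("exposure", "outcome", "method", "estimate", "std.error",
                     "statistic", "p.value", "conf.low", "conf.high", "k"))
  gl <- glance(r)
  expect_equal(gl$egger_intercept, r$egger_intercept)
})
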