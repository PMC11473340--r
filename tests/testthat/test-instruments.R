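test_that("p-value selection is strict and monotone in the threshold", {
  raw <- make_raw_sumstats(10, seed = 2)
  raw$pval <- c(4e-8, 5e-8, 1e-6, rep(0.5, 7))
  ss <- as_sumstats(raw, quiet = TRUE)
  sel <- select_by_pvalue(ss, 5e-8)
  expect_equal(sel$snp_id, "rs001")      # strictly below, order preserved
  expect_equal(nrow(select_by_pvalue(ss, 1e-12)), 0)
  thresholds <- c(5e-8, 5e-7, 5e-6, 1e-5)
  ks <- vapply(thresholds, function(p) nrow(select_by_pvalue(ss, p)), numeric(1))
  expect_true(all(diff(ks) >= 0))
  expect_error(select_by_pvalue(ss, 0), "0, 1")
})

test_that("clumping keeps the smaller-p variant of a correlated nearby pair", {
  raw <- make_raw_sumstats(2, seed = 4)
  raw$chrom <- "1"
  raw$pos <- c(1e6, 1e6 + 100e3)       # 100 kb apart
  raw$pval <- c(1e-9, 1e-12)
  ss <- as_sumstats(raw, quiet = TRUE)
  ld <- ld_info(tibble::tibble(snp_a = "rs001", snp_b = "rs002", r2 = 0.5))
  kept <- clump(ss, ld, window_kb = 250, r2_max = 0.01)
  expect_equal(kept$snp_id, "rs002")
  # independent pair is untouched
  kept2 <- clump(ss, ld_info(), window_kb = 250, r2_max = 0.01)
  expect_equal(nrow(kept2), 2)
  # distance-only mode clumps regardless of r2
  kept3 <- clump(ss, ld_info(), window_kb = 250, r2_max = 0.01,
                 distance_only = TRUE)
  expect_equal(kept3$snp_id, "rs002")
})

test_that("greedy clumping matches an independent oracle on random instances", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(4:12, 1)
      df <- make_raw_sumstats(n, seed = seed + 100)
      df$chrom <- as.character(sample(1:2, n, replace = TRUE))
      df$pos <- sample(seq(1e6, 3e6, by = 50e3), n)
      pairs <- t(combn(df$snp_id, 2))
      ld <- ld_info(tibble::tibble(
        snp_a = pairs[, 1], snp_b = pairs[, 2],
        r2 = sample(c(0, 0.005, 0.3, 0.9), nrow(pairs), replace = TRUE)
      ))
      ss <- as_sumstats(df, quiet = TRUE)
      mine <- clump(ss, ld, window_kb = 500, r2_max = 0.01)
      ref <- oracle_clump(as.data.frame(ss), ld, window_kb = 500, r2_max = 0.01)
      expect_equal(mine$snp_id, ref$snp_id)

      # pairwise compatibility of the retained set
      if (nrow(mine) > 1) {
        pr <- t(combn(seq_len(nrow(mine)), 2))
        compatible <- mine$chrom[pr[, 1]] != mine$chrom[pr[, 2]] |
          abs(mine$pos[pr[, 1]] - mine$pos[pr[, 2]]) > 500e3 |
          ld_r2(ld, mine$snp_id[pr[, 1]], mine$snp_id[pr[, 2]]) <= 0.01
        expect_true(all(compatible))
      }
      # idempotence of selection + clumping
      again <- clump(select_by_pvalue(mine, 0.9999), ld,
                     window_kb = 500, r2_max = 0.01)
      expect_equal(again$snp_id, mine$snp_id)
    })
  }
})

test_that("confounder exclusion removes listed ids and ignores unknown ones", {
  ss <- as_sumstats(make_raw_sumstats(5, seed = 9), quiet = TRUE)
  expect_identical(exclude_confounders(ss, NULL), ss)
  out <- exclude_confounders(ss, c("rs002", "rs004", "rs999"))
  expect_setequal(out$snp_id, c("rs001", "rs003", "rs005"))
  expect_warning(exclude_confounders(ss, ss$snp_id), "no variants remain")
})

test_that("per-variant variance explained follows 2p(1-p)beta^2", {
  d <- tibble::tibble(eaf = c(0.5, 0.2, 0.1), beta = c(0.1, 0, -0.2),
                      se = 0.01, n = 1000)
  expect_equal(snp_r2(d), c(2 * 0.25 * 0.01, 0, 2 * 0.1 * 0.9 * 0.04))
  expect_equal(snp_r2(d[1, ]), 0.005)
  # permutation invariance of the cumulative sum
  expect_equal(sum(snp_r2(d)), sum(snp_r2(d[c(3, 1, 2), ])))
  # t-statistic alternative
  expect_equal(snp_r2(d, method = "tstat")[1],
               (0.1 / 0.01)^2 / ((0.1 / 0.01)^2 + 998))
})

test_that("the F statistic matches the closed form and flags weak sets", {
  f <- f_statistic(0.01, n = 18340, k = 10)
  expect_equal(f$f_stat, (18340 - 10 - 1) / 10 * (0.01 / 0.99))
  expect_equal(f$f_stat, 18.514, tolerance = 1e-4)
  expect_false(f$weak_instruments)
  f0 <- f_statistic(0, n = 100, k = 5)
  expect_equal(f0$f_stat, 0)
  expect_true(f0$weak_instruments)
  expect_error(f_statistic(0.1, n = 11, k = 10), "n > k")
  # strictly increasing in r2_total
  fs <- vapply(c(0.001, 0.01, 0.1, 0.5),
               function(r2) f_statistic(r2, 1000, 10)$f_stat, numeric(1))
  expect_true(all(diff(fs) > 0))
})
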