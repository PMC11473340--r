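mk_rec <- function(snp_id = "rs1", ea = "A", oa = "G", eaf = 0.3,
                   beta = 0.1, se = 0.01, pval = 1e-9, n = 10000,
                   chrom = "1", pos = 1e6) {
  tibble::tibble(snp_id = snp_id, chrom = chrom, pos = pos,
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta, se = se, pval = pval, n = n)
}

test_that("an allele swap negates the outcome beta and complements its eaf", {
  exp <- mk_rec(ea = "A", oa = "G", beta = 0.10)
  out <- mk_rec(ea = "G", oa = "A", beta = -0.05, eaf = 0.7)
  h <- align_record(exp, out)
  expect_equal(h$action, "swap")
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$eaf_out, 0.3)
  expect_equal(h$beta_exp, 0.10)
})

test_that("strand flips are recognized and palindromes near 0.5 are dropped", {
  # T/C complements to A/G: pure strand flip, no numeric change
  exp <- mk_rec(ea = "A", oa = "G", beta = 0.1)
  out <- mk_rec(ea = "T", oa = "C", beta = 0.07, eaf = 0.3)
  h <- align_record(exp, out)
  expect_equal(h$action, "strand_flip")
  expect_equal(h$beta_out, 0.07)

  # complement + swap
  out2 <- mk_rec(ea = "C", oa = "T", beta = 0.07, eaf = 0.3)
  h2 <- align_record(exp, out2)
  expect_equal(h2$action, "swap")
  expect_equal(h2$beta_out, -0.07)
  expect_equal(h2$eaf_out, 0.7)

  # flips disabled -> incompatible
  h3 <- align_record(exp, out, allow_strand_flip = FALSE)
  expect_equal(h3$action, "dropped_incompatible")

  # palindromic with eaf at 0.5 cannot be oriented
  pexp <- mk_rec(ea = "A", oa = "T", eaf = 0.50)
  pout <- mk_rec(ea = "A", oa = "T", eaf = 0.50)
  expect_equal(align_record(pexp, pout)$action, "dropped_palindromic")
  # just inside the default window (0.42, 0.58)
  pexp2 <- mk_rec(ea = "A", oa = "T", eaf = 0.43)
  pout2 <- mk_rec(ea = "A", oa = "T", eaf = 0.30)
  expect_equal(align_record(pexp2, pout2)$action, "dropped_palindromic")
  # missing frequency on a palindrome is ambiguous
  pout3 <- mk_rec(ea = "A", oa = "T", eaf = NA_real_)
  pexp3 <- mk_rec(ea = "A", oa = "T", eaf = 0.2)
  expect_equal(align_record(pexp3, pout3)$action, "dropped_palindromic")
})

test_that("palindromes outside the window are frequency-aligned consistently", {
  # Enumerate the four allele/frequency orientations of a C/G palindrome
  # with eaf_exp = 0.10: the unique consistent alignment puts both aligned
  # frequencies on the same side of 0.5.
  exp <- mk_rec(ea = "C", oa = "G", eaf = 0.10, beta = 0.1)
  for (ea_out in c("C", "G")) {
    for (eaf_out in c(0.88, 0.12)) {
      out <- mk_rec(ea = ea_out, oa = setdiff(c("C", "G"), ea_out),
                    eaf = eaf_out, beta = 0.05)
      h <- align_record(exp, out)
      expect_false(startsWith(h$action, "dropped"))
      expect_lt(h$eaf_out, 0.5)   # same side as eaf_exp = 0.10
    }
  }
  # the spec case: labels match, frequency says flip
  out <- mk_rec(ea = "C", oa = "G", eaf = 0.88, beta = 0.05)
  h <- align_record(exp, out)
  expect_equal(h$action, "strand_flip")
  expect_equal(h$eaf_out, 0.12)
  expect_equal(h$beta_out, -0.05)
})

test_that("irreconcilable allele sets and mismatched ids are handled", {
  exp <- mk_rec(ea = "A", oa = "G")
  out <- mk_rec(ea = "A", oa = "C")
  expect_equal(align_record(exp, out)$action, "dropped_incompatible")
  out2 <- mk_rec(snp_id = "rs2")
  expect_error(align_record(exp, out2), "snp_id")
})

test_that("harmonize intersects, counts every action, and errors on disjoint sets", {
  exposure <- as_sumstats(dplyr::bind_rows(
    mk_rec("rs1", ea = "A", oa = "G", beta = 0.10),
    mk_rec("rs2", ea = "C", oa = "T", beta = 0.20),
    mk_rec("rs3", ea = "A", oa = "T", eaf = 0.50),   # palindromic, ambiguous
    mk_rec("rs4", ea = "A", oa = "C", beta = 0.15)
  ), quiet = TRUE)
  outcome <- as_sumstats(dplyr::bind_rows(
    mk_rec("rs1", ea = "G", oa = "A", beta = -0.05, eaf = 0.7),  # swap
    mk_rec("rs2", ea = "C", oa = "T", beta = 0.02),              # none
    mk_rec("rs3", ea = "A", oa = "T", eaf = 0.50),
    mk_rec("rs5", ea = "A", oa = "C", beta = 0.15)               # not shared
  ), quiet = TRUE)
  h <- harmonize(exposure, outcome)
  counts <- attr(h, "action_counts")
  expect_equal(nrow(h), 2)
  expect_equal(attr(h, "n_shared"), 3)
  expect_equal(sum(counts), attr(h, "n_shared"))
  expect_equal(unname(counts[["dropped_palindromic"]]), 1)
  expect_equal(sort(h$snp_id), c("rs1", "rs2"))

  disjoint <- as_sumstats(mk_rec("zz9"), quiet = TRUE)
  expect_error(harmonize(exposure, disjoint), "share no snp_id")
})

test_that("harmonization is an involution and aligned sets pass through unchanged", {
  withr::with_seed(11, {
    exposure <- make_raw_sumstats(12, seed = 21)
    outcome <- make_raw_sumstats(12, seed = 22)
    outcome$effect_allele <- exposure$effect_allele
    outcome$other_allele <- exposure$other_allele
    # randomly swap half the outcome records' alleles
    swap <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    tmp <- outcome$effect_allele[swap]
    outcome$effect_allele[swap] <- outcome$other_allele[swap]
    outcome$other_allele[swap] <- tmp
    outcome$beta[swap] <- -outcome$beta[swap]
    outcome$eaf[swap] <- 1 - outcome$eaf[swap]
    h1 <- harmonize(as_sumstats(exposure, quiet = TRUE),
                    as_sumstats(outcome, quiet = TRUE))
    expect_equal(sort(unique(h1$action[swap[match(h1$snp_id, exposure$snp_id)]])),
                 "swap")
    # rebuild both sides on the aligned frame and harmonize again
    rebuild <- function(beta, se, eaf) {
      tibble::tibble(
        snp_id = h1$snp_id, chrom = h1$chrom, pos = h1$pos,
        effect_allele = h1$effect_allele, other_allele = h1$other_allele,
        eaf = eaf, beta = beta, se = se, pval = 0.5, n = 10000
      )
    }
    e2 <- as_sumstats(rebuild(h1$beta_exp, h1$se_exp, h1$eaf_exp), quiet = TRUE)
    o2 <- as_sumstats(rebuild(h1$beta_out, h1$se_out, h1$eaf_out), quiet = TRUE)
    h2 <- harmonize(e2, o2)
    expect_true(all(h2$action == "none"))
    expect_equal(h2$beta_out, h1$beta_out)
    expect_equal(h2$beta_exp, h1$beta_exp)
    expect_equal(h2$eaf_out, h1$eaf_out)
  })
})

test_that("negating exposure beta together with an allele swap leaves ratios unchanged", {
  withr::with_seed(5, {
    exposure <- make_raw_sumstats(10, seed = 31)
    outcome <- make_raw_sumstats(10, seed = 32)
    outcome$effect_allele <- exposure$effect_allele
    outcome$other_allele <- exposure$other_allele
    h1 <- harmonize(as_sumstats(exposure, quiet = TRUE),
                    as_sumstats(outcome, quiet = TRUE))
    # flip the exposure's declared effect allele and negate its beta
    flipped <- exposure
    flipped$effect_allele <- exposure$other_allele
    flipped$other_allele <- exposure$effect_allele
    flipped$beta <- -exposure$beta
    flipped$eaf <- 1 - exposure$eaf
    h2 <- harmonize(as_sumstats(flipped, quiet = TRUE),
                    as_sumstats(outcome, quiet = TRUE))
    r1 <- h1$beta_out / h1$beta_exp
    r2 <- h2$beta_out[match(h1$snp_id, h2$snp_id)] /
      h2$beta_exp[match(h1$snp_id, h2$snp_id)]
    expect_equal(r1, r2)
  })
})
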