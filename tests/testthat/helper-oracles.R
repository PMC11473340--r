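# Independent reference implementations used to cross-check the estimators.

# Weighted least squares through the origin, via stats::lm.
oracle_wls_origin <- function(bx, by, se_out) {
  fit <- lm(by ~ bx - 1, weights = 1 / se_out^2)
  unname(coef(fit)[1])
}

# Weighted median by interpolation over all knots, via stats::approx.
oracle_weighted_median <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  approx(x = s, y = r, xout = 0.5, ties = "ordered")$y
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  ranked <- p[ord] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  adj[ord] <- pmin(1, rev(cummin(rev(ranked))))
  adj
}

# Greedy clumping re-derived from the rule: smallest p becomes an index,
# then purge conflicts, repeat. Independent loop structure from clump().
oracle_clump <- function(df, ld, window_kb, r2_max) {
  remaining <- df
  idx <- df[0, ]
  while (nrow(remaining) > 0) {
    o <- order(remaining$pval, remaining$chrom, remaining$pos)
    top <- remaining[o[1], ]
    idx <- rbind(idx, top)
    remaining <- remaining[-o[1], , drop = FALSE]
    if (nrow(remaining) > 0) {
      conflict <- remaining$chrom == top$chrom &
        abs(remaining$pos - top$pos) <= window_kb * 1000 &
        ld_r2(ld, remaining$snp_id, top$snp_id) > r2_max
      remaining <- remaining[!conflict, , drop = FALSE]
    }
  }
  idx[order(idx$pval, idx$chrom, idx$pos), ]
}

# Summary-level instrument generator: k instruments with true slope beta,
# optional per-instrument pleiotropic shifts, normal estimation noise.
make_harmonized <- function(k = 10, beta = 0.3, se_exp = 0.02, se_out = 0.05,
                            bx_range = c(0.05, 0.25), pleio = numeric(k),
                            seed = NULL) {
  gen <- function() {
    bx_true <- runif(k, bx_range[1], bx_range[2])
    tibble::tibble(
      snp_id = sprintf("snp%02d", seq_len(k)),
      beta_exp = rnorm(k, bx_true, se_exp),
      se_exp = se_exp,
      beta_out = rnorm(k, beta * bx_true + pleio, se_out),
      se_out = se_out
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# A small raw summary-statistics table with controllable fields.
make_raw_sumstats <- function(n = 8, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      snp_id = sprintf("rs%03d", seq_len(n)),
      chrom = as.character(((seq_len(n) - 1) %% 4) + 1),
      pos = 1e6 * seq_len(n),
      effect_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      other_allele = NA_character_,
      eaf = runif(n, 0.05, 0.45),
      beta = rnorm(n, 0, 0.1),
      se = runif(n, 0.01, 0.05),
      pval = runif(n),
      n = 10000
    ) |>
      dplyr::mutate(other_allele = purrr::map_chr(effect_allele, function(a) {
        sample(setdiff(c("A", "C", "G", "T"), c(a, chartr("ACGT", "TGCA", a))), 1)
      }))
  })
}
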