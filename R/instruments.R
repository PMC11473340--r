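#' Filter variants by association p-value
#'
#' Retains records with `pval` strictly below the threshold, preserving the
#' input order. In instrument selection the genome-wide cutoff 5e-8 is the
#' primary threshold; 1e-5 is the conventional relaxed cutoff when too few
#' variants reach genome-wide significance, and 5e-6 a common compromise for
#' secondary datasets.
#'
#' @param stats A summary-statistics tibble.
#' @param p_threshold Significance cutoff in (0, 1).
#' @return The filtered tibble (possibly zero rows; the caller decides
#'   whether to relax the threshold).
#' @export
select_by_pvalue <- function(stats, p_threshold = 5e-8) {
  if (!(p_threshold > 0 && p_threshold < 1)) {
    abort("p_threshold must lie in (0, 1)")
  }
  stats[stats$pval < p_threshold, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unprocessed record as an index variant
#' and removes every unprocessed record on the same chromosome within
#' `window_kb` of it **and** in LD with it above `r2_max`. Index variants
#' form the output, sorted by ascending p-value; ties on p are broken by
#' (chrom, pos) so the result is deterministic. With no LD input every pair
#' is treated as independent (r2 = 0) and nothing is removed unless
#' `distance_only = TRUE`, which treats any same-chromosome pair within the
#' window as clumped — a panel-free approximation to LD pruning.
#'
#' @param stats A summary-statistics tibble with `chrom`, `pos`, `pval`.
#' @param ld An [ld_info()] object, or `NULL` for all-independent.
#' @param window_kb Distance window in kilobases (250 for microbiome-scale
#'   exposures, 1,000 or 10,000 for large-biobank traits are the presets
#'   shipped in [selection_config()]).
#' @param r2_max LD cutoff: pairs with r2 strictly greater are clumped.
#' @param distance_only Clump on distance alone, ignoring r2.
#' @return The clumped tibble, sorted by ascending `pval`.
#' @export
clump <- function(stats, ld = NULL, window_kb = 250, r2_max = 0.01,
                  distance_only = FALSE) {
  if (!(window_kb > 0)) abort("window_kb must be positive")
  if (!(r2_max > 0 && r2_max < 1)) abort("r2_max must lie in (0, 1)")
  if (nrow(stats) == 0) return(stats)
  ld <- ld %||% ld_info()
  ord <- order(stats$pval, stats$chrom, stats$pos)
  x <- stats[ord, , drop = FALSE]
  n <- nrow(x)
  state <- rep("unprocessed", n)
  for (i in seq_len(n)) {
    if (state[i] != "unprocessed") next
    state[i] <- "index"
    cand <- which(state == "unprocessed" &
                    x$chrom == x$chrom[i] &
                    abs(x$pos - x$pos[i]) <= window_kb * 1000)
    if (length(cand) > 0) {
      hit <- if (distance_only) {
        rep(TRUE, length(cand))
      } else {
        ld_r2(ld, x$snp_id[cand], x$snp_id[i]) > r2_max
      }
      state[cand[hit]] <- "removed"
    }
  }
  x[state == "index", , drop = FALSE]
}

#' Remove known confounder-associated variants
#'
#' Drops records whose `snp_id` appears in a user-supplied exclusion list
#' (e.g. variants associated with body-mass index or smoking in an external
#' phenotype-association screen). Ids in the list that are absent from
#' `stats` are ignored.
#'
#' @param stats A summary-statistics tibble.
#' @param confounder_snps Character vector of snp ids to exclude (or `NULL`).
#' @param quiet Suppress the removal-count message.
#' @return The filtered tibble.
#' @export
exclude_confounders <- function(stats, confounder_snps = NULL, quiet = TRUE) {
  if (is.null(confounder_snps) || length(confounder_snps) == 0) return(stats)
  hit <- stats$snp_id %in% confounder_snps
  unknown <- sum(!confounder_snps %in% stats$snp_id)
  if (!quiet) {
    inform(sprintf(
      "exclude_confounders(): removed %d variant(s); %d listed id(s) not present",
      sum(hit), unknown
    ))
  }
  out <- stats[!hit, , drop = FALSE]
  if (nrow(out) == 0) warn("exclude_confounders(): no variants remain")
  out
}

#' Per-variant variance explained
#'
#' Under Hardy-Weinberg equilibrium and a variance-1 trait, one variant with
#' effect-allele frequency p and per-allele effect beta explains
#' `2 p (1 - p) beta^2` of the trait variance (`method = "maf_beta"`). The
#' alternative `"tstat"` form `t^2 / (t^2 + n - 2)` with t = beta/se is
#' offered for users whose betas are not on a standardized scale.
#'
#' @param stats A summary-statistics tibble (vectorized over rows).
#' @param method `"maf_beta"` (default) or `"tstat"`.
#' @return Numeric vector of per-variant R-squared values.
#' @export
snp_r2 <- function(stats, method = c("maf_beta", "tstat")) {
  method <- match.arg(method)
  if (method == "maf_beta") {
    2 * stats$eaf * (1 - stats$eaf) * stats$beta^2
  } else {
    t2 <- (stats$beta / stats$se)^2
    t2 / (t2 + stats$n - 2)
  }
}

#' Instrument-strength F statistic
#'
#' `F = (n - k - 1)/k * R2/(1 - R2)`, where R2 is the cumulative variance in
#' the exposure explained by the k instruments and n is the exposure sample
#' size. F above 10 is the conventional bar for ruling out weak-instrument
#' bias in a two-sample design.
#'
#' @param r2_total Cumulative variance explained, in \[0, 1).
#' @param n Exposure sample size; must exceed `k + 1`.
#' @param k Number of instruments.
#' @return A list with `f_stat` and `weak_instruments` (`TRUE` when
#'   `f_stat <= 10`).
#' @export
f_statistic <- function(r2_total, n, k) {
  if (!(k >= 1)) abort("k must be at least 1")
  if (!(n > k + 1)) abort("f_statistic() requires n > k + 1")
  if (!(r2_total >= 0 && r2_total < 1)) abort("r2_total must lie in [0, 1)")
  f <- (n - k - 1) / k * (r2_total / (1 - r2_total))
  list(f_stat = f, weak_instruments = f <= 10)
}

#' Summarize instrument strength for a selected set
#'
#' Convenience wrapper: sums [snp_r2()] across the instruments, takes the
#' minimum reported sample size, and applies [f_statistic()].
#'
#' @param stats The selected instruments (summary-statistics tibble).
#' @param method Passed to [snp_r2()].
#' @return A one-row tibble with `k`, `r2_total`, `n`, `f_stat`,
#'   `weak_instruments`.
#' @export
instrument_diagnostics <- function(stats, method = c("maf_beta", "tstat")) {
  method <- match.arg(method)
  k <- nrow(stats)
  if (k == 0) abort("no instruments supplied")
  r2_total <- min(sum(snp_r2(stats, method = method)), 1 - 1e-12)
  n <- min(stats$n)
  f <- f_statistic(r2_total, n = n, k = k)
  tibble(
    k = k, r2_total = r2_total, n = n,
    f_stat = f$f_stat, weak_instruments = f$weak_instruments
  )
}
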