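.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align one outcome record onto the exposure effect-allele frame
#'
#' Places an outcome association on the exposure's effect allele, handling
#' allele swaps (negate `beta_out`, complement `eaf_out`), strand flips
#' (complement both outcome alleles, then re-evaluate) and palindromic (A/T,
#' C/G) variants. Palindromic variants with either allele frequency inside
#' `0.5 +/- palindrome_window`, or with a missing frequency, cannot be
#' oriented and are dropped; outside the window they are oriented so that the
#' aligned frequencies sit on the same side of 0.5. Irreconcilable allele
#' sets are dropped as incompatible.
#'
#' @param exp,out One-row data frames (or named lists) carrying the
#'   summary-statistics fields for the same `snp_id`.
#' @param palindrome_window Half-width w of the ambiguity window: palindromic
#'   variants with eaf in (0.5 - w, 0.5 + w) are dropped. Default 0.08, the
#'   community-standard tolerance for "close to 0.5". Must lie in (0, 0.5).
#' @param allow_strand_flip Attempt to reconcile alleles by complementing the
#'   outcome pair (default `TRUE`).
#' @return A one-row tibble with `snp_id`, the exposure-frame alleles,
#'   `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`, `eaf_out`, and an
#'   `action` in `none`, `swap`, `strand_flip`, `dropped_palindromic`,
#'   `dropped_incompatible`.
#' @export
align_record <- function(exp, out, palindrome_window = 0.08,
                         allow_strand_flip = TRUE) {
  exp <- as.list(exp)
  out <- as.list(out)
  if (!identical(as.character(exp$snp_id), as.character(out$snp_id))) {
    abort("align_record(): exposure and outcome snp_id differ")
  }
  if (!(palindrome_window > 0 && palindrome_window < 0.5)) {
    abort("palindrome_window must lie in (0, 0.5)")
  }
  a1 <- exp$effect_allele; a2 <- exp$other_allele
  b1 <- out$effect_allele; b2 <- out$other_allele
  beta_out <- out$beta; eaf_out <- out$eaf
  action <- NULL

  res <- function(action) {
    tibble(
      snp_id = as.character(exp$snp_id),
      chrom = as.character(exp$chrom %||% NA_character_),
      pos = as.numeric(exp$pos %||% NA_real_),
      effect_allele = a1, other_allele = a2,
      beta_exp = exp$beta, se_exp = exp$se, eaf_exp = exp$eaf,
      pval_exp = as.numeric(exp$pval %||% NA_real_),
      n_exp = as.numeric(exp$n %||% NA_real_),
      beta_out = beta_out, se_out = out$se, eaf_out = eaf_out,
      pval_out = as.numeric(out$pval %||% NA_real_),
      n_out = as.numeric(out$n %||% NA_real_),
      action = action
    )
  }

  if (.is_palindromic(a1, a2)) {
    # Any strand reading of a palindromic pair is the same two alleles, so
    # the label can only tell us whether they are the same pair at all.
    if (!setequal(c(b1, b2), c(a1, a2))) return(res("dropped_incompatible"))
    w <- palindrome_window
    if (is.na(exp$eaf) || is.na(eaf_out) ||
        abs(exp$eaf - 0.5) < w || abs(eaf_out - 0.5) < w) {
      return(res("dropped_palindromic"))
    }
    # Nominal orientation from the labels, then frequency decides the strand.
    swapped <- b1 == a2
    if (swapped) {
      beta_out <- -beta_out
      eaf_out <- 1 - eaf_out
    }
    freq_flip <- (exp$eaf < 0.5) != (eaf_out < 0.5)
    if (freq_flip) {
      beta_out <- -beta_out
      eaf_out <- 1 - eaf_out
    }
    action <- if (swapped == freq_flip) {
      "none"
    } else if (swapped) "swap" else "strand_flip"
    return(res(action))
  }

  if (b1 == a1 && b2 == a2) return(res("none"))
  if (b1 == a2 && b2 == a1) {
    beta_out <- -beta_out
    eaf_out <- if (is.na(eaf_out)) NA_real_ else 1 - eaf_out
    return(res("swap"))
  }
  if (allow_strand_flip) {
    c1 <- .complement(b1); c2 <- .complement(b2)
    if (c1 == a1 && c2 == a2) return(res("strand_flip"))
    if (c1 == a2 && c2 == a1) {
      beta_out <- -beta_out
      eaf_out <- if (is.na(eaf_out)) NA_real_ else 1 - eaf_out
      return(res("swap"))
    }
  }
  res("dropped_incompatible")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two tables on `snp_id` and aligns every shared variant onto
#' the exposure effect-allele frame via [align_record()]. Records dropped as
#' palindromic-ambiguous or allele-incompatible are removed from the result;
#' per-action counts are attached and reported.
#'
#' @param exposure,outcome `mr_sumstats` tibbles (or data frames with the
#'   required columns).
#' @inheritParams align_record
#' @param quiet Suppress the per-action count message.
#' @return A tibble of class `mr_harmonized` with one row per retained
#'   variant (`beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`,
#'   `eaf_out`, `action`, exposure-frame alleles), and attributes
#'   `action_counts`, `exposure_label`, `outcome_label`, `outcome_type`.
#' @examples
#' ss <- as_sumstats(example_sumstats())
#' h <- harmonize(ss, ss)  # self-harmonization: all actions "none"
#' attr(h, "action_counts")
#' @export
harmonize <- function(exposure, outcome, palindrome_window = 0.08,
                      allow_strand_flip = TRUE, quiet = TRUE) {
  exposure_label <- attr(exposure, "trait_label") %||% "exposure"
  outcome_label <- attr(outcome, "trait_label") %||% "outcome"
  outcome_type <- attr(outcome, "trait_type") %||% "quantitative"
  exposure <- as_tibble(as.data.frame(exposure))
  outcome_tbl <- as_tibble(as.data.frame(outcome))
  shared <- intersect(exposure$snp_id, outcome_tbl$snp_id)
  if (length(shared) == 0) {
    abort("harmonize(): exposure and outcome share no snp_id")
  }
  ei <- exposure[match(shared, exposure$snp_id), ]
  oi <- outcome_tbl[match(shared, outcome_tbl$snp_id), ]
  rows <- purrr::map(seq_along(shared), function(i) {
    align_record(ei[i, ], oi[i, ],
                 palindrome_window = palindrome_window,
                 allow_strand_flip = allow_strand_flip)
  })
  all_rows <- dplyr::bind_rows(rows)
  counts <- table(factor(all_rows$action, levels = c(
    "none", "swap", "strand_flip", "dropped_palindromic", "dropped_incompatible"
  )))
  kept <- all_rows[!startsWith(all_rows$action, "dropped"), , drop = FALSE]
  if (!quiet) {
    inform(sprintf(
      "harmonize(): %d shared variant(s); retained %d (none %d, swap %d, strand_flip %d); dropped %d palindromic, %d incompatible",
      length(shared), nrow(kept), counts[["none"]], counts[["swap"]],
      counts[["strand_flip"]], counts[["dropped_palindromic"]],
      counts[["dropped_incompatible"]]
    ))
  }
  structure(
    kept,
    action_counts = counts,
    n_shared = length(shared),
    exposure_label = exposure_label,
    outcome_label = outcome_label,
    outcome_type = outcome_type,
    class = c("mr_harmonized", class(kept))
  )
}
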