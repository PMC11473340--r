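#' Instrument-selection settings for one MR leg
#'
#' Collects the thresholds that turn a full summary-statistics table into an
#' instrument set: significance cutoff (with an optional relaxed fallback
#' applied when fewer than `min_instruments` variants pass), greedy-clumping
#' window and r-squared cutoff, and an optional confounder exclusion list.
#'
#' Three presets ship with the package:
#' \describe{
#'   \item{`"primary"`}{p < 5e-8 relaxed to 1e-5 when instruments are
#'     scarce, 250 kb window, r2 < 0.01 — the convention for small-cohort
#'     exposures such as microbiome taxa.}
#'   \item{`"biobank"`}{p < 5e-8, 10,000 kb window, r2 < 0.001 — the
#'     convention for large-biobank traits.}
#'   \item{`"secondary"`}{p < 5e-6, 1,000 kb window, r2 = 0.01 — a relaxed
#'     compromise for secondary datasets with few genome-wide hits.}
#' }
#'
#' @param p_threshold Significance cutoff.
#' @param relax_threshold Fallback cutoff, or `NULL` for none.
#' @param min_instruments Minimum instruments before relaxing.
#' @param clump_window_kb,clump_r2_max,distance_only Passed to [clump()].
#' @param confounder_snps Passed to [exclude_confounders()].
#' @param preset One of `"primary"`, `"biobank"`, `"secondary"`; explicit
#'   arguments override preset values.
#' @return A list of class `mr_selection`.
#' @export
selection_config <- function(p_threshold = NULL, relax_threshold = NULL,
                             min_instruments = 3,
                             clump_window_kb = NULL, clump_r2_max = NULL,
                             distance_only = FALSE, confounder_snps = NULL,
                             preset = c("primary", "biobank", "secondary")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    primary = list(p = 5e-8, relax = 1e-5, kb = 250, r2 = 0.01),
    biobank = list(p = 5e-8, relax = NULL, kb = 10000, r2 = 0.001),
    secondary = list(p = 5e-6, relax = NULL, kb = 1000, r2 = 0.01)
  )
  cfg <- list(
    p_threshold = p_threshold %||% defaults$p,
    relax_threshold = if (is.null(relax_threshold)) defaults$relax else relax_threshold,
    min_instruments = min_instruments,
    clump_window_kb = clump_window_kb %||% defaults$kb,
    clump_r2_max = clump_r2_max %||% defaults$r2,
    distance_only = distance_only,
    confounder_snps = confounder_snps,
    preset = preset
  )
  if (!(cfg$p_threshold > 0 && cfg$p_threshold < 1)) abort("p_threshold must lie in (0, 1)")
  structure(cfg, class = "mr_selection")
}

.empty_report <- function() {
  tibble(
    exposure = character(), outcome = character(), method = character(),
    k = integer(), beta = numeric(), se = numeric(), pval = numeric(),
    or_ = numeric(), or_ci_low = numeric(), or_ci_high = numeric(),
    q_stat = numeric(), q_pval = numeric(),
    egger_intercept_pval = numeric(), presso_global_pval = numeric(),
    f_stat = numeric(), effect_scale = character(), status = character()
  )
}

.report_row <- function(res, f_stat, presso_pval, effect_scale) {
  tibble(
    exposure = res$exposure, outcome = res$outcome, method = res$method,
    k = res$k, beta = res$beta, se = res$se, pval = res$pval,
    or_ = exp(res$beta),
    or_ci_low = exp(res$ci_low), or_ci_high = exp(res$ci_high),
    q_stat = res$q_stat, q_pval = res$q_pval,
    egger_intercept_pval = res$egger_intercept_pval,
    presso_global_pval = presso_pval,
    f_stat = f_stat, effect_scale = effect_scale, status = "ok"
  )
}

#' Run one MR leg end to end
#'
#' Applies the full per-leg workflow: p-value selection (with optional
#' relaxed fallback), greedy clumping, confounder exclusion, harmonization
#' onto the exposure allele frame, instrument-strength diagnostics, and the
#' estimator battery — IVW in auto mode (fixed effects, switching to the
#' random-effects inflation when the Cochran Q p-value falls below 0.05),
#' weighted median and MR-Egger when at least 3 instruments remain, and the
#' pleiotropy RSS test with outlier flagging when at least 4 remain. Fewer
#' than 2 harmonized instruments is reported as a status
#' (`"insufficient_instruments"`), not an error, because in bidirectional
#' screens the reverse leg routinely has no genome-wide hits.
#'
#' @param exposure,outcome `mr_sumstats` tibbles.
#' @param selection A [selection_config()].
#' @param ld An [ld_info()] or `NULL`.
#' @param palindrome_window,allow_strand_flip Passed to [harmonize()].
#' @param n_boot Weighted-median bootstrap replicates.
#' @param n_sim Pleiotropy-test replicates.
#' @param seed Optional integer seed; the weighted-median bootstrap uses
#'   `seed` and the pleiotropy test `seed + 1`.
#' @param run_presso Set `FALSE` to skip the simulation-based test.
#' @return An object of class `mr_leg`: `status`, `results` (named list of
#'   `mr_result`s), `harmonized`, `diagnostics`, `presso`, `report` (one
#'   tibble row per method), selection counts.
#' @export
mr_leg <- function(exposure, outcome, selection = selection_config(),
                   ld = NULL, palindrome_window = 0.08,
                   allow_strand_flip = TRUE, n_boot = 1000, n_sim = 1000,
                   seed = NULL, run_presso = TRUE) {
  stopifnot(inherits(selection, "mr_selection"))
  exp_label <- attr(exposure, "trait_label") %||% "exposure"
  out_label <- attr(outcome, "trait_label") %||% "outcome"
  out_type <- attr(outcome, "trait_type") %||% "quantitative"
  effect_scale <- if (identical(out_type, "binary")) "odds_ratio" else "exp_beta"

  sel <- select_by_pvalue(exposure, selection$p_threshold)
  relaxed <- FALSE
  if (nrow(sel) < selection$min_instruments && !is.null(selection$relax_threshold)) {
    sel <- select_by_pvalue(exposure, selection$relax_threshold)
    relaxed <- TRUE
  }
  n_significant <- nrow(sel)
  if (nrow(sel) > 0) {
    sel <- clump(sel, ld = ld, window_kb = selection$clump_window_kb,
                 r2_max = selection$clump_r2_max,
                 distance_only = selection$distance_only)
    sel <- exclude_confounders(sel, selection$confounder_snps)
  }

  leg <- list(
    exposure = exp_label, outcome = out_label,
    status = "ok", selection = selection, relaxed = relaxed,
    n_significant = n_significant, n_selected = nrow(sel),
    results = list(), harmonized = NULL, diagnostics = NULL, presso = NULL,
    report = .empty_report()
  )
  class(leg) <- "mr_leg"

  if (nrow(sel) == 0) {
    leg$status <- "insufficient_instruments"
    return(leg)
  }
  attr(sel, "trait_label") <- exp_label
  h <- harmonize(sel, outcome, palindrome_window = palindrome_window,
                 allow_strand_flip = allow_strand_flip)
  leg$harmonized <- h
  k <- nrow(h)
  if (k < 2) {
    leg$status <- "insufficient_instruments"
    return(leg)
  }

  diag_tbl <- instrument_diagnostics(tibble(
    eaf = h$eaf_exp, beta = h$beta_exp, se = h$se_exp,
    n = ifelse(is.na(h$n_exp), Inf, h$n_exp)
  ))
  leg$diagnostics <- diag_tbl

  results <- list(ivw = mr_ivw(h, mode = "auto"))
  if (k >= 3) {
    results$weighted_median <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
    results$egger <- mr_egger(h)
  }
  presso_pval <- NA_real_
  if (run_presso && k >= 4) {
    leg$presso <- mr_presso(h, n_sim = n_sim,
                            seed = if (is.null(seed)) NULL else seed + 1)
    presso_pval <- leg$presso$global_pval
  }
  leg$results <- results
  leg$report <- dplyr::bind_rows(purrr::map(
    results, .report_row,
    f_stat = diag_tbl$f_stat, presso_pval = presso_pval,
    effect_scale = effect_scale
  ))
  leg
}

#' @export
print.mr_leg <- function(x, ...) {
  cat(sprintf("<mr_leg> %s -> %s [%s]\n", x$exposure, x$outcome, x$status))
  cat(sprintf("  %d significant variant(s)%s, %d after clumping/exclusion\n",
              x$n_significant, if (x$relaxed) " (relaxed threshold)" else "",
              x$n_selected))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  k = %d harmonized instrument(s), F = %.1f\n",
                nrow(x$harmonized), x$diagnostics$f_stat))
  }
  if (x$status == "ok") print(tidy(x))
  invisible(x)
}

#' @describeIn mr_leg The per-method report tibble.
#' @param x An `mr_leg`.
#' @param ... Unused.
#' @export
tidy.mr_leg <- function(x, ...) x$report

#' @describeIn mr_leg One-row summary with IVW estimate, heterogeneity,
#'   pleiotropy diagnostics and instrument strength.
#' @export
glance.mr_leg <- function(x, ...) {
  ivw <- x$results$ivw
  tibble(
    exposure = x$exposure, outcome = x$outcome, status = x$status,
    k = if (is.null(ivw)) 0L else ivw$k,
    ivw_beta = if (is.null(ivw)) NA_real_ else ivw$beta,
    ivw_pval = if (is.null(ivw)) NA_real_ else ivw$pval,
    ivw_method = if (is.null(ivw)) NA_character_ else ivw$method,
    q_pval = if (is.null(ivw)) NA_real_ else ivw$q_pval,
    egger_intercept_pval = if (is.null(x$results$egger)) NA_real_ else
      x$results$egger$egger_intercept_pval,
    presso_global_pval = if (is.null(x$presso)) NA_real_ else x$presso$global_pval,
    f_stat = if (is.null(x$diagnostics)) NA_real_ else x$diagnostics$f_stat
  )
}

#' Forward and reverse MR between two traits
#'
#' Runs [mr_leg()] in both directions, with direction-appropriate selection
#' settings, to screen for bidirectional causation: a causal reading of the
#' forward estimate is undermined if the reverse leg is also significant.
#'
#' @param trait_a,trait_b `mr_sumstats` tibbles.
#' @param selection_forward,selection_reverse [selection_config()]s for the
#'   a-to-b and b-to-a legs.
#' @param ... Passed to [mr_leg()].
#' @return A list of class `mr_bidirectional` with `forward`, `reverse`,
#'   and `bidirectional_significant` (both IVW p-values below `alpha`).
#' @param alpha Significance level for the flag.
#' @export
mr_bidirectional <- function(trait_a, trait_b,
                             selection_forward = selection_config(),
                             selection_reverse = selection_config(preset = "biobank"),
                             alpha = 0.05, ...) {
  forward <- mr_leg(trait_a, trait_b, selection = selection_forward, ...)
  reverse <- mr_leg(trait_b, trait_a, selection = selection_reverse, ...)
  p_f <- if (forward$status == "ok") forward$results$ivw$pval else NA_real_
  p_r <- if (reverse$status == "ok") reverse$results$ivw$pval else NA_real_
  structure(
    list(
      forward = forward, reverse = reverse,
      bidirectional_significant = isTRUE(p_f < alpha) && isTRUE(p_r < alpha)
    ),
    class = "mr_bidirectional"
  )
}

#' @export
print.mr_bidirectional <- function(x, ...) {
  cat("<mr_bidirectional>\n-- forward --\n")
  print(x$forward)
  cat("-- reverse --\n")
  print(x$reverse)
  invisible(x)
}

#' Two-step mediation analysis over three trait datasets
#'
#' Runs the three MR legs of the mediation triangle — exposure to outcome
#' (total effect), exposure to mediator (leg A), mediator to outcome
#' (leg B) — and assembles the product-of-coefficients decomposition via
#' [two_step()]. Optionally runs the three reverse legs (outcome to
#' exposure, outcome to mediator, mediator to exposure) as gates: the
#' mediation reading requires each reverse IVW to be non-significant
#' (p at or above `reverse_gate_p`) or to lack instruments altogether.
#'
#' @param exposure,mediator,outcome `mr_sumstats` tibbles.
#' @param selection_exposure Selection settings for legs using the exposure
#'   instruments (total effect and leg A).
#' @param selection_mediator Selection settings for the mediator's
#'   instruments (leg B and the mediator-to-exposure reverse leg).
#' @param selection_outcome Selection settings for the outcome's
#'   instruments (reverse legs).
#' @param check_reverse Run the reverse-direction gates (default `TRUE`).
#' @param reverse_gate_p Reverse legs with IVW p below this are flagged.
#' @param ... Passed to every [mr_leg()] call.
#' @return An object of class `mr_two_step`: `status`, `mediation`
#'   (an `mr_mediation`, or `NULL` when a leg lacks instruments), `legs`,
#'   `reverse`, `gates` (tibble), and `report` (stacked leg reports).
#' @export
mr_two_step <- function(exposure, mediator, outcome,
                        selection_exposure = selection_config(),
                        selection_mediator = selection_config(preset = "biobank"),
                        selection_outcome = selection_config(preset = "biobank"),
                        check_reverse = TRUE, reverse_gate_p = 0.05, ...) {
  legs <- list(
    total = mr_leg(exposure, outcome, selection = selection_exposure, ...),
    a = mr_leg(exposure, mediator, selection = selection_exposure, ...),
    b = mr_leg(mediator, outcome, selection = selection_mediator, ...)
  )
  reverse <- list()
  gates <- tibble(
    leg = character(), status = character(), ivw_pval = numeric(),
    passed = logical()
  )
  if (check_reverse) {
    reverse <- list(
      outcome_to_exposure = mr_leg(outcome, exposure,
                                   selection = selection_outcome, ...),
      outcome_to_mediator = mr_leg(outcome, mediator,
                                   selection = selection_outcome, ...),
      mediator_to_exposure = mr_leg(mediator, exposure,
                                    selection = selection_mediator, ...)
    )
    gates <- dplyr::bind_rows(purrr::imap(reverse, function(rev_leg, nm) {
      p <- if (rev_leg$status == "ok") rev_leg$results$ivw$pval else NA_real_
      ok_leg <- rev_leg$status == "ok"
      tibble(
        leg = nm, status = rev_leg$status, ivw_pval = p,
        passed = !ok_leg || p >= reverse_gate_p
      )
    }))
  }

  ok <- all(vapply(legs, function(l) l$status == "ok", logical(1)))
  mediation <- NULL
  if (ok) {
    mediation <- two_step(
      legs$total$results$ivw, legs$a$results$ivw, legs$b$results$ivw,
      exposure = legs$total$exposure, mediator = legs$a$outcome,
      outcome = legs$total$outcome
    )
  }
  structure(
    list(
      status = if (ok) "ok" else "insufficient_instruments",
      mediation = mediation, legs = legs, reverse = reverse, gates = gates,
      reverse_gates_passed = if (check_reverse) all(gates$passed) else NA,
      report = dplyr::bind_rows(c(
        purrr::map(legs, tidy),
        purrr::map(reverse, tidy)
      ))
    ),
    class = "mr_two_step"
  )
}

#' @export
print.mr_two_step <- function(x, ...) {
  cat(sprintf("<mr_two_step> [%s]\n", x$status))
  if (!is.null(x$mediation)) print(x$mediation)
  if (nrow(x$gates) > 0) {
    cat(sprintf("  reverse gates passed: %s\n", x$reverse_gates_passed))
  }
  invisible(x)
}

#' @describeIn mr_two_step One mediation row in the two-step report shape
#'   (total, beta A, beta B, indirect, proportion).
#' @param x An `mr_two_step`.
#' @param ... Unused.
#' @export
tidy.mr_two_step <- function(x, ...) {
  if (is.null(x$mediation)) {
    return(tibble(
      exposure = x$legs$total$exposure, mediator = x$legs$a$outcome,
      outcome = x$legs$total$outcome, status = x$status
    ))
  }
  out <- tidy(x$mediation)
  out$status <- x$status
  out$reverse_gates_passed <- x$reverse_gates_passed
  out
}

#' Multiple-testing adjustment for report rows
#'
#' Adds an `adjusted_pval` column (and a `significant` flag) to a report
#' tibble using Benjamini-Hochberg false-discovery-rate control by default;
#' any method known to [stats::p.adjust()] (e.g. `"bonferroni"`) may be
#' substituted. Adjustment is monotone and order-preserving, and the
#' adjusted value is never below the raw one.
#'
#' @param rows A tibble with a p-value column.
#' @param method Passed to [stats::p.adjust()].
#' @param alpha Level for the `significant` flag.
#' @param p_col Name of the p-value column.
#' @return `rows` with `adjusted_pval` and `significant` appended.
#' @export
adjust_multiple <- function(rows, method = "BH", alpha = 0.05, p_col = "pval") {
  if (!p_col %in% names(rows)) abort(sprintf("column '%s' not found", p_col))
  rows$adjusted_pval <- p.adjust(rows[[p_col]], method = method)
  rows$significant <- !is.na(rows$adjusted_pval) & rows$adjusted_pval < alpha
  rows
}

#' Screen many exposures against one outcome
#'
#' Runs [mr_leg()] for each exposure in a named list and returns exactly one
#' IVW row per exposure (rows for legs without sufficient instruments carry
#' `NA` estimates and the leg status), with family-wise multiple-testing
#' adjustment across the screen's IVW p-values.
#'
#' @param exposures Named list of `mr_sumstats` tibbles (e.g. one per
#'   taxon).
#' @param outcome An `mr_sumstats` tibble.
#' @param selection A [selection_config()] shared across exposures.
#' @param adjust_method Passed to [adjust_multiple()].
#' @param alpha Significance level after adjustment.
#' @param ... Passed to [mr_leg()] (e.g. `run_presso = FALSE` for speed).
#' @return A tibble with one row per exposure.
#' @export
mr_screen <- function(exposures, outcome, selection = selection_config(),
                      adjust_method = "BH", alpha = 0.05, ...) {
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    abort("mr_screen(): 'exposures' must be a fully named list")
  }
  rows <- purrr::imap(exposures, function(ss, nm) {
    attr(ss, "trait_label") <- nm
    leg <- mr_leg(ss, outcome, selection = selection, ...)
    if (leg$status != "ok") {
      tibble(
        exposure = nm, outcome = attr(outcome, "trait_label") %||% "outcome",
        method = "ivw_fixed", k = leg$n_selected,
        beta = NA_real_, se = NA_real_, pval = NA_real_,
        or_ = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
        q_stat = NA_real_, q_pval = NA_real_,
        egger_intercept_pval = NA_real_, presso_global_pval = NA_real_,
        f_stat = NA_real_, effect_scale = NA_character_, status = leg$status
      )
    } else {
      leg$report[leg$report$method %in% c("ivw_fixed", "ivw_random"), ][1, ]
    }
  })
  adjust_multiple(dplyr::bind_rows(rows), method = adjust_method, alpha = alpha)
}
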