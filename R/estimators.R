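new_mr_result <- function(method, beta, se, pval, k,
                          q_stat = NA_real_, q_pval = NA_real_, i2 = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_se = NA_real_,
                          egger_intercept_pval = NA_real_,
                          pleiotropy_evidence = NA,
                          n_boot = NA_integer_, seed = NA_integer_,
                          exposure = NA_character_, outcome = NA_character_) {
  z <- qnorm(0.975)
  structure(
    list(
      method = method, beta = beta, se = se, pval = pval, k = k,
      ci_low = beta - z * se, ci_high = beta + z * se,
      q_stat = q_stat, q_pval = q_pval, i2 = i2,
      egger_intercept = egger_intercept,
      egger_intercept_se = egger_intercept_se,
      egger_intercept_pval = egger_intercept_pval,
      pleiotropy_evidence = pleiotropy_evidence,
      n_boot = n_boot, seed = seed,
      exposure = exposure, outcome = outcome
    ),
    class = "mr_result"
  )
}

.check_harmonized <- function(dat, min_k = 1, caller = "estimator") {
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(need %in% names(dat))) {
    abort(paste0(caller, "(): input needs columns ", paste(need, collapse = ", ")))
  }
  if (nrow(dat) < min_k) {
    abort(sprintf("%s() requires at least %d instrument(s), got %d",
                  caller, min_k, nrow(dat)))
  }
  if (any(dat$se_exp <= 0) || any(dat$se_out <= 0)) {
    abort(paste0(caller, "(): standard errors must be positive"))
  }
  invisible(dat)
}

.labels_of <- function(dat) {
  list(
    exposure = attr(dat, "exposure_label") %||% NA_character_,
    outcome = attr(dat, "outcome_label") %||% NA_character_
  )
}

#' Single-instrument Wald ratio
#'
#' The degenerate one-instrument causal estimate `beta_out / beta_exp`, with
#' the first-order delta-method standard error `se_out / |beta_exp|` and a
#' two-sided normal p-value.
#'
#' @param dat A one-row harmonized tibble (extra rows are an error).
#' @return An `mr_result`.
#' @export
mr_wald_ratio <- function(dat) {
  .check_harmonized(dat, 1, "mr_wald_ratio")
  if (nrow(dat) != 1) abort("mr_wald_ratio() takes exactly one record")
  if (dat$beta_exp == 0) abort("mr_wald_ratio(): beta_exp must be nonzero")
  beta <- dat$beta_out / dat$beta_exp
  se <- dat$se_out / abs(dat$beta_exp)
  lab <- .labels_of(dat)
  new_mr_result("wald_ratio", beta, se, 2 * pnorm(-abs(beta / se)), k = 1,
                exposure = lab$exposure, outcome = lab$outcome)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum (1/se_out^2) (beta_out - beta_ref * beta_exp)^2`, referred to a
#' chi-square with k - 1 degrees of freedom, together with the
#' heterogeneity fraction `I2 = max(0, (Q - (k-1))/Q)`.
#'
#' @param dat A harmonized tibble.
#' @param beta_ref The reference causal slope (normally the fixed-effect
#'   IVW estimate).
#' @return A list with `q_stat`, `q_pval`, `i2`, `df`.
#' @export
cochran_q <- function(dat, beta_ref) {
  .check_harmonized(dat, 2, "cochran_q")
  k <- nrow(dat)
  q <- sum((dat$beta_out - beta_ref * dat$beta_exp)^2 / dat$se_out^2)
  list(
    q_stat = q,
    q_pval = pchisq(q, df = k - 1, lower.tail = FALSE),
    i2 = if (q > 0) max(0, (q - (k - 1)) / q) else 0,
    df = k - 1
  )
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_out^2`:
#' `beta = sum(w beta_exp beta_out) / sum(w beta_exp^2)`, fixed-effect
#' standard error `sqrt(1 / sum(w beta_exp^2))`. The random-effects mode
#' inflates the standard error by `sqrt(max(1, Q/(k-1)))` (multiplicative
#' overdispersion, floored at 1, so it never undercuts the fixed model);
#' `mode = "auto"` switches to random effects when the Cochran Q p-value
#' falls below `het_alpha`. P-values use the normal reference. A single
#' record delegates to [mr_wald_ratio()].
#'
#' @param dat A harmonized tibble (k >= 1 rows).
#' @param mode `"fixed"`, `"random"`, or `"auto"`.
#' @param het_alpha Q-test level driving the auto switch.
#' @return An `mr_result` with heterogeneity statistics attached; `method`
#'   records which mode was used.
#' @examples
#' d <- tibble::tibble(beta_exp = c(1, 1), se_exp = 0.05,
#'                     beta_out = c(0.5, 0.5), se_out = 0.1)
#' mr_ivw(d)$se  # 0.1/sqrt(2)
#' @export
mr_ivw <- function(dat, mode = c("fixed", "random", "auto"), het_alpha = 0.05) {
  mode <- match.arg(mode)
  .check_harmonized(dat, 1, "mr_ivw")
  if (nrow(dat) == 1) return(mr_wald_ratio(dat))
  k <- nrow(dat)
  w <- 1 / dat$se_out^2
  sxx <- sum(w * dat$beta_exp^2)
  if (sxx == 0) abort("mr_ivw(): all exposure betas are zero")
  beta <- sum(w * dat$beta_exp * dat$beta_out) / sxx
  se_fixed <- sqrt(1 / sxx)
  het <- cochran_q(dat, beta)
  use_random <- switch(mode,
    fixed = FALSE,
    random = TRUE,
    auto = het$q_pval < het_alpha
  )
  infl <- if (use_random) sqrt(max(1, het$q_stat / (k - 1))) else 1
  se <- se_fixed * infl
  lab <- .labels_of(dat)
  new_mr_result(
    method = if (use_random) "ivw_random" else "ivw_fixed",
    beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)), k = k,
    q_stat = het$q_stat, q_pval = het$q_pval, i2 = het$i2,
    exposure = lab$exposure, outcome = lab$outcome
  )
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept (weights `1/se_out^2`), after orienting every record so
#' the exposure effect is non-negative. The slope is the causal estimate;
#' the heterogeneity statistic is taken about the Egger fit itself (k - 2
#' degrees of freedom); the intercept estimates the average directional
#' pleiotropic effect, and
#' its p-value (t reference with k - 2 degrees of freedom, as is usual at
#' the small instrument counts typical here) tests for directional
#' pleiotropy — values above 0.05 are weak evidence of pleiotropy, recorded
#' in `pleiotropy_evidence`. Standard errors use multiplicative
#' overdispersion with the scale floored at 1.
#'
#' @param dat A harmonized tibble (k >= 3 rows).
#' @param pleio_alpha Level for the intercept-based pleiotropy flag.
#' @return An `mr_result` with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval` filled in.
#' @export
mr_egger <- function(dat, pleio_alpha = 0.05) {
  .check_harmonized(dat, 3, "mr_egger")
  k <- nrow(dat)
  s <- sign(dat$beta_exp)
  s[s == 0] <- 1
  bx <- dat$beta_exp * s
  by <- dat$beta_out * s
  w <- 1 / dat$se_out^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx_inv <- solve(crossprod(X, X * w))
  coefs <- drop(xtwx_inv %*% crossprod(X, by * w))
  resid <- by - drop(X %*% coefs)
  phi <- sum(w * resid^2) / (k - 2)
  se_vec <- sqrt(diag(xtwx_inv)) * sqrt(max(1, phi))
  tstat <- coefs / se_vec
  pvals <- 2 * pt(-abs(tstat), df = k - 2)
  # heterogeneity about the Egger fit itself (intercept included), df = k - 2
  q <- sum(w * resid^2)
  het <- list(
    q_stat = q,
    q_pval = pchisq(q, df = k - 2, lower.tail = FALSE),
    i2 = if (q > 0) max(0, (q - (k - 2)) / q) else 0
  )
  lab <- .labels_of(dat)
  new_mr_result(
    method = "egger",
    beta = coefs[["slope"]], se = se_vec[["slope"]], pval = pvals[["slope"]],
    k = k, q_stat = het$q_stat, q_pval = het$q_pval, i2 = het$i2,
    egger_intercept = coefs[["intercept"]],
    egger_intercept_se = se_vec[["intercept"]],
    egger_intercept_pval = pvals[["intercept"]],
    pleiotropy_evidence = pvals[["intercept"]] <= pleio_alpha,
    exposure = lab$exposure, outcome = lab$outcome
  )
}

# Weighted interpolated median of ratios r with weights w: the point
# estimate of the weighted-median estimator.
.weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  k <- length(r)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[k]) return(r[k])
  j <- max(which(s <= 0.5))
  if (s[j] == 0.5) return(r[j])
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted-median estimator
#'
#' Per-instrument ratio estimates `r_j = beta_out_j / beta_exp_j` with
#' first-order inverse-variance weights `w_j = (beta_exp_j / se_out_j)^2`;
#' the causal estimate is the weighted 50th percentile of the sorted ratios,
#' interpolating linearly in the normalized cumulative weights
#' `s_j = (cumsum(w)_j - w_j/2) / sum(w)`. It is consistent as long as at
#' least half the weight comes from valid instruments. The standard error
#' comes from a parametric bootstrap: exposure and outcome effects are
#' redrawn from normals centred at their estimates with their standard
#' errors, the estimator recomputed, and the replicate standard deviation
#' reported. Records with `beta_exp == 0` are excluded with a warning.
#'
#' @param dat A harmonized tibble (k >= 3 usable rows).
#' @param n_boot Bootstrap replicates (default 1,000).
#' @param seed Optional integer seed scoping the bootstrap draws; recorded
#'   in the result for reproducibility.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed = NULL) {
  .check_harmonized(dat, 3, "mr_weighted_median")
  zero <- dat$beta_exp == 0
  if (any(zero)) {
    warn(sprintf("mr_weighted_median(): excluding %d record(s) with beta_exp = 0", sum(zero)))
    dat <- dat[!zero, , drop = FALSE]
  }
  if (nrow(dat) < 3) abort("mr_weighted_median() requires at least 3 usable instruments")
  if (!(n_boot >= 1)) abort("n_boot must be at least 1")
  k <- nrow(dat)
  wm_of <- function(bx, by) {
    .weighted_median_point(by / bx, (bx / dat$se_out)^2)
  }
  beta <- wm_of(dat$beta_exp, dat$beta_out)
  boot_fun <- function() {
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(k, dat$beta_exp, dat$se_exp)
      by <- rnorm(k, dat$beta_out, dat$se_out)
      bx[bx == 0] <- .Machine$double.eps
      wm_of(bx, by)
    }, numeric(1))
    sd(reps)
  }
  se <- if (is.null(seed)) boot_fun() else withr::with_seed(seed, boot_fun())
  lab <- .labels_of(dat)
  new_mr_result(
    method = "weighted_median", beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), k = k,
    n_boot = as.integer(n_boot), seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    exposure = lab$exposure, outcome = lab$outcome
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "<mr_result> %s: beta = %.5g (se %.4g), p = %.3g, k = %d\n",
    x$method, x$beta, x$se, x$pval, x$k
  ))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  Cochran Q = %.4g (p = %.3g), I2 = %.1f%%\n",
                x$q_stat, x$q_pval, 100 * x$i2))
  }
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4g (p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_pval))
  }
  invisible(x)
}

#' @describeIn mr_ivw Tidy a fitted `mr_result` into a one-row tibble with
#'   `method`, `estimate`, `std.error`, `statistic`, `p.value`, `conf.low`,
#'   `conf.high`, `k`.
#' @param x An `mr_result`.
#' @param ... Unused.
#' @export
tidy.mr_result <- function(x, ...) {
  tibble(
    exposure = x$exposure, outcome = x$outcome,
    method = x$method, estimate = x$beta, std.error = x$se,
    statistic = x$beta / x$se, p.value = x$pval,
    conf.low = x$ci_low, conf.high = x$ci_high, k = x$k
  )
}

#' @describeIn mr_ivw One-row tibble of fit-level diagnostics (heterogeneity
#'   and, for MR-Egger, the intercept test).
#' @export
glance.mr_result <- function(x, ...) {
  tibble(
    method = x$method, k = x$k,
    q_stat = x$q_stat, q_pval = x$q_pval, i2 = x$i2,
    egger_intercept = x$egger_intercept,
    egger_intercept_pval = x$egger_intercept_pval,
    pleiotropy_evidence = x$pleiotropy_evidence
  )
}
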