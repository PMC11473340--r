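#' Product-of-coefficients indirect effect
#'
#' The indirect (mediated) effect of an exposure on an outcome through a
#' mediator is the product of the exposure-to-mediator effect `beta_a` and
#' the mediator-to-outcome effect `beta_b`, with the first-order
#' delta-method standard error
#' `sqrt(beta_a^2 se_b^2 + beta_b^2 se_a^2)`.
#'
#' @param beta_a,se_a Exposure-to-mediator estimate and standard error.
#' @param beta_b,se_b Mediator-to-outcome estimate and standard error.
#' @return A one-row tibble with `indirect_beta`, `indirect_se` and the
#'   normal-reference `indirect_pval`.
#' @examples
#' indirect_effect(-0.0219, 0.01, 0.00845, 0.002)
#' @export
indirect_effect <- function(beta_a, se_a, beta_b, se_b) {
  if (se_a < 0 || se_b < 0) abort("standard errors must be non-negative")
  b <- beta_a * beta_b
  se <- sqrt(beta_a^2 * se_b^2 + beta_b^2 * se_a^2)
  p <- if (se > 0) 2 * pnorm(-abs(b / se)) else as.numeric(b == 0)
  tibble(indirect_beta = b, indirect_se = se, indirect_pval = p)
}

#' Proportion of the total effect that is mediated
#'
#' The exact ratio `indirect_beta / total_beta`, a signed fraction
#' (multiply by 100 only at presentation). Mediation is called
#' "inconsistent" when the indirect and total effects disagree in sign or
#' the proportion exceeds 1 in magnitude; the estimate is still returned.
#'
#' @param indirect_beta Indirect effect.
#' @param total_beta Total effect; must be nonzero.
#' @return A one-row tibble with `proportion` and `inconsistent`.
#' @export
proportion_mediated <- function(indirect_beta, total_beta) {
  if (total_beta == 0) abort("proportion_mediated(): total_beta must be nonzero")
  p <- indirect_beta / total_beta
  inconsistent <- (indirect_beta != 0 && sign(indirect_beta) != sign(total_beta)) ||
    abs(p) > 1
  tibble(proportion = p, inconsistent = inconsistent)
}

.coerce_leg <- function(x, what) {
  if (inherits(x, "mr_result")) {
    list(beta = x$beta, se = x$se, pval = x$pval)
  } else if (is.list(x) && all(c("beta", "se") %in% names(x))) {
    list(beta = x$beta, se = x$se, pval = x$pval %||% NA_real_)
  } else {
    abort(sprintf("two_step(): '%s' must be an mr_result or a list with beta/se", what))
  }
}

#' Assemble a two-step mediation result from three MR legs
#'
#' Combines the total-effect leg (exposure to outcome), leg A (exposure to
#' mediator) and leg B (mediator to outcome) into the product-of-coefficients
#' mediation decomposition: indirect effect `beta_a * beta_b`, delta-method
#' standard error, direct effect `total - indirect`, and proportion
#' mediated `indirect / total`.
#'
#' @param total,leg_a,leg_b `mr_result` objects (or lists with `beta`, `se`,
#'   optionally `pval`).
#' @param exposure,mediator,outcome Trait labels carried into the result.
#' @return An object of class `mr_mediation`.
#' @examples
#' two_step(list(beta = -0.007139, se = 0.002),
#'          list(beta = -0.0219, se = 0.01),
#'          list(beta = 0.00845, se = 0.002))
#' @export
two_step <- function(total, leg_a, leg_b,
                     exposure = "exposure", mediator = "mediator",
                     outcome = "outcome") {
  tot <- .coerce_leg(total, "total")
  a <- .coerce_leg(leg_a, "leg_a")
  b <- .coerce_leg(leg_b, "leg_b")
  ind <- indirect_effect(a$beta, a$se, b$beta, b$se)
  prop <- proportion_mediated(ind$indirect_beta, tot$beta)
  structure(
    list(
      exposure = exposure, mediator = mediator, outcome = outcome,
      total_beta = tot$beta, total_se = tot$se, total_pval = tot$pval,
      beta_a = a$beta, se_a = a$se, pval_a = a$pval,
      beta_b = b$beta, se_b = b$se, pval_b = b$pval,
      indirect_beta = ind$indirect_beta,
      indirect_se = ind$indirect_se,
      indirect_pval = ind$indirect_pval,
      direct_beta = tot$beta - ind$indirect_beta,
      proportion = prop$proportion,
      inconsistent = prop$inconsistent
    ),
    class = "mr_mediation"
  )
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf("<mr_mediation> %s -> %s -> %s\n", x$exposure, x$mediator, x$outcome))
  cat(sprintf("  total  = %.6g   (exposure -> outcome)\n", x$total_beta))
  cat(sprintf("  beta A = %.6g   (exposure -> mediator)\n", x$beta_a))
  cat(sprintf("  beta B = %.6g   (mediator -> outcome)\n", x$beta_b))
  cat(sprintf("  indirect = %.6g (se %.3g), direct = %.6g\n",
              x$indirect_beta, x$indirect_se, x$direct_beta))
  cat(sprintf("  proportion mediated = %.4f (%.2f%%)%s\n",
              x$proportion, 100 * x$proportion,
              if (isTRUE(x$inconsistent)) " [inconsistent mediation]" else ""))
  invisible(x)
}

#' @describeIn two_step One-row tibble in the shape of a two-step report
#'   row: the three leg betas, indirect effect, proportion mediated.
#' @param x An `mr_mediation` object.
#' @param ... Unused.
#' @export
tidy.mr_mediation <- function(x, ...) {
  tibble(
    exposure = x$exposure, mediator = x$mediator, outcome = x$outcome,
    total_beta = x$total_beta, beta_a = x$beta_a, beta_b = x$beta_b,
    indirect_beta = x$indirect_beta, indirect_se = x$indirect_se,
    direct_beta = x$direct_beta,
    proportion = x$proportion, proportion_pct = 100 * x$proportion,
    inconsistent = x$inconsistent
  )
}

#' @describeIn two_step One-row tibble of the three leg p-values and the
#'   indirect-effect test.
#' @export
glance.mr_mediation <- function(x, ...) {
  tibble(
    total_pval = x$total_pval, pval_a = x$pval_a, pval_b = x$pval_b,
    indirect_pval = x$indirect_pval
  )
}
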