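#' Scatter plot of one MR leg
#'
#' Exposure effects against outcome effects for the harmonized instruments,
#' with one fitted line per estimator (IVW through the origin, MR-Egger with
#' its intercept, weighted median as a slope through the origin) and
#' per-instrument standard-error bars.
#'
#' @param object An `mr_leg` with status `"ok"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_leg <- function(object, ...) {
  if (object$status != "ok") abort("cannot plot a leg without instruments")
  h <- as_tibble(object$harmonized)
  s <- sign(h$beta_exp)
  s[s == 0] <- 1
  h$bx <- h$beta_exp * s
  h$by <- h$beta_out * s
  fits <- purrr::imap(object$results, function(res, nm) {
    tibble(
      method = res$method,
      intercept = if (nm == "egger") res$egger_intercept else 0,
      slope = res$beta
    )
  })
  fits <- dplyr::bind_rows(fits)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$by - .data$se_out, ymax = .data$by + .data$se_out),
      width = 0, colour = "grey60"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$bx - .data$se_exp, xmax = .data$bx + .data$se_exp),
      height = 0, colour = "grey60"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$method)
    ) +
    ggplot2::labs(
      x = sprintf("effect on %s", object$exposure),
      y = sprintf("effect on %s", object$outcome),
      colour = "method"
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of report rows
#'
#' Odds ratios (or exponentiated betas) with confidence intervals, one row
#' per exposure/method combination, in the style of an MR screen summary.
#'
#' @param rows A report tibble from [mr_leg()], [mr_screen()] or
#'   [adjust_multiple()], containing `exposure`, `method`, `or_`,
#'   `or_ci_low`, `or_ci_high`.
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(rows) {
  rows <- rows[!is.na(rows$or_), , drop = FALSE]
  if (nrow(rows) == 0) abort("no estimable rows to plot")
  rows$label <- paste(rows$exposure, rows$method, sep = " / ")
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$or_, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$or_ci_low, xmax = .data$or_ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
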