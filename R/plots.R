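#' Diagnostic scatter of fitted versus reference log D for a QSRR fit
#'
#' @param object A `qsrr_fit`.
#' @param ... Unused.
#' @return A ggplot: fitted values against the training response, with the
#'   identity line.
#' @method autoplot qsrr_fit
#' @export
autoplot.qsrr_fit <- function(object, ...) {
  d <- tibble(
    reference = object$fitted + object$residuals,
    fitted = object$fitted
  )
  ggplot(d, aes(x = .data$reference, y = .data$fitted)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.8) +
    labs(
      x = "reference log D",
      y = "fitted log D",
      title = object$name,
      subtitle = sprintf("N = %d, R² = %.4f", object$n, object$r2)
    ) +
    theme_minimal()
}

#' Fitted-versus-reference panels for both cascade stages
#'
#' @param object A `qsrr_cascade`.
#' @param ... Unused.
#' @return A ggplot faceted by stage.
#' @method autoplot qsrr_cascade
#' @export
autoplot.qsrr_cascade <- function(object, ...) {
  d <- bind_rows(
    tibble(
      stage = sprintf("stage 1 (IS), R² = %.3f", object$stage1$r2),
      reference = object$stage1$fitted + object$stage1$residuals,
      fitted = object$stage1$fitted
    ),
    tibble(
      stage = sprintf("stage 2 (IP), R² = %.3f", object$stage2$r2),
      reference = object$stage2$fitted + object$stage2$residuals,
      fitted = object$stage2$fitted
    )
  )
  ggplot(d, aes(x = .data$reference, y = .data$fitted)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.8) +
    facet_wrap(~stage) +
    labs(x = "reference log D", y = "fitted log D") +
    theme_minimal()
}

#' Signed-error plot of an external-validation report
#'
#' @param object A `prediction_report`.
#' @param bound Relative-error bound drawn as context in the point colour
#'   (default 0.10).
#' @param ... Unused.
#' @return A ggplot of predicted vs reference log D, coloured by whether the
#'   row exceeds the relative-error bound.
#' @method autoplot prediction_report
#' @export
autoplot.prediction_report <- function(object, bound = 0.10, ...) {
  d <- as_tibble(object) |>
    mutate(within = ifelse(.data$rel_error <= bound, "within bound", "discrepant"))
  ggplot(d, aes(x = .data$reference, y = .data$predicted, colour = .data$within)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(size = 2) +
    labs(
      x = "reference log D", y = "predicted log D (stage 2)",
      colour = sprintf("relative error vs %.0f%%", 100 * bound)
    ) +
    theme_minimal()
}

#' Retention linearity plot: log k against organic-modifier fraction
#'
#' Plots the measured log retention factors and the fitted LSS lines for each
#' (compound, mode), the standard visual check behind the extrapolation of
#' `log_kw`.
#'
#' @param data Retention measurements as taken by [fit_lss()].
#' @param fits Optional precomputed [fit_lss()] result; computed (quietly) if
#'   omitted.
#' @param denominator Passed to [retention_factor()].
#' @return A ggplot.
#' @export
plot_lss <- function(data, fits = NULL, denominator = c("t0", "tR")) {
  denominator <- match.arg(denominator)
  if (is.null(fits)) {
    fits <- suppressWarnings(fit_lss(data, denominator = denominator))
  }
  pts <- data |>
    group_by(.data$compound_id, .data$mode, .data$phi) |>
    summarise(t_r = mean(.data$t_r), t_0 = mean(.data$t_0), .groups = "drop") |>
    mutate(log_k = log10(retention_factor(.data$t_r, .data$t_0, denominator)))
  ggplot(pts, aes(x = .data$phi, y = .data$log_k, colour = .data$compound_id)) +
    geom_point() +
    geom_abline(
      data = fits,
      aes(intercept = .data$log_kw, slope = -.data$s, colour = .data$compound_id),
      linewidth = 0.3
    ) +
    facet_wrap(~mode) +
    labs(
      x = expression(phi ~ "(organic modifier volume fraction)"),
      y = expression(log[10] ~ k), colour = "compound"
    ) +
    theme_minimal()
}
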