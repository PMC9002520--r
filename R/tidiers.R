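#' Tidy a Bland-Altman result
#'
#' @param x A `ba_result`.
#' @param ... Unused.
#' @return Tibble with one row per quantity (`bias`, `loa_lower`,
#'   `loa_upper`) and columns `term`, `estimate`, `conf.low`, `conf.high`.
#' @method tidy ba_result
#' @export
tidy.ba_result <- function(x, ...) {
  tibble::tibble(
    term = c("bias", "loa_lower", "loa_upper"),
    estimate = c(x$bias, x$loa_lower, x$loa_upper),
    conf.low = c(x$ci_bias[1], x$ci_loa_lower[1], x$ci_loa_upper[1]),
    conf.high = c(x$ci_bias[2], x$ci_loa_lower[2], x$ci_loa_upper[2])
  )
}

#' Glance at a Bland-Altman result
#'
#' @param x A `ba_result`.
#' @param ... Unused.
#' @return One-row tibble: bias, limits, total SD, variance components,
#'   counts, method and gate p-values (when the decision tree produced it).
#' @method glance ba_result
#' @export
glance.ba_result <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, loa_lower = x$loa_lower, loa_upper = x$loa_upper,
    sd_total = x$sd_total, var_between = x$var_between,
    var_within = x$var_within, n = x$n, m = x$m, method = x$method,
    proportional_bias = x$gates$proportional_bias %||% FALSE,
    heteroscedastic = x$gates$heteroscedastic %||% FALSE,
    non_normal = x$gates$non_normal %||% NA,
    transform = x$gates$transform %||% "none"
  )
}

#' Tidy a modeled Bland-Altman result
#'
#' @param x A `modeled_ba`.
#' @param ... Unused.
#' @return Tibble of the four coefficients (`b0`, `b1`, `c0`, `c1`) with
#'   bootstrap confidence intervals.
#' @method tidy modeled_ba
#' @export
tidy.modeled_ba <- function(x, ...) x$coef_ci

#' Glance at a modeled Bland-Altman result
#'
#' @param x A `modeled_ba`.
#' @param ... Unused.
#' @return One-row tibble: coefficients, flags, gate p-values, the bias and
#'   LOA evaluated at the mean reference value, and counts.
#' @method glance modeled_ba
#' @export
glance.modeled_ba <- function(x, ...) {
  at_mean <- predict(x)
  tibble::tibble(
    b0 = x$b0, b1 = x$b1, c0 = x$c0, c1 = x$c1,
    loa_multiplier = x$loa_multiplier,
    bias_at_mean = at_mean$bias,
    loa_lower_at_mean = at_mean$loa_lower,
    loa_upper_at_mean = at_mean$loa_upper,
    proportional_bias = x$gates$proportional_bias,
    heteroscedastic = x$gates$heteroscedastic,
    non_normal = x$gates$non_normal,
    normality_p = x$gates$normality_p,
    proportional_bias_p = x$gates$proportional_bias_p,
    heteroscedasticity_p = x$gates$heteroscedasticity_p,
    transform = x$transform, n = x$n, m = x$m, method = "modeled"
  )
}

#' Bland-Altman plot
#'
#' Difference against reference value with bias and limit lines and their
#' confidence bands.
#'
#' @param object A `ba_result` carrying its pair data.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ba_result
#' @export
autoplot.ba_result <- function(object, ...) {
  if (is.null(object$data)) {
    abort("This result carries no pair data to plot.",
          class = "sleepagree_input_error")
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ref, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "red") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        colour = "red", linetype = "dashed") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$ci_bias[1], ymax = object$ci_bias[2],
                      alpha = 0.15, fill = "red") +
    ggplot2::labs(x = "Reference measurement",
                  y = "Difference (reference - device)") +
    ggplot2::theme_minimal()
}

#' Modeled Bland-Altman plot
#'
#' Difference against reference with the regression-modeled bias line and the
#' heteroscedastic limits `bias +/- 2.46 (c0 + c1 ref)`.
#'
#' @param object A `modeled_ba`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot modeled_ba
#' @export
autoplot.modeled_ba <- function(object, ...) {
  grid <- predict(object, ref = seq(object$ref_range[1], object$ref_range[2],
                                    length.out = 100))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ref, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$bias), colour = "red") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$loa_lower),
                       colour = "red", linetype = "dashed") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$loa_upper),
                       colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "Reference measurement",
                  y = "Difference (reference - device)") +
    ggplot2::theme_minimal()
}
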