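new_ba_result <- function(bias, sd_total, n, m = NA_integer_,
                          var_between = NA_real_, var_within = NA_real_,
                          ci_bias, ci_loa_lower, ci_loa_upper,
                          method, data = NULL, gates = NULL) {
  structure(
    list(bias = bias, loa_lower = bias - 1.96 * sd_total,
         loa_upper = bias + 1.96 * sd_total, sd_total = sd_total,
         ci_bias = ci_bias, ci_loa_lower = ci_loa_lower,
         ci_loa_upper = ci_loa_upper,
         var_between = var_between, var_within = var_within,
         n = n, m = m, method = method, data = data, gates = gates),
    class = "ba_result"
  )
}

#' Simple Bland-Altman analysis (one pair per subject)
#'
#' Differences are oriented `reference - device`, so a positive bias means the
#' device underestimates the reference. Limits of agreement are
#' `bias +/- 1.96 * SD` of the differences (n - 1 denominator), with the
#' classical confidence intervals: `CI(bias) = bias +/- t * SD / sqrt(n)` and
#' `CI(LOA) = LOA +/- t * SD * sqrt(3 / n)`, t the 97.5% quantile on n - 1
#' degrees of freedom.
#'
#' @param ref,dev Numeric vectors of paired reference and device measurements
#'   (one per subject), or `dev = NULL` to treat `ref` as precomputed
#'   differences.
#' @return Object of class `ba_result`. See [tidy.ba_result()],
#'   [glance.ba_result()], [autoplot.ba_result()].
#' @examples
#' simple_ba(c(16, 20, 12), c(13, 17, 9))  # constant difference of 3
#' @export
simple_ba <- function(ref, dev = NULL) {
  d <- if (is.null(dev)) ref else ref - dev
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) {
    abort("At least 3 paired differences are required.",
          class = "sleepagree_insufficient_data_error")
  }
  bias <- mean(d)
  s <- sd(d)
  tq <- qt(0.975, n - 1)
  half_loa <- tq * s * sqrt(3 / n)
  dat <- if (is.null(dev)) NULL else
    tibble::tibble(mean = (ref + dev) / 2, ref = ref, diff = ref - dev)
  new_ba_result(
    bias = bias, sd_total = s, n = n,
    ci_bias = bias + c(-1, 1) * tq * s / sqrt(n),
    ci_loa_lower = bias - 1.96 * s + c(-1, 1) * half_loa,
    ci_loa_upper = bias + 1.96 * s + c(-1, 1) * half_loa,
    method = "simple", data = dat
  )
}

#' Repeated-measures Bland-Altman analysis
#'
#' For epoch-by-epoch comparisons with many differences per subject. The
#' difference variance is decomposed by one-way random-effects ANOVA with
#' subject as the grouping factor: within-subject variance is the mean square
#' within; between-subject variance is `max(0, (MSB - MSW) / n0)` with the
#' unequal-group-size correction `n0 = (N - sum(n_i^2) / N) / (m - 1)`. Limits
#' of agreement are `bias +/- 1.96 * sqrt(between + within)`. Confidence
#' intervals use the delta method: `Var(bias) = between * sum(n_i^2) / N^2 +
#' within / N`, `Var(total SD)` from the chi-square variances of the two mean
#' squares, with t quantiles on m - 1 degrees of freedom.
#'
#' If any subject contributes fewer than 2 differences the function falls
#' back to [simple_ba()] over all differences, with a warning.
#'
#' @param data Data frame with one row per paired epoch.
#' @param ref,dev,subject Column names of the reference value, device value
#'   and subject identifier.
#' @return Object of class `ba_result` with variance components.
#' @export
rm_ba <- function(data, ref = "ref", dev = "dev", subject = "subject") {
  d <- data[[ref]] - data[[dev]]
  g <- as.character(data[[subject]])
  ok <- is.finite(d) & !is.na(g)
  d <- d[ok]; g <- g[ok]
  ni <- tapply(rep(1, length(d)), g, sum)
  if (length(ni) < 2 || any(ni < 2)) {
    if (any(ni < 2)) {
      warn("Some subjects contribute < 2 differences; falling back to simple Bland-Altman over all differences.")
    }
    return(simple_ba(d))
  }
  N <- length(d); m <- length(ni)
  gm <- mean(d)
  means <- tapply(d, g, mean)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((d - means[g])^2)
  msb <- ssb / (m - 1)
  msw <- ssw / (N - m)
  n0 <- (N - sum(ni^2) / N) / (m - 1)
  between <- max(0, (msb - msw) / n0)
  within <- msw
  sd_total <- sqrt(between + within)
  var_bias <- between * sum(ni^2) / N^2 + within / N
  # delta method on sigma_total^2 = MSB/n0 + (1 - 1/n0) MSW
  var_sd2 <- (2 * msb^2 / (m - 1)) / n0^2 + (1 - 1 / n0)^2 * 2 * msw^2 / (N - m)
  var_sd <- if (sd_total > 0) var_sd2 / (4 * sd_total^2) else 0
  var_loa <- var_bias + 1.96^2 * var_sd
  tq <- qt(0.975, m - 1)
  dat <- tibble::tibble(
    mean = (data[[ref]][ok] + data[[dev]][ok]) / 2,
    ref = data[[ref]][ok], diff = d, subject = g
  )
  new_ba_result(
    bias = gm, sd_total = sd_total, n = N, m = m,
    var_between = between, var_within = within,
    ci_bias = gm + c(-1, 1) * tq * sqrt(var_bias),
    ci_loa_lower = gm - 1.96 * sd_total + c(-1, 1) * tq * sqrt(var_loa),
    ci_loa_upper = gm + 1.96 * sd_total + c(-1, 1) * tq * sqrt(var_loa),
    method = "repeated", data = dat
  )
}

#' Test for proportional bias
#'
#' Ordinary least squares of the difference (reference - device) on the
#' reference value; proportional bias is flagged when the two-sided t-test on
#' the slope is significant.
#'
#' @param ref,dev Numeric paired measurements.
#' @param alpha Significance level for the flag.
#' @return List with `b0`, `b1`, `p` (slope p-value), `ci_b0`, `ci_b1`,
#'   `detected`, and the `lm` fit.
#' @export
test_proportional_bias <- function(ref, dev, alpha = 0.05) {
  ok <- is.finite(ref) & is.finite(dev)
  ref <- ref[ok]; dev <- dev[ok]
  if (length(ref) < 4) {
    abort("At least 4 pairs are required.",
          class = "sleepagree_insufficient_data_error")
  }
  if (sd(ref) == 0) {
    abort("Regression undefined: zero variance in the reference.",
          class = "sleepagree_degenerate_error")
  }
  fit <- lm(I(ref - dev) ~ ref)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  list(b0 = unname(coef(fit)[1]), b1 = unname(coef(fit)[2]),
       p = sm[2, 4], ci_b0 = unname(ci[1, ]), ci_b1 = unname(ci[2, ]),
       detected = sm[2, 4] < alpha, fit = fit)
}

#' Test for heteroscedasticity of the differences
#'
#' Regresses the absolute residuals of the fitted bias model on the reference
#' value. Under homoscedastic normal residuals the absolute residual has mean
#' `sigma * sqrt(2 / pi)`, so the 95% band is recovered as
#' `2.46 * (c0 + c1 * ref)` (2.46 is approximately `1.96 * sqrt(pi / 2)`).
#' Heteroscedasticity is flagged when the slope `c1` is significant.
#'
#' @param ref,dev Numeric paired measurements.
#' @param bias_fit `lm` fit from [test_proportional_bias()]; refitted when
#'   omitted.
#' @param alpha Significance level for the flag.
#' @return List with `c0`, `c1`, `p`, `ci_c0`, `ci_c1`, `detected`, `fit`.
#' @export
test_heteroscedasticity <- function(ref, dev, bias_fit = NULL, alpha = 0.05) {
  ok <- is.finite(ref) & is.finite(dev)
  ref <- ref[ok]; dev <- dev[ok]
  if (is.null(bias_fit)) bias_fit <- test_proportional_bias(ref, dev)$fit
  res <- abs(stats::residuals(bias_fit))
  if (sd(ref) == 0) {
    abort("Regression undefined: zero variance in the reference.",
          class = "sleepagree_degenerate_error")
  }
  fit <- lm(res ~ ref)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  list(c0 = unname(coef(fit)[1]), c1 = unname(coef(fit)[2]),
       p = sm[2, 4], ci_c0 = unname(ci[1, ]), ci_c1 = unname(ci[2, ]),
       detected = sm[2, 4] < alpha, fit = fit)
}

#' Shapiro-Wilk normality gate
#'
#' @param x Numeric differences, 3 <= n <= 5000.
#' @param alpha Significance level for the non-normality flag.
#' @return List with `W`, `p`, `non_normal`.
#' @export
normality_test <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) {
    abort("Shapiro-Wilk supports 3 <= n <= 5000; subsample larger inputs.",
          class = "sleepagree_input_error")
  }
  if (sd(x) == 0) return(list(W = NA_real_, p = 0, non_normal = TRUE))
  sw <- shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value, non_normal = sw$p.value < alpha)
}

#' Basic bootstrap confidence intervals
#'
#' Reflected-percentile ("basic") bootstrap: for estimate `t0` and resample
#' quantiles `q`, the interval is `(2 t0 - q_{1-a/2}, 2 t0 - q_{a/2})`. The
#' resampling unit is configurable: whole rows, whole groups (subjects, for
#' per-subject summary statistics), or rows within each group (epochs within
#' subject, for epoch-level statistics).
#'
#' @param data Data frame passed to `statistic`.
#' @param statistic Function `data -> named numeric vector`.
#' @param B Number of resamples (>= 200).
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @param unit One of "rows", "groups", "within"; the latter two require
#'   `group`.
#' @param group Column name of the grouping variable.
#' @return Tibble with `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
bootstrap_ci <- function(data, statistic, B = 1000, level = 0.95, seed = NULL,
                         unit = c("rows", "groups", "within"), group = "subject") {
  unit <- match.arg(unit)
  if (B < 200) {
    abort("Use at least 200 bootstrap resamples.", class = "sleepagree_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  t0 <- statistic(data)
  k <- length(t0)
  idx_by_group <- if (unit != "rows") split(seq_len(nrow(data)), data[[group]])
  draws <- matrix(NA_real_, B, k)
  for (b in seq_len(B)) {
    idx <- switch(unit,
      rows = sample.int(nrow(data), replace = TRUE),
      groups = unlist(idx_by_group[sample.int(length(idx_by_group), replace = TRUE)],
                      use.names = FALSE),
      within = unlist(lapply(idx_by_group,
                             function(ii) ii[sample.int(length(ii), replace = TRUE)]),
                      use.names = FALSE)
    )
    draws[b, ] <- statistic(data[idx, , drop = FALSE])
  }
  a <- (1 - level) / 2
  lo <- numeric(k); hi <- numeric(k)
  for (j in seq_len(k)) {
    q <- quantile(draws[, j], c(1 - a, a), na.rm = TRUE, names = FALSE)
    lo[j] <- 2 * t0[j] - q[1]
    hi[j] <- 2 * t0[j] - q[2]
    if (isTRUE(all.equal(lo[j], hi[j]))) {
      warn(sprintf("Degenerate bootstrap interval for '%s'.",
                   names(t0)[j] %||% as.character(j)))
    }
  }
  tibble::tibble(term = names(t0) %||% paste0("t", seq_len(k)),
                 estimate = unname(t0), conf.low = lo, conf.high = hi)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors, n >= 4.
#' @param level Confidence level.
#' @return One-row tibble with `r`, `conf.low`, `conf.high`, `n`.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) {
    abort("At least 4 complete pairs are required.",
          class = "sleepagree_insufficient_data_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: zero variance.",
          class = "sleepagree_degenerate_error")
  }
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    return(tibble::tibble(r = r, conf.low = r, conf.high = r, n = n))
  }
  zc <- qnorm(1 - (1 - level) / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * zc / sqrt(n - 3))
  tibble::tibble(r = r, conf.low = ci[1], conf.high = ci[2], n = n)
}

#' Full agreement decision tree
#'
#' Runs the gated Bland-Altman battery on curated reference/device pairs:
#'
#' 1. Shapiro-Wilk on the differences (subsampled to 5000 when larger). If
#'    non-normal and both measurements are non-negative, a `log(x + 1)`
#'    retest is recorded (`transform = "log"`), keeping both p-values.
#' 2. Proportional-bias regression (difference on reference).
#' 3. Heteroscedasticity regression (absolute residuals on reference).
#' 4. If neither regression gate fires: a plain Bland-Altman result -
#'    [simple_ba()] in summary mode, [rm_ba()] in epoch mode. Otherwise: a
#'    regression-modeled result (`modeled_ba`) with bias model
#'    `b0 + b1 * ref` and limits `bias +/- 2.46 * (c0 + c1 * ref)`,
#'    coefficient confidence intervals by basic bootstrap (subjects resampled
#'    in summary mode, epochs within subject in epoch mode). All models are
#'    reported on the original measurement scale so coefficients stay in the
#'    units of the signal.
#'
#' All gate p-values are retained in the result.
#'
#' @param data Data frame of pairs with columns named by `ref`, `dev` and (for
#'   epoch mode) `subject`.
#' @param mode `"epoch"` (repeated measures) or `"summary"` (one pair per
#'   subject).
#' @param ref,dev,subject Column names.
#' @param alpha Gate significance level.
#' @param B Bootstrap resamples for modeled coefficients.
#' @param seed Optional integer seed (gates' subsampling and bootstrap).
#' @param loa_multiplier Multiplier converting the mean absolute residual line
#'   to a 95% band; 2.46 is 1.96 * sqrt(pi / 2).
#' @return A `ba_result` or `modeled_ba` object.
#' @export
analyze_agreement <- function(data, mode = c("epoch", "summary"),
                              ref = "ref", dev = "dev", subject = "subject",
                              alpha = 0.05, B = 1000, seed = NULL,
                              loa_multiplier = 2.46) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  ok <- is.finite(data[[ref]]) & is.finite(data[[dev]])
  data <- data[ok, , drop = FALSE]
  r <- data[[ref]]; d <- data[[dev]]

  gate_sample <- function(x) if (length(x) > 5000) sample(x, 5000) else x
  diffs <- r - d
  if (sd(diffs) == 0) {
    # perfectly agreeing (or constant-offset) channel: gates are vacuous
    out <- if (mode == "summary") simple_ba(r, d)
           else rm_ba(data, ref = ref, dev = dev, subject = subject)
    out$gates <- list(normality_p = NA_real_, non_normal = FALSE,
                      proportional_bias_p = NA_real_, proportional_bias = FALSE,
                      heteroscedasticity_p = NA_real_, heteroscedastic = FALSE,
                      transform = "none", alpha = alpha)
    return(out)
  }
  nt <- normality_test(gate_sample(diffs), alpha)
  transform <- "none"
  if (nt$non_normal && all(r >= 0) && all(d >= 0)) {
    # non-normal differences on a non-negative scale: retest on log(x + 1);
    # the transform is recorded and the retest p kept alongside the original
    transform <- "log"
    nt_log <- normality_test(gate_sample(log1p(r) - log1p(d)), alpha)
    nt <- list(W = nt_log$W, p = nt_log$p, non_normal = nt_log$non_normal,
               p_original = nt$p)
  }
  pb <- test_proportional_bias(r, d, alpha)
  ht <- test_heteroscedasticity(r, d, pb$fit, alpha)
  gates <- list(normality_p = nt$p, non_normal = nt$non_normal,
                proportional_bias_p = pb$p, proportional_bias = pb$detected,
                heteroscedasticity_p = ht$p, heteroscedastic = ht$detected,
                transform = transform, alpha = alpha)

  if (!pb$detected && !ht$detected) {
    out <- if (mode == "summary") simple_ba(r, d)
           else rm_ba(data, ref = ref, dev = dev, subject = subject)
    out$gates <- gates
    return(out)
  }

  # modeled path: original-scale coefficient models
  b <- if (pb$detected) c(b0 = pb$b0, b1 = pb$b1)
       else c(b0 = mean(r - d), b1 = 0)
  res <- if (pb$detected) stats::residuals(pb$fit) else (r - d) - mean(r - d)
  ht_orig_fit <- lm(abs(res) ~ r)
  cc <- if (ht$detected) c(c0 = unname(coef(ht_orig_fit)[1]),
                           c1 = unname(coef(ht_orig_fit)[2]))
        else c(c0 = mean(abs(res)), c1 = 0)

  # bootstrap only the coefficients that are actually estimated; structurally
  # zero terms (b1 without proportional bias, c1 without heteroscedasticity)
  # are reported with a point interval
  coef_stat <- function(dd) {
    rr <- dd[[ref]]; vv <- dd[[dev]]
    f <- lm(I(rr - vv) ~ rr)
    b0b <- if (pb$detected) unname(coef(f)[1]) else mean(rr - vv)
    b1b <- if (pb$detected) unname(coef(f)[2]) else NULL
    rs <- if (pb$detected) stats::residuals(f) else (rr - vv) - mean(rr - vv)
    if (ht$detected) {
      f2 <- lm(abs(rs) ~ rr)
      c(b0 = b0b, b1 = b1b, c0 = unname(coef(f2)[1]), c1 = unname(coef(f2)[2]))
    } else {
      c(b0 = b0b, b1 = b1b, c0 = mean(abs(rs)))
    }
  }
  unit <- if (mode == "summary") "rows" else "within"
  ci <- bootstrap_ci(data, coef_stat, B = B, unit = unit, group = subject)
  for (fixed in setdiff(c("b0", "b1", "c0", "c1"), ci$term)) {
    ci <- dplyr::bind_rows(ci, tibble::tibble(term = fixed, estimate = 0,
                                              conf.low = 0, conf.high = 0))
  }
  ci <- ci[match(c("b0", "b1", "c0", "c1"), ci$term), ]

  structure(
    list(b0 = unname(b[1]), b1 = unname(b[2]),
         c0 = unname(cc[1]), c1 = unname(cc[2]),
         coef_ci = ci, loa_multiplier = loa_multiplier,
         gates = gates, transform = transform,
         mode = mode, n = length(r),
         m = if (mode == "epoch") length(unique(data[[subject]])) else length(r),
         ref_range = range(r), ref_mean = mean(r),
         data = tibble::tibble(ref = r, dev = d, diff = r - d)),
    class = "modeled_ba"
  )
}

#' Evaluate a modeled Bland-Altman fit at reference values
#'
#' @param object A `modeled_ba` object.
#' @param ref Reference values at which to evaluate; defaults to the observed
#'   mean.
#' @param ... Unused.
#' @return Tibble with `ref`, `bias`, `loa_lower`, `loa_upper`.
#' @export
predict.modeled_ba <- function(object, ref = NULL, ...) {
  ref <- ref %||% object$ref_mean
  bias <- object$b0 + object$b1 * ref
  half <- object$loa_multiplier * (object$c0 + object$c1 * ref)
  tibble::tibble(ref = ref, bias = bias,
                 loa_lower = bias - half, loa_upper = bias + half)
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("<Bland-Altman, %s> n = %d%s\n", x$method, x$n,
              if (!is.na(x$m)) sprintf(", subjects = %d", x$m) else ""))
  cat(sprintf("  bias  %8.3f  [%.3f, %.3f]\n", x$bias, x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  LOA   %8.3f  [%.3f, %.3f]\n", x$loa_lower,
              x$ci_loa_lower[1], x$ci_loa_lower[2]))
  cat(sprintf("        %8.3f  [%.3f, %.3f]\n", x$loa_upper,
              x$ci_loa_upper[1], x$ci_loa_upper[2]))
  invisible(x)
}

#' @export
print.modeled_ba <- function(x, ...) {
  cat(sprintf("<Bland-Altman, modeled (%s mode)> n = %d\n", x$mode, x$n))
  cat(sprintf("  bias(ref) = %.3f %+.3f x ref\n", x$b0, x$b1))
  cat(sprintf("  LOA(ref)  = bias +/- %.2f x (%.3f %+.3f x ref)\n",
              x$loa_multiplier, x$c0, x$c1))
  cat(sprintf("  gates: normality p = %.3g%s, prop. bias p = %.3g%s, heterosced. p = %.3g%s\n",
              x$gates$normality_p, if (x$transform == "log") " (log scale)" else "",
              x$gates$proportional_bias_p,
              if (x$gates$proportional_bias) "*" else "",
              x$gates$heteroscedasticity_p,
              if (x$gates$heteroscedastic) "*" else ""))
  invisible(x)
}
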