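#' Overnight profile concordance for one subject
#'
#' Smooths the reference and device HR and BR epoch profiles with a centered
#' 15 min window and computes the lag-zero Pearson correlation over jointly
#' covered epochs (the series are assumed clock-aligned; see
#' [estimate_offset()]).
#'
#' @param data One subject's epoch tibble with columns `ref_hr`, `dev_hr`,
#'   `ref_br`, `dev_br`, `hr_covered`, `br_covered` (and optionally
#'   `psg_artifact`).
#' @param window_minutes Smoothing window, minutes.
#' @return One-row tibble with `r_hr`, `p_hr`, `n_hr`, `r_br`, `p_br`,
#'   `n_br`.
#' @export
subject_concordance <- function(data, window_minutes = 15) {
  art <- if ("psg_artifact" %in% names(data)) data$psg_artifact else FALSE
  one <- function(ref, dev, covered) {
    sr <- smooth_profile(ref, window_minutes, covered = !art)
    sd_ <- smooth_profile(dev, window_minutes, covered = covered & !art)
    profile_xcorr(sr, sd_)
  }
  hr <- one(data$ref_hr, data$dev_hr, data$hr_covered)
  br <- one(data$ref_br, data$dev_br, data$br_covered)
  tibble::tibble(r_hr = hr$r, p_hr = hr$p, n_hr = hr$n,
                 r_br = br$r, p_br = br$p, n_br = br$n)
}

#' Cohort-level concordance of HR and BR profiles
#'
#' Per subject: estimates the device clock offset from the movement channels,
#' realigns the device streams, then computes smoothed-profile lag-zero
#' correlations for HR and BR ([subject_concordance()]). Cohort level:
#' unweighted mean and SD of the correlations and a two-sided paired t-test of
#' the per-subject HR-vs-BR difference.
#'
#' @param cohort A `sleep_cohort`.
#' @param max_lag Maximum clock offset scanned, epochs.
#' @param window_minutes Smoothing window, minutes.
#' @param align Estimate and remove the clock offset first.
#' @return Object of class `concordance_result`: `records` (per-subject
#'   correlations joined to covariates), `summary` (mean/SD per signal),
#'   `paired_p` (HR vs BR paired t-test p, `NA` when all differences vanish).
#' @export
cohort_concordance <- function(cohort, max_lag = 20, window_minutes = 15,
                               align = TRUE) {
  records <- cohort$epochs |>
    dplyr::group_by(subject_id = .data$subject_id) |>
    dplyr::group_modify(function(g, key) {
      lag <- 0L
      if (align) {
        est <- estimate_offset(g$ref_move, g$dev_move, max_lag = max_lag)
        lag <- est$lag
      }
      g2 <- g
      if (lag != 0L) {
        for (col in c("dev_hr", "dev_br")) {
          shifted <- apply_offset(g[[col]], -lag,
                                  covered = g[[sub("dev_(hr|br)", "\\1_covered", col)]])
          g2[[col]] <- shifted$value
          g2[[sub("dev_(hr|br)", "\\1_covered", col)]] <- shifted$covered
        }
      }
      dplyr::mutate(subject_concordance(g2, window_minutes), lag = lag)
    }) |>
    dplyr::ungroup()
  if (!is.null(cohort$subjects)) {
    records <- dplyr::left_join(
      records,
      dplyr::select(cohort$subjects, "subject_id",
                    dplyr::any_of(c("age", "sex", "bmi", "ahi"))),
      by = "subject_id"
    )
  }
  if (nrow(records) < 3) {
    abort("At least 3 subjects are required.",
          class = "sleepagree_insufficient_data_error")
  }
  dd <- records$r_hr - records$r_br
  paired_p <- if (sd(dd) < 1e-12) NA_real_ else t.test(dd)$p.value
  summary <- tibble::tibble(
    signal = c("hr", "br"),
    mean_r = c(mean(records$r_hr), mean(records$r_br)),
    sd_r = c(sd(records$r_hr), sd(records$r_br)),
    n = nrow(records)
  )
  structure(list(records = records, summary = summary, paired_p = paired_p),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance> HR r = %.4f +/- %.4f; BR r = %.4f +/- %.4f; paired p = %s\n",
              x$summary$mean_r[1], x$summary$sd_r[1],
              x$summary$mean_r[2], x$summary$sd_r[2],
              format.pval(x$paired_p, digits = 3)))
  invisible(x)
}

#' Covariate regression on concordance
#'
#' Ordinary least squares of a per-subject concordance value on sex, age and
#' BMI (sex coded female = 1), with two-sided t-tests per coefficient and the
#' sex group means with standard errors. AHI can be added via `extra`.
#'
#' @param records Data frame with the response column plus `sex` (`"F"`/`"M"`
#'   or 0/1 female indicator), `age`, `bmi` (and optionally `ahi`).
#' @param response Response column name (default `r_hr`).
#' @param extra Optional additional covariate column names.
#' @return Object of class `concordance_regression`: list with `fit` (the
#'   `lm`), `coefficients` (tidy tibble), `sex_means` (mean +/- SE by sex).
#' @export
covariate_regression <- function(records, response = "r_hr", extra = NULL) {
  female <- if (is.numeric(records$sex)) records$sex else
    as.numeric(records$sex == "F")
  df <- tibble::tibble(
    y = records[[response]], sex_female = female,
    age = records$age, bmi = records$bmi
  )
  for (v in extra) df[[v]] <- records[[v]]
  if (nrow(df) <= ncol(df)) {
    abort("More coefficients than subjects.",
          class = "sleepagree_insufficient_data_error")
  }
  X <- as.matrix(cbind(1, df[-1]))
  if (qr(X)$rank < ncol(X)) {
    sds <- apply(X[, -1, drop = FALSE], 2, sd)
    abort(sprintf("Rank-deficient design; check collinear columns (%s).",
                  paste(names(sds)[sds == 0], collapse = ", ")),
          class = "sleepagree_input_error")
  }
  fit <- lm(stats::reformulate(setdiff(names(df), "y"), response = "y"), data = df)
  sm <- summary(fit)$coefficients
  coefficients <- tibble::tibble(
    term = rownames(sm), estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]), statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
  sex_means <- df |>
    dplyr::group_by(sex = ifelse(df$sex_female == 1, "F", "M")) |>
    dplyr::summarise(mean = mean(.data$y),
                     se = sd(.data$y) / sqrt(dplyr::n()), .groups = "drop")
  structure(list(fit = fit, coefficients = coefficients, sex_means = sex_means),
            class = "concordance_regression")
}

#' @method tidy concordance_regression
#' @export
tidy.concordance_regression <- function(x, ...) x$coefficients

#' @export
print.concordance_regression <- function(x, ...) {
  cat("<concordance regression>\n")
  print(x$coefficients)
  invisible(x)
}

#' Sample size for a correlation confidence interval
#'
#' Smallest n (>= 4) such that the back-transformed Fisher-z confidence
#' interval for an expected correlation `r`,
#' `tanh(atanh(r) +/- z / sqrt(n - 3))`, has total width at most
#' `2 * half_width`. For an expected correlation of 0.85 and half-width 0.1
#' at the 95% level this returns 36 participants.
#'
#' @param r Expected correlation, strictly between 0 and 1.
#' @param half_width Target interval half-width (> 0).
#' @param level Confidence level.
#' @param n_max Search cap; if the width is still too wide at `n_max` the cap
#'   is returned with a warning.
#' @return Integer sample size.
#' @export
sample_size_correlation <- function(r, half_width, level = 0.95,
                                    n_max = 1e6) {
  if (r <= 0 || r >= 1) {
    abort("`r` must lie strictly between 0 and 1.",
          class = "sleepagree_input_error")
  }
  if (half_width <= 0 || level <= 0 || level >= 1) {
    abort("`half_width` must be positive and `level` in (0, 1).",
          class = "sleepagree_input_error")
  }
  zc <- qnorm(1 - (1 - level) / 2)
  z <- atanh(r)
  width <- function(n) tanh(z + zc / sqrt(n - 3)) - tanh(z - zc / sqrt(n - 3))
  for (n in 4:n_max) {
    if (width(n) <= 2 * half_width) return(as.integer(n))
  }
  warn("Target width not attainable within `n_max`; returning the cap.")
  as.integer(n_max)
}
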