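as_sleep_logical <- function(x, name) {
  if (is.logical(x)) return(x)
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    bad <- !is.na(x) & !(x %in% c("sleep", "wake"))
    if (any(bad)) {
      abort(sprintf("`%s` must be logical or 'sleep'/'wake' labels.", name),
            class = "sleepagree_input_error")
    }
    return(x == "sleep")
  }
  abort(sprintf("`%s` must be logical or 'sleep'/'wake' labels.", name),
        class = "sleepagree_input_error")
}

#' Confusion counts for sleep/wake prediction
#'
#' Sleep is the positive class: `tp` = sleep predicted sleep, `fn` = sleep
#' predicted wake, `fp` = wake predicted sleep, `tn` = wake predicted wake.
#' Epochs with a missing truth or prediction are excluded.
#'
#' @param truth,pred Aligned binary series: logicals (TRUE = sleep) or
#'   `"sleep"`/`"wake"` labels (see [to_binary()]).
#' @return One-row tibble with `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(truth, pred) {
  t <- as_sleep_logical(truth, "truth")
  p <- as_sleep_logical(pred, "pred")
  if (length(t) != length(p)) {
    abort("`truth` and `pred` must have equal length.",
          class = "sleepagree_input_error")
  }
  ok <- !is.na(t) & !is.na(p)
  t <- t[ok]; p <- p[ok]
  if (!length(t)) {
    abort("No analyzable epochs.", class = "sleepagree_no_epochs_error")
  }
  tibble::tibble(tp = sum(t & p), fn = sum(t & !p),
                 fp = sum(!t & p), tn = sum(!t & !p))
}

#' Sleep/wake agreement metrics from confusion counts
#'
#' Computes the epoch-by-epoch battery: sensitivity (sleep detected),
#' specificity (wake detected), accuracy, balanced accuracy, precision,
#' Cohen's kappa, the prevalence-and-bias-adjusted kappa
#' (PABAK = 2 x accuracy - 1), and signal-detection d-prime
#' `qnorm(hit rate) - qnorm(false-alarm rate)` with rates clamped to
#' `[1/(2n), 1 - 1/(2n)]` (n the relevant class count) so perfect rates stay
#' finite. Rates whose marginal is empty are `NA`; kappa is `NA` when the
#' truth contains a single class.
#'
#' @param counts One-row data frame with `tp`, `fn`, `fp`, `tn` (from
#'   [confusion_counts()]).
#' @return One-row tibble with `sensitivity`, `specificity`, `accuracy`,
#'   `balanced_accuracy`, `precision`, `kappa`, `pabak`, `dprime`, `n`.
#' @export
class_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  n <- tp + fn + fp + tn
  if (n < 1) abort("Empty confusion table.", class = "sleepagree_input_error")
  n_sleep <- tp + fn
  n_wake <- fp + tn
  sens <- if (n_sleep > 0) tp / n_sleep else NA_real_
  spec <- if (n_wake > 0) tn / n_wake else NA_real_
  acc <- (tp + tn) / n
  bacc <- (sens + spec) / 2
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  pe <- (n_sleep * (tp + fp) + n_wake * (fn + tn)) / n^2
  kappa <- if (n_sleep == 0 || n_wake == 0 || pe >= 1) NA_real_
           else (acc - pe) / (1 - pe)
  clamp <- function(r, m) min(max(r, 1 / (2 * m)), 1 - 1 / (2 * m))
  dprime <- if (n_sleep > 0 && n_wake > 0) {
    qnorm(clamp(sens, n_sleep)) - qnorm(clamp(1 - spec, n_wake))
  } else NA_real_
  tibble::tibble(
    sensitivity = sens, specificity = spec, accuracy = acc,
    balanced_accuracy = bacc, precision = prec,
    kappa = kappa, pabak = 2 * acc - 1, dprime = dprime, n = n
  )
}

#' Pooled ROC curve and AUC
#'
#' Threshold sweep over the unique score values (predict sleep when
#' `score >= threshold`), with the area under the curve by the trapezoidal
#' rule. Equal to the Mann-Whitney pair statistic with ties counted half.
#'
#' @param scores Numeric sleep scores pooled across subjects.
#' @param truth Binary truth (logical TRUE = sleep, or `"sleep"`/`"wake"`).
#' @return Object of class `roc_result`: list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
pooled_roc <- function(scores, truth) {
  t <- as_sleep_logical(truth, "truth")
  ok <- !is.na(t) & is.finite(scores)
  t <- t[ok]; s <- scores[ok]
  n_pos <- sum(t); n_neg <- sum(!t)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC requires at least one epoch of each class.",
          class = "sleepagree_input_error")
  }
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; t <- t[ord]
  # collapse tied scores so each threshold appears once
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(t)[last_of_tie] / n_pos
  fpr <- cumsum(!t)[last_of_tie] / n_neg
  points <- tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fpr), tpr = c(0, tpr)
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n = length(s)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<ROC> AUC = %.4f over %d epochs (%d thresholds)\n",
              x$auc, x$n, nrow(x$points) - 1L))
  invisible(x)
}

#' ROC plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Cohort sleep/wake classification summary
#'
#' Per-subject classification metrics, their unweighted cohort mean and SD
#' (undefined values excluded, with counts reported), and the AUC pooled over
#' all epochs (a single study-level curve rather than a per-subject average).
#'
#' @param data Epoch-level data frame (one row per subject-epoch).
#' @param truth,pred,score,subject Column names: binary truth, binary
#'   prediction, continuous sleep score, subject identifier.
#' @return List of class `class_summary`: `per_subject` (tibble of metrics),
#'   `summary` (tibble `metric`, `mean`, `sd`, `n_defined`), `roc`
#'   (`roc_result`), `auc`.
#' @export
cohort_class_summary <- function(data, truth = "truth", pred = "pred",
                                 score = "score", subject = "subject") {
  per_subject <- data |>
    dplyr::group_by(subject_id = .data[[subject]]) |>
    dplyr::group_modify(function(g, key) {
      class_metrics(confusion_counts(g[[truth]], g[[pred]]))
    }) |>
    dplyr::ungroup()
  metrics <- setdiff(names(per_subject), c("subject_id", "n"))
  summary <- purrr::map_dfr(metrics, function(mcol) {
    v <- per_subject[[mcol]]
    tibble::tibble(metric = mcol, mean = mean(v, na.rm = TRUE),
                   sd = sd(v, na.rm = TRUE), n_defined = sum(!is.na(v)))
  })
  roc <- pooled_roc(data[[score]], data[[truth]])
  structure(list(per_subject = per_subject, summary = summary,
                 roc = roc, auc = roc$auc),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("<sleep/wake classification> %d subjects, pooled AUC = %.3f\n",
              nrow(x$per_subject), x$auc))
  print(x$summary)
  invisible(x)
}
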