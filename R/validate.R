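align_subject <- function(g, max_lag = 20) {
  est <- tryCatch(estimate_offset(g$ref_move, g$dev_move, max_lag = max_lag),
                  sleepagree_alignment_error = function(e) NULL)
  lag <- if (is.null(est)) 0L else est$lag
  if (lag != 0L) {
    for (pair in list(c("dev_hr", "hr_covered"), c("dev_br", "br_covered"))) {
      sh <- apply_offset(g[[pair[1]]], -lag, covered = g[[pair[2]]])
      g[[pair[1]]] <- sh$value
      g[[pair[2]]] <- sh$covered
    }
    for (col in c("dev_score", "dev_move")) {
      g[[col]] <- shift_vector(g[[col]], -lag)
    }
    g$dev_pred_sleep <- shift_vector(g$dev_pred_sleep, -lag)
  }
  attr(g, "lag") <- lag
  g
}

#' Run the full validation pipeline on a cohort
#'
#' The end-to-end analysis performed when comparing a contactless device
#' against PSG: per subject, estimate and remove the device clock offset from
#' the movement channels; curate reference/device HR and BR pairs (artifact
#' epochs excluded first, then uncovered epochs); then compute (i)
#' epoch-by-epoch and all-night HR/BR agreement through the gated
#' Bland-Altman decision tree plus Pearson correlations, (ii) epoch-by-epoch
#' sleep/wake classification against the consensus hypnogram, (iii)
#' summary-variable (SOL/WASO/TST/SE) agreement, and (iv) overnight profile
#' concordance. When `out_dir` is given, `agreement.json`,
#' `classification.json`, `summary_agreement.json` and `concordance.json`
#' are written there.
#'
#' @param cohort A `sleep_cohort`.
#' @param max_lag Maximum clock offset scanned, epochs.
#' @param B Bootstrap resamples for modeled coefficient intervals.
#' @param seed Optional integer seed.
#' @param out_dir Optional output directory for JSON reports.
#' @return Object of class `validation_report`: list with `agreement`
#'   (per-channel results for `hr_epoch`, `br_epoch`, `hr_night`, `br_night`
#'   plus correlations and exclusion tallies), `classification`,
#'   `summary_agreement`, `concordance`, and `alignment` (per-subject lags).
#' @export
validate_cohort <- function(cohort, max_lag = 20, B = 1000, seed = NULL,
                            out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aligned <- cohort$epochs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(g, key) {
      g2 <- align_subject(g, max_lag)
      dplyr::mutate(g2, lag = attr(g2, "lag"))
    }) |>
    dplyr::ungroup()
  lags <- dplyr::distinct(aligned, .data$subject_id, .data$lag)

  curate_channel <- function(sig) {
    aligned |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_modify(function(g, key) {
        cp <- curate_pairs(
          tibble::tibble(ref = g[[paste0("ref_", sig)]],
                         dev = g[[paste0("dev_", sig)]],
                         covered = g[[paste0(sig, "_covered")]],
                         artifact = g$psg_artifact))
        dplyr::mutate(cp$pairs, coverage = cp$coverage,
                      total = cp$counts$total,
                      psg_artifact_excluded = cp$counts$psg_artifact_excluded,
                      not_covered = cp$counts$not_covered)
      }) |>
      dplyr::ungroup()
  }

  agreement <- list()
  for (sig in c("hr", "br")) {
    ch <- curate_channel(sig)
    pairs <- dplyr::select(ch, subject = "subject_id", "ref", "dev")
    tallies <- dplyr::distinct(ch, .data$subject_id, .data$total,
                               .data$psg_artifact_excluded, .data$not_covered,
                               .data$coverage)
    nights <- pairs |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(ref = mean(.data$ref), dev = mean(.data$dev),
                       .groups = "drop")
    agreement[[paste0(sig, "_epoch")]] <- list(
      ba = analyze_agreement(pairs, mode = "epoch", B = B),
      correlation = pearson_ci(pairs$ref, pairs$dev),
      coverage = sum(tallies$total - tallies$psg_artifact_excluded -
                       tallies$not_covered) /
        sum(tallies$total - tallies$psg_artifact_excluded),
      tallies = tallies
    )
    agreement[[paste0(sig, "_night")]] <- list(
      ba = analyze_agreement(nights, mode = "summary", B = B),
      correlation = pearson_ci(nights$ref, nights$dev)
    )
  }

  class_data <- aligned |>
    dplyr::mutate(truth = to_binary(consensus(.data$stage_scorer1,
                                              .data$stage_scorer2,
                                              .data$stage_scorer3,
                                              .data$stage_expert)) == "sleep",
                  pred = .data$dev_pred_sleep, score = .data$dev_score) |>
    dplyr::filter(!is.na(.data$pred) & !is.na(.data$score))
  classification <- cohort_class_summary(class_data, subject = "subject_id")

  summary_agreement <- cohort_summary_agreement(
    list(epochs = aligned, subjects = cohort$subjects), B = B)
  concordance <- cohort_concordance(
    list(epochs = aligned, subjects = cohort$subjects), max_lag = max_lag,
    align = FALSE)

  report <- structure(
    list(agreement = agreement, classification = classification,
         summary_agreement = summary_agreement, concordance = concordance,
         alignment = lags),
    class = "validation_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

ba_to_list <- function(x) {
  if (inherits(x, "ba_result")) {
    list(method = x$method, bias = x$bias, loa_lower = x$loa_lower,
         loa_upper = x$loa_upper, sd_total = x$sd_total,
         var_between = x$var_between, var_within = x$var_within,
         ci_bias = x$ci_bias, ci_loa_lower = x$ci_loa_lower,
         ci_loa_upper = x$ci_loa_upper, n = x$n, m = x$m, gates = x$gates)
  } else {
    list(method = "modeled", b0 = x$b0, b1 = x$b1, c0 = x$c0, c1 = x$c1,
         loa_multiplier = x$loa_multiplier, coef_ci = x$coef_ci,
         transform = x$transform, n = x$n, m = x$m, gates = x$gates)
  }
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  wj(lapply(report$agreement, function(ch) {
    out <- list(ba = ba_to_list(ch$ba), correlation = ch$correlation)
    if (!is.null(ch$coverage)) {
      out$coverage <- ch$coverage
      out$tallies <- ch$tallies
    }
    out
  }), "agreement.json")
  wj(list(per_subject = report$classification$per_subject,
          summary = report$classification$summary,
          auc = report$classification$auc,
          roc_points = report$classification$roc$points),
     "classification.json")
  wj(list(per_subject = report$summary_agreement$per_subject,
          table = report$summary_agreement$table,
          results = lapply(report$summary_agreement$results, ba_to_list)),
     "summary_agreement.json")
  wj(list(records = report$concordance$records,
          summary = report$concordance$summary,
          paired_p = report$concordance$paired_p),
     "concordance.json")
  invisible(out_dir)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation report>\n\n-- epoch-by-epoch HR --\n")
  print(x$agreement$hr_epoch$ba)
  cat(sprintf("  coverage %.1f%%, r = %.3f [%.3f, %.3f]\n",
              100 * x$agreement$hr_epoch$coverage,
              x$agreement$hr_epoch$correlation$r,
              x$agreement$hr_epoch$correlation$conf.low,
              x$agreement$hr_epoch$correlation$conf.high))
  cat("\n-- epoch-by-epoch BR --\n")
  print(x$agreement$br_epoch$ba)
  cat("\n-- sleep/wake classification --\n")
  print(x$classification)
  cat("\n-- summary variables --\n")
  print(x$summary_agreement$table)
  cat("\n-- concordance --\n")
  print(x$concordance)
  invisible(x)
}
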