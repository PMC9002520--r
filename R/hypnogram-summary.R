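#' Consensus hypnogram from three scorers and an expert
#'
#' Per epoch, the consensus is the stage chosen by at least two of the three
#' technicians; when all three disagree, the expert's label decides.
#' The result is invariant to the ordering of the scorers.
#'
#' @param scorer1,scorer2,scorer3 Equal-length stage vectors.
#' @param expert Expert stage vector; may be omitted only if no epoch has a
#'   three-way disagreement.
#' @return Factor of consensus stages over W, N1, N2, N3, REM.
#' @export
consensus <- function(scorer1, scorer2, scorer3, expert = NULL) {
  s1 <- as.character(scorer1); s2 <- as.character(scorer2)
  s3 <- as.character(scorer3)
  n <- length(s1)
  if (length(s2) != n || length(s3) != n) {
    abort("Scorer hypnograms must have equal length.",
          class = "sleepagree_input_error")
  }
  out <- ifelse(s1 == s2 | s1 == s3, s1, ifelse(s2 == s3, s2, NA))
  tie <- is.na(out)
  if (any(tie)) {
    if (is.null(expert)) {
      abort("Three-way scorer disagreement requires an expert hypnogram.",
            class = "sleepagree_input_error")
    }
    out[tie] <- as.character(expert)[tie]
  }
  factor(out, levels = STAGES)
}

#' All-night summary variables from a hypnogram
#'
#' Computes, in minutes (epochs x 0.5, no rounding):
#' * SOL - lights-off to the first epoch scored as any stage other than wake;
#' * WASO - wake strictly between sleep onset and sleep offset (the last
#'   non-wake epoch);
#' * TST - total epochs scored as sleep;
#' * terminal wake - wake after sleep offset, reported so that
#'   SOL + WASO + TST + terminal wake equals time in bed exactly;
#' * SE - TST / time in bed, a fraction in `[0, 1]`.
#'
#' An all-wake night yields SOL = time in bed and WASO = TST = SE = 0.
#'
#' @param stages Stage vector over the in-bed period (lights-off to
#'   lights-on), or a logical sleep indicator (TRUE = sleep).
#' @param epoch_minutes Epoch duration in minutes.
#' @return One-row tibble with `sol`, `waso`, `tst`, `terminal_wake`, `se`,
#'   `tib` (all minutes except `se`).
#' @export
summary_vars <- function(stages, epoch_minutes = 0.5) {
  if (!length(stages)) {
    abort("Empty hypnogram.", class = "sleepagree_input_error")
  }
  asleep <- if (is.logical(stages)) stages else to_binary(stages) == "sleep"
  if (any(is.na(asleep))) {
    abort("Hypnogram contains missing stages.", class = "sleepagree_input_error")
  }
  n <- length(asleep)
  tib <- n * epoch_minutes
  if (!any(asleep)) {
    return(tibble::tibble(sol = tib, waso = 0, tst = 0, terminal_wake = 0,
                          se = 0, tib = tib))
  }
  onset <- which(asleep)[1]
  offset <- which(asleep)[length(which(asleep))]
  sol <- (onset - 1) * epoch_minutes
  waso <- sum(!asleep[onset:offset]) * epoch_minutes
  tst <- sum(asleep) * epoch_minutes
  terminal <- (n - offset) * epoch_minutes
  tibble::tibble(sol = sol, waso = waso, tst = tst, terminal_wake = terminal,
                 se = tst / tib, tib = tib)
}

cohort_summaries <- function(cohort) {
  cohort$epochs |>
    dplyr::group_by(subject_id = .data$subject_id) |>
    dplyr::group_modify(function(g, key) {
      ref_stage <- consensus(g$stage_scorer1, g$stage_scorer2, g$stage_scorer3,
                             g$stage_expert)
      ref <- summary_vars(ref_stage)
      # lights-off/on taken from the reference grid; unscored (clock-shifted)
      # device epochs count as wake
      dev <- summary_vars(!is.na(g$dev_pred_sleep) & g$dev_pred_sleep)
      dplyr::bind_rows(
        dplyr::mutate(ref, source = "ref"),
        dplyr::mutate(dev, source = "dev")
      )
    }) |>
    dplyr::ungroup()
}

#' Cohort-level agreement of all-night summary variables
#'
#' For each subject, computes SOL, WASO, TST and SE from the consensus
#' reference hypnogram and from the device's predicted sleep/wake series
#' (using the reference lights-off/lights-on boundaries), then runs the full
#' agreement decision tree ([analyze_agreement()], summary mode) per variable.
#'
#' @param cohort A `sleep_cohort` (or any list with an `epochs` tibble in the
#'   cohort dialect).
#' @param variables Summary variables to analyze.
#' @param B Bootstrap resamples for modeled coefficient intervals.
#' @param seed Optional integer seed.
#' @return Object of class `summary_agreement`: list with `per_subject`
#'   (tibble of per-subject reference and device summaries), `results` (named
#'   list of `ba_result`/`modeled_ba` objects) and `table` (one row per
#'   variable: per-method mean (SD), bias or bias coefficients, limits or
#'   limit coefficients).
#' @export
cohort_summary_agreement <- function(cohort,
                                     variables = c("sol", "waso", "tst", "se"),
                                     B = 1000, seed = NULL) {
  sums <- cohort_summaries(cohort)
  if (dplyr::n_distinct(sums$subject_id) < 3) {
    abort("At least 3 subjects are required.",
          class = "sleepagree_insufficient_data_error")
  }
  if (!is.null(seed)) set.seed(seed)
  results <- list()
  rows <- list()
  for (v in variables) {
    wide <- sums |>
      dplyr::select("subject_id", "source", value = dplyr::all_of(v)) |>
      tidyr::pivot_wider(names_from = "source", values_from = "value")
    pairs <- tibble::tibble(subject = wide$subject_id, ref = wide$ref,
                            dev = wide$dev)
    res <- analyze_agreement(pairs, mode = "summary", B = B)
    results[[v]] <- res
    rows[[v]] <- tibble::tibble(
      variable = v,
      ref_mean = mean(wide$ref), ref_sd = sd(wide$ref),
      dev_mean = mean(wide$dev), dev_sd = sd(wide$dev),
      bias = if (inherits(res, "ba_result")) res$bias else NA_real_,
      b0 = if (inherits(res, "modeled_ba")) res$b0 else NA_real_,
      b1 = if (inherits(res, "modeled_ba")) res$b1 else NA_real_,
      loa_lower = if (inherits(res, "ba_result")) res$loa_lower else NA_real_,
      loa_upper = if (inherits(res, "ba_result")) res$loa_upper else NA_real_,
      c0 = if (inherits(res, "modeled_ba")) res$c0 else NA_real_,
      c1 = if (inherits(res, "modeled_ba")) res$c1 else NA_real_,
      modeled = inherits(res, "modeled_ba")
    )
  }
  structure(list(per_subject = sums, results = results,
                 table = dplyr::bind_rows(rows)),
            class = "summary_agreement")
}

#' @export
print.summary_agreement <- function(x, ...) {
  cat("<summary-variable agreement>\n")
  print(x$table)
  invisible(x)
}
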