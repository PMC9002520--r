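#' Aggregate instantaneous values to the epoch grid
#'
#' Means of instantaneous values within half-open 30 s windows
#' `[t, t + 30)` anchored at lights-off (`t0`). A value timed exactly at an
#' epoch boundary belongs to the following epoch. Epochs containing no values
#' are masked as uncovered.
#'
#' @param data Data frame with a timestamp column and a value column.
#' @param time,value Column names (tidyselect) of timestamps (seconds) and
#'   values; defaults `time_s` and `value`.
#' @param n_epochs Number of epochs on the grid.
#' @param epoch_seconds Epoch duration, seconds.
#' @param t0 Grid anchor (lights-off time), seconds.
#' @return Tibble with `epoch` (0-based), `value`, `covered`.
#' @export
aggregate_epochs <- function(data, time = "time_s", value = "value",
                             n_epochs, epoch_seconds = 30, t0 = 0) {
  ts <- data[[time]]
  v <- data[[value]]
  if (any(!is.finite(ts))) {
    abort("Timestamps must be finite.", class = "sleepagree_input_error")
  }
  idx <- floor((ts - t0) / epoch_seconds)
  keep <- idx >= 0 & idx < n_epochs
  lev <- factor(idx[keep], levels = 0:(n_epochs - 1))
  sums <- as.numeric(tapply(v[keep], lev, sum))
  counts <- as.numeric(tapply(rep(1, sum(keep)), lev, sum))
  counts[is.na(counts)] <- 0
  tibble::tibble(
    epoch = 0:(n_epochs - 1),
    value = ifelse(counts > 0, sums / counts, NA_real_),
    covered = counts > 0
  )
}

#' Curate reference/device epoch pairs
#'
#' Applies the exclusion cascade used for epoch-by-epoch HR/BR agreement:
#' epochs with reference (PSG) artifacts are excluded first; among the
#' remainder, epochs without a device reading are counted as not covered and
#' excluded. Coverage is the device-covered fraction of artifact-free epochs.
#'
#' @param data Data frame with one row per epoch on the common grid
#'   (post-alignment).
#' @param ref,dev Column names of the reference and device values.
#' @param covered Column name of the device coverage mask.
#' @param artifact Column name of the reference artifact mask.
#' @return Object of class `paired_epochs`: list with `pairs` (tibble of
#'   analyzed `ref`, `dev`), `counts` (one-row tibble: `total`,
#'   `psg_artifact_excluded`, `not_covered`, `analyzed`) and `coverage`.
#' @export
curate_pairs <- function(data, ref = "ref", dev = "dev",
                         covered = "covered", artifact = "artifact") {
  r <- data[[ref]]; d <- data[[dev]]
  cov <- if (covered %in% names(data)) data[[covered]] else !is.na(d)
  art <- if (artifact %in% names(data)) data[[artifact]] else rep(FALSE, length(r))
  art <- art | is.na(r)
  total <- length(r)
  n_art <- sum(art)
  remaining <- total - n_art
  not_cov <- sum(!cov[!art] | is.na(d[!art]))
  analyzed <- remaining - not_cov
  if (analyzed == 0) {
    abort("No analyzable epochs after exclusions.",
          class = "sleepagree_no_epochs_error")
  }
  keep <- !art & cov & !is.na(d)
  structure(
    list(
      pairs = tibble::tibble(epoch = which(keep) - 1L, ref = r[keep], dev = d[keep]),
      counts = tibble::tibble(total = total, psg_artifact_excluded = n_art,
                              not_covered = not_cov, analyzed = analyzed),
      coverage = if (remaining > 0) analyzed / remaining else NA_real_
    ),
    class = "paired_epochs"
  )
}

#' @export
print.paired_epochs <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "<paired_epochs> %d analyzed of %d (artifact %d, not covered %d); coverage %.1f%%\n",
    analyzed, total, psg_artifact_excluded, not_covered, 100 * x$coverage)))
  invisible(x)
}

#' Collapse stages to binary sleep/wake
#'
#' W maps to wake; N1, N2, N3 and REM map to sleep.
#'
#' @param stages Character or factor vector of stage labels.
#' @return Factor with levels `wake`, `sleep`.
#' @export
to_binary <- function(stages) {
  s <- as.character(stages)
  bad <- !is.na(s) & !(s %in% STAGES)
  if (any(bad)) {
    abort(sprintf("Unknown stage labels: %s.",
                  paste(unique(s[bad]), collapse = ", ")),
          class = "sleepagree_input_error")
  }
  factor(ifelse(s == "W", "wake", "sleep"), levels = c("wake", "sleep"))
}

#' Stage-stratified summaries of an epoch series
#'
#' Mean, SD and count of an epoch-level signal grouped by sleep stage.
#' Stages with no analyzed epochs are absent from the output.
#'
#' @param data Data frame with one row per epoch.
#' @param stage,value Column names of the stage labels and the signal.
#' @param covered Optional column name of a coverage mask; uncovered epochs
#'   are dropped.
#' @return Tibble with `stage`, `mean`, `sd`, `n`.
#' @export
stage_stratified_stats <- function(data, stage = "stage", value = "value",
                                   covered = NULL) {
  s <- as.character(data[[stage]])
  v <- data[[value]]
  keep <- !is.na(v) & !is.na(s)
  if (!is.null(covered)) keep <- keep & data[[covered]]
  tibble::tibble(stage = factor(s[keep], levels = STAGES), value = v[keep]) |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$stage)
}
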