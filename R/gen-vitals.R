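#' Generate reference vitals for one night
#'
#' Simulates instantaneous heart-rate and breathing-rate series driven by the
#' hypnogram (stage baseline + zero-mean linear overnight trend + AR(1)
#' fluctuation, floored at 1), then aggregates them to 30 s epoch means. This
#' stands in for the PSG-derived reference rates: the epoch values are exactly
#' the within-epoch means of the instantaneous series, mirroring how a
#' reference is built from beat/breath detections.
#'
#' @param hypnogram Tibble from [gen_hypnogram()].
#' @param config A [vitals_config()].
#' @param seed Optional integer seed.
#' @return List with `instant` (tibble: `time_s`, `hr`, `br`) and `epochs`
#'   (tibble: `epoch`, `ref_hr`, `ref_br`).
#' @export
gen_reference_vitals <- function(hypnogram, config = vitals_config(), seed = NULL) {
  stopifnot(inherits(config, "vitals_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(hypnogram)
  m <- config$sampling_rate
  total <- n * m
  stage_idx <- rep(match(as.character(hypnogram$stage), STAGES), each = m)
  # position in (0, 1) across the night; trend declines linearly from +amp to -amp
  frac <- (seq_len(total) - 0.5) / total
  trend <- 1 - 2 * frac

  one_signal <- function(baseline, amp, innov_sd) {
    base <- baseline[stage_idx] + amp * trend
    noise <- if (innov_sd > 0) {
      as.numeric(stats::filter(rnorm(total, 0, innov_sd), config$ar_coef,
                               method = "recursive"))
    } else {
      numeric(total)
    }
    pmax(base + noise, 1)
  }

  hr <- one_signal(config$hr_baseline, config$hr_trend_amp, config$hr_innov_sd)
  br <- one_signal(config$br_baseline, config$br_trend_amp, config$br_innov_sd)
  step <- 30 / m
  instant <- tibble::tibble(time_s = (seq_len(total) - 1) * step, hr = hr, br = br)
  epochs <- tibble::tibble(
    epoch = hypnogram$epoch,
    ref_hr = colMeans(matrix(hr, nrow = m)),
    ref_br = colMeans(matrix(br, nrow = m))
  )
  list(instant = instant, epochs = epochs)
}

clock_shift_epochs <- function(config, n_epochs) {
  hours_mid <- n_epochs * 30 / 3600 / 2
  as.integer(round((config$clock_offset + config$clock_drift * hours_mid) / 30))
}

shift_vector <- function(x, lag, fill = NA) {
  n <- length(x)
  if (lag == 0L) return(x)
  if (abs(lag) >= n) return(rep(fill, n))
  if (lag > 0) c(rep(fill, lag), x[seq_len(n - lag)])
  else c(x[(1 - lag):n], rep(fill, -lag))
}

#' Generate the device observation of one night
#'
#' Applies the device error model to the reference epoch series: constant and
#' proportional bias, heteroscedastic Gaussian noise, per-epoch coverage
#' dropout, and a whole-night clock shift (offset plus drift accumulated to
#' mid-night, rounded to whole epochs; positive shift delays the device
#' stream). Also emits the device sleep score (logit-perturbed state
#' probability), the thresholded sleep/wake prediction, and movement channels
#' for both systems with bursts at wake-bout onsets, which downstream
#' alignment uses to recover the clock shift.
#'
#' @param ref_epochs Tibble with `epoch`, `ref_hr`, `ref_br` (from
#'   [gen_reference_vitals()]).
#' @param hypnogram Tibble from [gen_hypnogram()].
#' @param config A [device_config()].
#' @param seed Optional integer seed.
#' @return Tibble with columns `epoch`, `dev_hr`, `hr_covered`, `dev_br`,
#'   `br_covered`, `dev_score`, `dev_pred_sleep`, `ref_move`, `dev_move`, and
#'   attribute `shift_epochs` (the applied clock shift).
#' @export
gen_device_observation <- function(ref_epochs, hypnogram,
                                   config = device_config(), seed = NULL) {
  stopifnot(inherits(config, "device_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ref_epochs)
  stages <- as.character(hypnogram$stage)

  observe <- function(ref, bias, prop, sd0, sd_slope, coverage) {
    noise_sd <- sd0 + sd_slope * ref
    if (any(noise_sd < 0)) {
      abort("Device noise SD is negative at some reference values.",
            class = "sleepagree_config_error")
    }
    value <- ref - bias - prop * ref + rnorm(n, 0, noise_sd)
    covered <- runif(n) < coverage
    value[!covered] <- NA_real_
    list(value = value, covered = covered)
  }

  hr <- observe(ref_epochs$ref_hr, config$hr_bias, config$hr_prop_bias,
                config$hr_noise_sd, config$hr_noise_slope, config$hr_coverage)
  br <- observe(ref_epochs$ref_br, config$br_bias, config$br_prop_bias,
                config$br_noise_sd, config$br_noise_slope, config$br_coverage)

  p_state <- ifelse(stages == "W", config$p_wake, config$p_sleep)
  score <- plogis(qlogis(p_state) + rnorm(n, 0, config$score_noise_sd))

  # movement bursts at wake-bout onsets (and lights-off), visible to both systems
  is_w <- stages == "W"
  onset <- is_w & !c(FALSE, is_w[-n])
  burst <- ifelse(onset, 5, 0) + ifelse(is_w, 0.5, 0)
  ref_move <- burst + abs(rnorm(n, 0, 0.1))

  shift <- clock_shift_epochs(config, n)
  dev <- tibble::tibble(
    epoch = ref_epochs$epoch,
    dev_hr = shift_vector(hr$value, shift),
    hr_covered = shift_vector(hr$covered, shift, fill = FALSE),
    dev_br = shift_vector(br$value, shift),
    br_covered = shift_vector(br$covered, shift, fill = FALSE),
    dev_score = shift_vector(score, shift),
    dev_pred_sleep = shift_vector(score >= config$score_threshold, shift),
    ref_move = ref_move,
    dev_move = shift_vector(burst, shift, fill = 0) + abs(rnorm(n, 0, 0.1))
  )
  attr(dev, "shift_epochs") <- shift
  dev
}
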