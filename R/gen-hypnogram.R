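lognormal_params <- function(mean, sd) {
  # moment-matched meanlog/sdlog
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic hypnogram
#'
#' Simulates one night of 30 s sleep-stage epochs from lights-off to
#' lights-on. The night starts with a wake run whose duration (the sleep onset
#' latency) is drawn from the configured lognormal distribution; the remainder
#' follows a first-order Markov chain over the five AASM stages, started from
#' `initial_stage`. Epoch indices are 0-based and anchored at lights-off.
#'
#' @param config A [hypnogram_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with columns `epoch` (0-based) and `stage` (factor over
#'   W, N1, N2, N3, REM).
#' @examples
#' hyp <- gen_hypnogram(hypnogram_config(time_in_bed = 960), seed = 1)
#' summary_vars(hyp$stage)
#' @export
gen_hypnogram <- function(config = hypnogram_config(), seed = NULL) {
  stopifnot(inherits(config, "hypnogram_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$time_in_bed
  lp <- lognormal_params(config$sol_mean, config$sol_sd)
  sol_epochs <- min(round(2 * rlnorm(1, lp$meanlog, lp$sdlog)), n)
  stages <- rep("W", n)
  if (sol_epochs < n) {
    cum <- t(apply(config$transition, 1, cumsum))
    state <- STAGES[findInterval(runif(1), cumsum(config$initial_stage)) + 1L]
    u <- runif(n - sol_epochs)
    for (i in seq_len(n - sol_epochs)) {
      stages[sol_epochs + i] <- state
      state <- STAGES[findInterval(u[i], cum[state, ]) + 1L]
    }
  }
  tibble::tibble(epoch = 0:(n - 1L), stage = factor(stages, levels = STAGES))
}

#' Generate a three-technician scorer panel
#'
#' Each technician reproduces the true stage with probability
#' `1 - error_rate`; otherwise a uniformly chosen different stage is recorded.
#' The expert scorer always equals the truth and is used downstream to break
#' three-way disagreements in [consensus()].
#'
#' @param hypnogram Tibble from [gen_hypnogram()] (columns `epoch`, `stage`).
#' @param error_rate Per-epoch mislabel probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Tibble with columns `epoch`, `truth`, `scorer1`, `scorer2`,
#'   `scorer3`, `expert` (all stage factors).
#' @export
gen_scorer_panel <- function(hypnogram, error_rate = 0.15, seed = NULL) {
  if (error_rate < 0 || error_rate >= 1) {
    abort("`error_rate` must lie in [0, 1).", class = "sleepagree_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  truth <- as.character(hypnogram$stage)
  n <- length(truth)
  score_once <- function() {
    err <- runif(n) < error_rate
    out <- truth
    if (any(err)) {
      # uniform over the four non-true stages
      offset <- sample.int(4L, sum(err), replace = TRUE)
      idx_true <- match(truth[err], STAGES)
      out[err] <- STAGES[((idx_true - 1L + offset) %% 5L) + 1L]
    }
    factor(out, levels = STAGES)
  }
  tibble::tibble(
    epoch = hypnogram$epoch,
    truth = factor(truth, levels = STAGES),
    scorer1 = score_once(),
    scorer2 = score_once(),
    scorer3 = score_once(),
    expert = factor(truth, levels = STAGES)
  )
}
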