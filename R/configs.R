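#' Default sleep-stage stationary distribution
#'
#' Stationary probabilities of the default per-epoch stage transition chain.
#' Wake occupancy matches a cohort whose post-onset wake accounts for roughly
#' 54 min of a 7.5 h night; sleep is split across N1/N2/N3/REM in proportions
#' typical of healthy adults (about 5/50/20/25% of sleep).
#'
#' @return Named numeric vector over stages W, N1, N2, N3, REM summing to 1.
#' @export
default_stage_occupancy <- function() {
  c(W = 0.1232, N1 = 0.0440, N2 = 0.4380, N3 = 0.1750, REM = 0.2198)
}

#' Default stage transition matrix
#'
#' Row-stochastic 5x5 per-epoch (30 s) transition matrix built from a target
#' stationary distribution by detailed balance: from any stage the chain moves
#' to stage j with probability `switch_rate * pi_j` (j different from the
#' current stage) and otherwise stays. Mean bout length in stage i is
#' `1 / (switch_rate * (1 - pi_i))` epochs, about 2 min for wake at defaults.
#'
#' @param occupancy Named stationary distribution over W, N1, N2, N3, REM.
#' @param switch_rate Per-epoch rate scale in (0, 1]; larger values mean more
#'   fragmented bouts.
#' @return 5x5 row-stochastic matrix with dimnames over the stages.
#' @export
default_transition_matrix <- function(occupancy = default_stage_occupancy(),
                                      switch_rate = 0.28) {
  stopifnot(length(occupancy) == 5L, abs(sum(occupancy) - 1) < 1e-6)
  p <- switch_rate * matrix(occupancy, 5, 5, byrow = TRUE,
                            dimnames = list(STAGES, STAGES))
  diag(p) <- 0
  diag(p) <- 1 - rowSums(p)
  p
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1].", name),
          class = "sleepagree_config_error")
  }
}

#' Hypnogram generator configuration
#'
#' Parameters of the synthetic hypnogram process: a wake run whose length is
#' drawn from a lognormal sleep-onset-latency distribution, followed by a
#' first-order Markov chain over the five AASM stages at 30 s resolution.
#'
#' @param time_in_bed Number of 30 s epochs from lights-off to lights-on.
#' @param transition 5x5 row-stochastic stage transition matrix (rows and
#'   columns ordered W, N1, N2, N3, REM).
#' @param initial_stage Distribution of the first post-onset stage.
#' @param sol_mean,sol_sd Mean and SD, in minutes, of the lognormal
#'   sleep-onset-latency distribution.
#' @return A list of class `hypnogram_config`.
#' @export
hypnogram_config <- function(time_in_bed = 920L,
                             transition = default_transition_matrix(),
                             initial_stage = c(W = 0, N1 = 1, N2 = 0, N3 = 0, REM = 0),
                             sol_mean = 16.4,
                             sol_sd = 13.6) {
  time_in_bed <- as.integer(time_in_bed)
  if (is.na(time_in_bed) || time_in_bed < 1L) {
    abort("`time_in_bed` must be at least 1 epoch.",
          class = "sleepagree_config_error")
  }
  transition <- as.matrix(transition)
  if (!identical(dim(transition), c(5L, 5L))) {
    abort("`transition` must be a 5x5 matrix over stages W, N1, N2, N3, REM.",
          class = "sleepagree_config_error")
  }
  check_prob(transition, "transition")
  if (any(abs(rowSums(transition) - 1) > 1e-12)) {
    abort("`transition` rows must each sum to 1 (tolerance 1e-12).",
          class = "sleepagree_config_error")
  }
  dimnames(transition) <- list(STAGES, STAGES)
  check_prob(initial_stage, "initial_stage")
  if (length(initial_stage) != 5L || abs(sum(initial_stage) - 1) > 1e-8) {
    abort("`initial_stage` must be a 5-element distribution over the stages.",
          class = "sleepagree_config_error")
  }
  if (sol_mean <= 0 || sol_sd <= 0) {
    abort("`sol_mean` and `sol_sd` must be positive minutes.",
          class = "sleepagree_config_error")
  }
  structure(
    list(time_in_bed = time_in_bed, transition = transition,
         initial_stage = setNames(as.numeric(initial_stage), STAGES),
         sol_mean = sol_mean, sol_sd = sol_sd),
    class = "hypnogram_config"
  )
}

#' Vitals generator configuration
#'
#' Stage-dependent instantaneous heart-rate and breathing-rate model: for each
#' signal, value = stage baseline + linear overnight trend (zero-mean, from
#' `+amp` at lights-off to `-amp` at lights-on) + AR(1) fluctuation, sampled
#' `sampling_rate` times per 30 s epoch and floored at 1. Baselines are
#' weighted by the default stage occupancy to give overnight means of about
#' 66.4 bpm (HR) and 14.9 breaths/min (BR).
#'
#' @param hr_baseline,br_baseline Named per-stage baselines (bpm, breaths/min).
#' @param hr_trend_amp,br_trend_amp Overnight linear trend amplitude.
#' @param ar_coef AR(1) coefficient of the instantaneous fluctuation, in (-1, 1).
#' @param hr_innov_sd,br_innov_sd AR(1) innovation SDs.
#' @param sampling_rate Instantaneous samples per 30 s epoch (>= 1).
#' @return A list of class `vitals_config`.
#' @export
vitals_config <- function(hr_baseline = c(W = 70, N1 = 68, N2 = 65.7, N3 = 63.5, REM = 67.5),
                          br_baseline = c(W = 15.5, N1 = 15.0, N2 = 14.8, N3 = 14.6, REM = 15.0),
                          hr_trend_amp = 1.5,
                          br_trend_amp = 0.3,
                          ar_coef = 0.95,
                          hr_innov_sd = 0.65,
                          br_innov_sd = 0.25,
                          sampling_rate = 60L) {
  for (b in list(hr_baseline = hr_baseline, br_baseline = br_baseline)) {
    if (length(b) != 5L || any(!is.finite(b)) || any(b <= 0)) {
      abort("Stage baselines must be 5 strictly positive values.",
            class = "sleepagree_config_error")
    }
  }
  if (abs(ar_coef) >= 1) {
    abort("`ar_coef` must lie in (-1, 1).", class = "sleepagree_config_error")
  }
  if (hr_innov_sd < 0 || br_innov_sd < 0) {
    abort("Innovation SDs must be non-negative.", class = "sleepagree_config_error")
  }
  sampling_rate <- as.integer(sampling_rate)
  if (is.na(sampling_rate) || sampling_rate < 1L) {
    abort("`sampling_rate` must be at least 1 sample per epoch.",
          class = "sleepagree_config_error")
  }
  structure(
    list(hr_baseline = setNames(as.numeric(hr_baseline), STAGES),
         br_baseline = setNames(as.numeric(br_baseline), STAGES),
         hr_trend_amp = hr_trend_amp, br_trend_amp = br_trend_amp,
         ar_coef = ar_coef, hr_innov_sd = hr_innov_sd, br_innov_sd = br_innov_sd,
         sampling_rate = sampling_rate),
    class = "vitals_config"
  )
}

#' Device error-model configuration
#'
#' Observation model for the contactless device. On covered epochs,
#' `device = reference - constant_bias - proportional_bias * reference + e`
#' with `e ~ N(0, (noise_sd_intercept + noise_sd_slope * reference)^2)`, so the
#' difference `reference - device` has mean `constant_bias` at zero
#' proportional bias (a positive constant bias means the device underestimates
#' the reference). The device clock is shifted by `clock_offset` seconds plus
#' `clock_drift` seconds/hour accumulated to mid-night, rounded to whole
#' epochs. The sleep score perturbs the state log-odds (`p_sleep` for sleep
#' epochs, `p_wake` for wake epochs) with Gaussian noise of SD
#' `score_noise_sd`; epochs scoring at or above `score_threshold` are
#' predicted asleep.
#'
#' @param hr_bias,br_bias Constant biases (reference - device), bpm.
#' @param hr_prop_bias,br_prop_bias Proportional bias slopes.
#' @param hr_noise_sd,br_noise_sd Noise SD intercepts.
#' @param hr_noise_slope,br_noise_slope Noise SD slopes on the reference value
#'   (heteroscedasticity).
#' @param hr_coverage,br_coverage Per-epoch probability the device emits a
#'   reading.
#' @param clock_offset Device clock offset, seconds.
#' @param clock_drift Device clock drift, seconds per hour.
#' @param p_sleep,p_wake State probabilities underlying the sleep score.
#' @param score_noise_sd SD of the logit perturbation of the sleep score.
#' @param score_threshold Cut-point in (0, 1) mapping score to predicted sleep.
#' @return A list of class `device_config`.
#' @export
device_config <- function(hr_bias = -0.23, br_bias = 0.08,
                          hr_prop_bias = 0, br_prop_bias = 0,
                          hr_noise_sd = 3.2, br_noise_sd = 1.05,
                          hr_noise_slope = 0, br_noise_slope = 0,
                          hr_coverage = 0.936, br_coverage = 0.994,
                          clock_offset = 60, clock_drift = 0,
                          p_sleep = 0.90, p_wake = 0.52,
                          score_noise_sd = 1.4, score_threshold = 0.5) {
  check_prob(c(hr_coverage, br_coverage), "coverage")
  check_prob(c(p_sleep, p_wake), "state probabilities")
  if (hr_noise_sd < 0 || br_noise_sd < 0 || score_noise_sd < 0) {
    abort("Noise SDs must be non-negative.", class = "sleepagree_config_error")
  }
  if (score_threshold <= 0 || score_threshold >= 1) {
    abort("`score_threshold` must lie strictly in (0, 1).",
          class = "sleepagree_config_error")
  }
  structure(
    list(hr_bias = hr_bias, br_bias = br_bias,
         hr_prop_bias = hr_prop_bias, br_prop_bias = br_prop_bias,
         hr_noise_sd = hr_noise_sd, br_noise_sd = br_noise_sd,
         hr_noise_slope = hr_noise_slope, br_noise_slope = br_noise_slope,
         hr_coverage = hr_coverage, br_coverage = br_coverage,
         clock_offset = clock_offset, clock_drift = clock_drift,
         p_sleep = p_sleep, p_wake = p_wake,
         score_noise_sd = score_noise_sd, score_threshold = score_threshold),
    class = "device_config"
  )
}

#' Cohort generator configuration
#'
#' Study-level configuration: number of subject-nights, master seed, covariate
#' distributions (age, sex, BMI, AHI), between-subject variation of vitals and
#' of device bias, and the coupling of device HR noise to BMI and sex (higher
#' BMI and female sex increase the device's HR noise SD, lowering overnight
#' concordance). Time in bed is drawn per subject as round(N(tib_mean, tib_sd))
#' epochs truncated to `tib_range`.
#'
#' @param n_subjects Number of subject-nights (>= 1).
#' @param seed Master seed; subject i uses `seed + i`.
#' @param hypnogram,vitals,device Component configurations.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated normal.
#' @param prop_female Proportion of female subjects.
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2).
#' @param ahi_mean,ahi_sd AHI distribution (events/h), lognormal by moments.
#' @param tib_mean,tib_sd,tib_range Time-in-bed distribution, epochs.
#' @param hr_subject_sd,br_subject_sd Between-subject SD of the vitals
#'   baselines (bpm, breaths/min).
#' @param hr_bias_subject_sd,br_bias_subject_sd Between-subject SD of the
#'   device constant bias.
#' @param bmi_noise_coupling Added device HR noise SD per kg/m^2 of BMI above
#'   the cohort mean.
#' @param female_noise_coupling Added device HR noise SD for female subjects.
#' @param scorer_error_rate Per-epoch probability a technician mislabels the
#'   stage.
#' @param artifact_prob Per-epoch probability of a PSG artifact.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 45L,
                          seed = 20160221L,
                          hypnogram = hypnogram_config(),
                          vitals = vitals_config(),
                          device = device_config(),
                          age_mean = 41.2, age_sd = 10.5, age_range = c(22, 64),
                          prop_female = 0.556,
                          bmi_mean = 25.9, bmi_sd = 4.4,
                          ahi_mean = 6.53, ahi_sd = 15.1,
                          tib_mean = 924, tib_sd = 60, tib_range = c(686L, 1036L),
                          hr_subject_sd = 8, br_subject_sd = 1.8,
                          hr_bias_subject_sd = 1.5, br_bias_subject_sd = 0.35,
                          bmi_noise_coupling = 0.15,
                          female_noise_coupling = 0.8,
                          scorer_error_rate = 0.15,
                          artifact_prob = 0.02) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) {
    abort("`n_subjects` must be at least 1.", class = "sleepagree_config_error")
  }
  check_prob(c(prop_female, scorer_error_rate, artifact_prob), "proportions")
  stopifnot(inherits(hypnogram, "hypnogram_config"),
            inherits(vitals, "vitals_config"),
            inherits(device, "device_config"))
  structure(
    list(n_subjects = n_subjects, seed = as.integer(seed),
         hypnogram = hypnogram, vitals = vitals, device = device,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         prop_female = prop_female, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         ahi_mean = ahi_mean, ahi_sd = ahi_sd,
         tib_mean = tib_mean, tib_sd = tib_sd,
         tib_range = as.integer(tib_range),
         hr_subject_sd = hr_subject_sd, br_subject_sd = br_subject_sd,
         hr_bias_subject_sd = hr_bias_subject_sd,
         br_bias_subject_sd = br_bias_subject_sd,
         bmi_noise_coupling = bmi_noise_coupling,
         female_noise_coupling = female_noise_coupling,
         scorer_error_rate = scorer_error_rate,
         artifact_prob = artifact_prob),
    class = "cohort_config"
  )
}
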