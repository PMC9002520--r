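test_that("config validation rejects malformed inputs", {
  bad <- default_transition_matrix()
  bad[1, 1] <- bad[1, 1] + 1e-6
  expect_error(hypnogram_config(transition = bad), class = "sleepagree_config_error")
  expect_error(hypnogram_config(time_in_bed = 0), class = "sleepagree_config_error")
  expect_error(vitals_config(hr_baseline = c(W = -1, N1 = 1, N2 = 1, N3 = 1, REM = 1)),
               class = "sleepagree_config_error")
  expect_error(vitals_config(ar_coef = 1), class = "sleepagree_config_error")
  expect_error(device_config(hr_coverage = 1.2), class = "sleepagree_config_error")
  expect_error(device_config(score_threshold = 0), class = "sleepagree_config_error")
  expect_error(cohort_config(n_subjects = 0), class = "sleepagree_config_error")
})

test_that("an absorbing wake chain yields an all-wake night with zero TST", {
  cfg <- hypnogram_config(time_in_bed = 200, transition = absorbing_matrix("W"),
                          initial_stage = stage_distribution("W"))
  hyp <- gen_hypnogram(cfg, seed = 5)
  expect_true(all(hyp$stage == "W"))
  sv <- summary_vars(hyp$stage)
  expect_equal(sv$tst, 0)
  expect_equal(sv$sol, sv$tib)
})

test_that("a symmetric two-state chain approaches its analytic sleep fraction", {
  # stationary sleep fraction of the q/q two-state chain is exactly 1/2;
  # Markov-chain CLT variance p(1-p)(1+rho)/(1-rho)/n with rho = 1 - 2q
  q <- 0.1
  n <- 20000
  cfg <- hypnogram_config(time_in_bed = n, transition = two_state_matrix(q),
                          initial_stage = stage_distribution("N2"),
                          sol_mean = 0.5, sol_sd = 0.1)
  hyp <- gen_hypnogram(cfg, seed = 42)
  post <- hyp$stage[-seq_len(which(hyp$stage != "W")[1] - 1)]
  frac <- mean(post != "W")
  rho <- 1 - 2 * q
  mc_se <- sqrt(0.25 * (1 + rho) / (1 - rho) / length(post))
  expect_lt(abs(frac - 0.5), 3 * mc_se)
})

test_that("hypnogram generation is reproducible and grid-conserving", {
  cfg <- hypnogram_config(time_in_bed = 500)
  expect_identical(gen_hypnogram(cfg, seed = 3), gen_hypnogram(cfg, seed = 3))
  hyp <- gen_hypnogram(cfg, seed = 3)
  expect_equal(nrow(hyp), 500)
  expect_equal(hyp$epoch, 0:499)
  expect_identical(as.character(hyp$stage[1]), "W")
})

test_that("scorer panel error rates match the binomial expectation", {
  hyp <- gen_hypnogram(hypnogram_config(time_in_bed = 10000), seed = 8)
  exact <- gen_scorer_panel(hyp, error_rate = 0, seed = 1)
  expect_identical(exact$scorer1, exact$truth)
  expect_identical(exact$scorer3, exact$truth)

  e <- 0.1
  panel <- gen_scorer_panel(hyp, error_rate = e, seed = 2)
  se <- sqrt(e * (1 - e) / nrow(panel))
  for (col in c("scorer1", "scorer2", "scorer3")) {
    expect_lt(abs(mean(panel[[col]] != panel$truth) - e), 3 * se)
  }
  expect_identical(panel$expert, panel$truth)
})

test_that("noise-free single-stage vitals equal the stage baseline exactly", {
  cfg <- hypnogram_config(time_in_bed = 50, transition = absorbing_matrix(),
                          initial_stage = stage_distribution("N2"),
                          sol_mean = 0.1, sol_sd = 0.01)
  hyp <- gen_hypnogram(cfg, seed = 1)
  hyp$stage[] <- "N2"  # force single stage (ignore the latency draw)
  v <- gen_reference_vitals(
    hyp, vitals_config(hr_trend_amp = 0, br_trend_amp = 0,
                       hr_innov_sd = 0, br_innov_sd = 0), seed = 1)
  expect_equal(v$epochs$ref_hr, rep(65.7, 50))
  expect_equal(v$epochs$ref_br, rep(14.8, 50))
})

test_that("pooled reference vitals hit the configured overnight means", {
  # baselines weighted by the chain's stationary stage mix target 66.4 / 14.9
  set.seed(99)
  vc <- vitals_config(sampling_rate = 10L)
  means <- purrr::map_dfr(1:80, function(i) {
    hyp <- gen_hypnogram(hypnogram_config())
    v <- gen_reference_vitals(hyp, vc)
    tibble::tibble(hr = mean(v$epochs$ref_hr), br = mean(v$epochs$ref_br))
  })
  expect_lt(abs(mean(means$hr) - 66.4), 2)
  expect_lt(abs(mean(means$br) - 14.9), 0.5)
})

test_that("stage-dependent baselines separate wake from deep sleep", {
  cfg <- hypnogram_config(time_in_bed = 600)
  for (seed in 1:5) {
    hyp <- gen_hypnogram(cfg, seed = seed)
    if (!any(hyp$stage == "N3") || !any(hyp$stage == "W")) next
    v <- gen_reference_vitals(
      hyp, vitals_config(hr_baseline = c(W = 70, N1 = 66, N2 = 64, N3 = 58, REM = 66),
                         hr_trend_amp = 0, hr_innov_sd = 0.5),
      seed = seed)
    st <- stage_stratified_stats(
      tibble::tibble(stage = hyp$stage, value = v$epochs$ref_hr))
    expect_gt(st$mean[st$stage == "W"], st$mean[st$stage == "N3"])
  }
})

test_that("an error-free device reproduces the reference on covered epochs", {
  hyp <- gen_hypnogram(hypnogram_config(time_in_bed = 300), seed = 2)
  v <- gen_reference_vitals(hyp, vitals_config(), seed = 2)
  dev <- gen_device_observation(
    v$epochs, hyp,
    device_config(hr_bias = 0, br_bias = 0, hr_noise_sd = 0, br_noise_sd = 0,
                  hr_coverage = 1, br_coverage = 1, clock_offset = 0),
    seed = 2)
  expect_equal(dev$dev_hr, v$epochs$ref_hr)
  expect_equal(dev$dev_br, v$epochs$ref_br)
  expect_equal(attr(dev, "shift_epochs"), 0L)
  ba <- simple_ba(v$epochs$ref_hr[1:50], dev$dev_hr[1:50])
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_upper - ba$loa_lower, 0)
})

test_that("coverage dropout matches its configured probability", {
  n <- 100000
  hyp <- gen_hypnogram(hypnogram_config(time_in_bed = n), seed = 4)
  ref <- tibble::tibble(epoch = hyp$epoch, ref_hr = 66, ref_br = 15)
  dev <- gen_device_observation(
    ref, hyp, device_config(clock_offset = 0, hr_coverage = 0.936), seed = 4)
  se <- sqrt(0.936 * (1 - 0.936) / n)
  expect_lt(abs(mean(dev$hr_covered) - 0.936), 3 * se)
})

test_that("an injected constant bias is recovered by direct arithmetic", {
  n <- 10000
  hyp <- gen_hypnogram(hypnogram_config(time_in_bed = n), seed = 6)
  ref <- tibble::tibble(epoch = hyp$epoch, ref_hr = rnorm(n, 66, 5),
                        ref_br = 15)
  noise_sd <- 1
  dev <- gen_device_observation(
    ref, hyp, device_config(hr_bias = 0.5, hr_noise_sd = noise_sd,
                            hr_coverage = 1, clock_offset = 0), seed = 6)
  d <- ref$ref_hr - dev$dev_hr
  expect_lt(abs(mean(d) - 0.5), 3 * noise_sd / sqrt(n))
})

test_that("negative modeled noise SD is rejected", {
  hyp <- gen_hypnogram(hypnogram_config(time_in_bed = 50), seed = 1)
  ref <- tibble::tibble(epoch = hyp$epoch, ref_hr = 60, ref_br = 15)
  expect_error(
    gen_device_observation(ref, hyp,
                           device_config(hr_noise_sd = 1, hr_noise_slope = -1),
                           seed = 1),
    class = "sleepagree_config_error")
})

test_that("the clock shift delays the device stream by whole epochs", {
  hyp <- gen_hypnogram(hypnogram_config(time_in_bed = 200), seed = 3)
  v <- gen_reference_vitals(hyp, vitals_config(), seed = 3)
  dev0 <- gen_device_observation(
    v$epochs, hyp, device_config(hr_noise_sd = 0, hr_bias = 0, hr_coverage = 1,
                                 clock_offset = 0), seed = 9)
  dev2 <- gen_device_observation(
    v$epochs, hyp, device_config(hr_noise_sd = 0, hr_bias = 0, hr_coverage = 1,
                                 clock_offset = 60), seed = 9)
  expect_equal(attr(dev2, "shift_epochs"), 2L)
  expect_false(dev2$hr_covered[1])
  expect_equal(dev2$dev_hr[3:200], dev0$dev_hr[1:198])
})

test_that("cohorts are deterministic under a fixed seed", {
  cfg <- cohort_config(n_subjects = 1, seed = 77)
  a <- gen_cohort(cfg)
  b <- gen_cohort(cfg)
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$subjects, b$subjects)
})

test_that("cohort nights stay inside the study's epoch range", {
  coh <- gen_cohort(cohort_config(n_subjects = 12, seed = 5))
  counts <- dplyr::count(coh$epochs, subject_id)
  expect_true(all(counts$n >= 686 & counts$n <= 1036))
  expect_identical(counts$n, coh$subjects$tib_epochs)
  # every series lives on the same per-subject grid
  expect_true(all(tapply(coh$epochs$epoch_index, coh$epochs$subject_id,
                         function(e) all(e == seq_along(e) - 1L))))
})

test_that("BMI-noise coupling propagates deterministically to subjects", {
  coh <- gen_cohort(cohort_config(n_subjects = 30, seed = 13,
                                  bmi_noise_coupling = -0.2,
                                  female_noise_coupling = 0))
  expect_lt(cor(coh$subjects$bmi, coh$subjects$hr_noise_sd_true), -0.99)
})
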