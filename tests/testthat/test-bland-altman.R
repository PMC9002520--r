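test_that("simple Bland-Altman reproduces the closed-form quantities", {
  ba <- simple_ba(c(1, 0, -1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_total, 1)
  expect_equal(ba$loa_lower, -1.96)
  expect_equal(ba$loa_upper, 1.96)

  const <- simple_ba(rep(2.5, 6))
  expect_equal(const$bias, 2.5)
  expect_equal(const$loa_lower, 2.5)
  expect_equal(const$loa_upper, 2.5)

  expect_error(simple_ba(c(1, 2)), class = "sleepagree_insufficient_data_error")
})

test_that("the simple bias CI agrees with the one-sample t interval", {
  set.seed(2)
  d <- rnorm(40, 0.4, 1.3)
  ba <- simple_ba(d)
  expect_equal(ba$ci_bias, as.numeric(t.test(d)$conf.int))
  # LOA CI half-width is t * SD * sqrt(3/n)
  expect_equal(diff(ba$ci_loa_upper) / 2,
               qt(0.975, 39) * sd(d) * sqrt(3 / 40))
})

test_that("LOA are symmetric about the bias for plain results", {
  set.seed(8)
  for (i in 1:20) {
    ba <- simple_ba(rnorm(sample(5:100, 1), rnorm(1), runif(1, 0.1, 3)))
    expect_equal(ba$loa_upper + ba$loa_lower, 2 * ba$bias)
  }
})

test_that("difference orientation: device underestimation gives positive bias", {
  ref <- c(10, 12, 14, 16)
  dev <- ref - 2  # device reads low
  expect_gt(simple_ba(ref, dev)$bias, 0)
  expect_equal(simple_ba(ref, dev)$bias, 2)
})

test_that("repeated-measures components vanish for constant differences", {
  d <- tibble::tibble(subject = rep(letters[1:4], each = 5),
                      ref = rep(3, 20), dev = rep(1.5, 20))
  ba <- rm_ba(d)
  expect_equal(ba$bias, 1.5)
  expect_equal(ba$var_between, 0)
  expect_equal(ba$var_within, 0)
  expect_equal(ba$loa_lower, 1.5)
  expect_equal(ba$loa_upper, 1.5)
})

test_that("one observation per subject falls back to the simple analysis", {
  set.seed(4)
  diffs <- rnorm(12)
  d <- tibble::tibble(subject = as.character(1:12), ref = diffs, dev = 0)
  expect_warning(ba <- rm_ba(d), "falling back")
  simple <- simple_ba(diffs)
  expect_equal(ba$bias, simple$bias, tolerance = 1e-10)
  expect_equal(ba$loa_upper, simple$loa_upper, tolerance = 1e-10)
  expect_equal(ba$ci_bias, simple$ci_bias, tolerance = 1e-10)
})

test_that("variance components match a REML fit on balanced instances", {
  set.seed(17)
  for (i in 1:20) {
    m <- 8; n_i <- 20
    u <- rnorm(m, 0, 1)
    d <- tibble::tibble(
      subject = rep(seq_len(m), each = n_i),
      ref = 0.3 + rep(u, each = n_i) + rnorm(m * n_i, 0, 1),
      dev = 0
    )
    ba <- rm_ba(d)
    fit <- lme4::lmer(ref ~ 1 + (1 | subject), data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sd_reml <- sqrt(sum(vc$vcov))
    expect_lt(abs(ba$sd_total - sd_reml) / sd_reml, 0.02)
  }
})

test_that("proportional bias regression recovers constructed coefficients", {
  # orthogonal construction: constant difference has exactly zero slope
  ref <- 1:20
  dev <- ref - 3
  pb <- suppressWarnings(test_proportional_bias(ref, dev))  # exact fit
  expect_equal(pb$b1, 0)
  expect_equal(pb$b0, 3)
  expect_false(pb$detected)

  set.seed(9)
  n <- 500
  ref <- runif(n, 40, 100)
  dev <- ref - (5 - 0.1 * ref) + rnorm(n, 0, 0.5)
  pb <- test_proportional_bias(ref, dev)
  expect_lt(abs(pb$b0 - 5), 0.5)
  expect_lt(abs(pb$b1 + 0.1), 0.02)
  expect_true(pb$detected)
  # normal-equations oracle
  X <- cbind(1, ref)
  beta <- solve(t(X) %*% X, t(X) %*% (ref - dev))
  expect_equal(c(pb$b0, pb$b1), as.numeric(beta), tolerance = 1e-10)

  expect_error(test_proportional_bias(rep(5, 10), rnorm(10)),
               class = "sleepagree_degenerate_error")
})

test_that("heteroscedasticity regression calibrates the 2.46 multiplier", {
  # E|e| = sigma * sqrt(2/pi), so 2.46 * c0 approximates 1.96 * sigma; the
  # intercept of a single n = 2000 fit is an extrapolation to ref = 0, so the
  # calibration is checked on the average over replicates
  set.seed(12)
  sigma <- 2
  fits <- t(replicate(20, {
    n <- 2000
    ref <- runif(n, 40, 100)
    dev <- ref + rnorm(n, 0, sigma)
    ht <- test_heteroscedasticity(ref, dev)
    c(c0 = ht$c0, c1 = ht$c1)
  }))
  expect_lt(abs(2.46 * mean(fits[, "c0"]) - 1.96 * sigma) / (1.96 * sigma), 0.05)
  expect_lt(abs(mean(fits[, "c1"])), 0.02)
})

test_that("the Shapiro-Wilk gate has proper size and power", {
  set.seed(3)
  size <- mean(replicate(200, normality_test(rnorm(100))$p > 0.05))
  expect_gte(size, 0.90)
  power <- mean(replicate(200, normality_test(rlnorm(100))$p < 0.05))
  expect_gte(power, 0.95)
  expect_error(normality_test(rnorm(2)), class = "sleepagree_input_error")
  expect_error(normality_test(rnorm(6000)), class = "sleepagree_input_error")
})

test_that("a constant statistic yields a degenerate bootstrap interval", {
  d <- tibble::tibble(x = 1:30)
  expect_warning(
    ci <- bootstrap_ci(d, function(dd) c(k = 5), B = 200, seed = 1),
    "Degenerate")
  expect_equal(ci$conf.low, 5)
  expect_equal(ci$conf.high, 5)
})

test_that("basic bootstrap intervals for a mean attain nominal coverage", {
  set.seed(14)
  covered <- replicate(500, {
    d <- data.frame(x = rnorm(100))
    ci <- bootstrap_ci(d, function(dd) c(mean = mean(dd$x)), B = 1000)
    ci$conf.low <= 0 && 0 <= ci$conf.high
  })
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})

test_that("within-subject resampling keeps every subject in each resample", {
  d <- tibble::tibble(subject = rep(c("a", "b", "c"), each = 30),
                      x = rnorm(90))
  ci <- bootstrap_ci(d, function(dd) {
    expect_setequal(unique(dd$subject), c("a", "b", "c"))
    c(m = mean(dd$x))
  }, B = 200, seed = 2, unit = "within", group = "subject")
  expect_true(ci$conf.low < ci$conf.high)
})

test_that("Pearson correlation CIs behave at the extremes and attain coverage", {
  x <- 1:10
  pc <- pearson_ci(x, x)
  expect_equal(pc$r, 1)
  expect_equal(pc$conf.low, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)

  set.seed(19)
  rho <- 0.8
  covered <- replicate(500, {
    x <- rnorm(50)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(50)
    ci <- pearson_ci(x, y)
    ci$conf.low <= rho && rho <= ci$conf.high
  })
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})

test_that("error-free channels take the plain path with zero-width limits", {
  d <- tibble::tibble(subject = rep(c("a", "b"), each = 10),
                      ref = rnorm(20, 60), dev = NA)
  d$dev <- d$ref
  res <- analyze_agreement(d, mode = "epoch")
  expect_s3_class(res, "ba_result")
  expect_equal(res$bias, 0)
  expect_equal(res$loa_upper - res$loa_lower, 0)
})

test_that("multiplicative error routes to the modeled path with a log transform", {
  set.seed(23)
  hits <- replicate(200, {
    n <- 45
    ref <- rlnorm(n, log(16), 0.8)
    dev <- ref * exp(rnorm(n, -0.7, 0.3))
    res <- analyze_agreement(tibble::tibble(subject = as.character(1:n),
                                            ref = ref, dev = dev),
                             mode = "summary", B = 200)
    inherits(res, "modeled_ba") && res$transform == "log" &&
      res$gates$proportional_bias
  })
  expect_gte(mean(hits), 0.90)
})

test_that("injected proportional bias is recovered on the original scale", {
  set.seed(31)
  n <- 600
  ref <- runif(n, 20, 90)
  dev <- ref - (15.3 - 0.5 * ref) + rnorm(n, 0, 3)
  res <- analyze_agreement(tibble::tibble(subject = rep(c("a", "b", "c"), 200),
                                          ref = ref, dev = dev),
                           mode = "epoch", B = 300, seed = 1)
  expect_s3_class(res, "modeled_ba")
  expect_true(res$gates$proportional_bias)
  expect_lt(abs(res$b0 - 15.3), 1.5)
  expect_lt(abs(res$b1 + 0.5), 0.05)
  td <- tidy(res)
  expect_true(td$conf.low[td$term == "b1"] < -0.5 &&
                -0.5 < td$conf.high[td$term == "b1"])
  # glance evaluates the modeled bias at the mean reference
  gl <- glance(res)
  expect_equal(gl$bias_at_mean, res$b0 + res$b1 * mean(ref))
})

test_that("tidy and glance expose the plain result quantities", {
  set.seed(6)
  ba <- simple_ba(rnorm(30, 1), rnorm(30))
  td <- tidy(ba)
  expect_equal(td$term, c("bias", "loa_lower", "loa_upper"))
  expect_equal(td$estimate[1], ba$bias)
  gl <- glance(ba)
  expect_equal(gl$method, "simple")
  expect_equal(gl$sd_total, ba$sd_total)
  p <- autoplot(ba)
  expect_s3_class(p, "ggplot")
})
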