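random_table <- function() {
  tibble::tibble(tp = sample(0:200, 1), fn = sample(0:60, 1),
                 fp = sample(0:60, 1), tn = sample(0:60, 1))
}

test_that("confusion counts tally the 2x2 table exhaustively", {
  truth <- c(rep(TRUE, 10), rep(FALSE, 5))
  perfect <- confusion_counts(truth, truth)
  expect_equal(as.numeric(perfect), c(10, 0, 0, 5))
  inverted <- confusion_counts(truth, !truth)
  expect_equal(inverted$tp, 0)
  expect_equal(inverted$tn, 0)
  expect_equal(inverted$fn, 10)

  # conservation over random masked inputs
  set.seed(41)
  for (i in 1:25) {
    n <- sample(20:300, 1)
    t <- runif(n) < 0.7
    p <- runif(n) < 0.8
    p[sample.int(n, 5)] <- NA
    cc <- confusion_counts(t, p)
    expect_equal(cc$tp + cc$fn + cc$fp + cc$tn, sum(!is.na(p)))
  }

  expect_error(confusion_counts(logical(0), logical(0)),
               class = "sleepagree_no_epochs_error")
  expect_error(confusion_counts(c("asleep"), c("sleep")),
               class = "sleepagree_input_error")
})

test_that("the metric battery matches direct formula evaluation", {
  m <- class_metrics(tibble::tibble(tp = 70, fn = 5, fp = 13, tn = 12))
  expect_equal(m$sensitivity, 70 / 75)
  expect_equal(m$specificity, 12 / 25)
  expect_equal(m$accuracy, 0.82)
  expect_equal(m$precision, 70 / 83)
  pe <- (75 * 83 + 25 * 17) / 100^2
  expect_equal(m$kappa, (0.82 - pe) / (1 - pe))
  expect_equal(m$kappa, 0.4627, tolerance = 1e-4)
  expect_equal(m$pabak, 0.64)
  expect_equal(m$dprime, qnorm(70 / 75) - qnorm(1 - 12 / 25))
  expect_equal(m$dprime, 1.451, tolerance = 1e-3)
  expect_equal(m$balanced_accuracy, (70 / 75 + 12 / 25) / 2)
})

test_that("a perfect classifier maxes every rate", {
  m <- class_metrics(tibble::tibble(tp = 50, fn = 0, fp = 0, tn = 20))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$kappa, 1)
  expect_equal(m$pabak, 1)
  # clamped rates keep d-prime finite
  expect_true(is.finite(m$dprime))
  expect_equal(m$dprime, qnorm(1 - 1 / 100) - qnorm(1 / 40))
})

test_that("degenerate marginals flag the affected metrics as undefined", {
  m <- class_metrics(tibble::tibble(tp = 30, fn = 5, fp = 0, tn = 0))
  expect_true(is.na(m$kappa))
  expect_true(is.na(m$specificity))
  expect_false(is.na(m$accuracy))
})

test_that("PABAK and balanced-accuracy identities hold on random tables", {
  set.seed(43)
  for (i in 1:1000) {
    counts <- random_table()
    if (sum(counts) == 0) next
    m <- class_metrics(counts)
    expect_identical(m$pabak, 2 * m$accuracy - 1)
    if (!is.na(m$balanced_accuracy)) {
      expect_identical(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    }
    if (!is.na(m$kappa)) expect_lte(m$kappa, m$accuracy)
  }
})

test_that("d-prime increases in sensitivity at fixed specificity", {
  n <- 1000
  spec_rate <- 0.5
  grid <- seq(0.55, 0.99, by = 0.02)
  dp <- vapply(grid, function(s) {
    tp <- round(s * n)
    class_metrics(tibble::tibble(tp = tp, fn = n - tp,
                                 fp = n / 2, tn = n / 2))$dprime
  }, numeric(1))
  expect_true(all(diff(dp) > 0))
})

test_that("the ROC sweep equals exhaustive pair counting", {
  # worked four-epoch example: 2 of 4 cross-class pairs concordant
  roc <- pooled_roc(c(0.9, 0.6, 0.8, 0.7), c("sleep", "sleep", "wake", "wake"))
  expect_equal(roc$auc, 0.5)

  brute_auc <- function(scores, truth) {
    pos <- scores[truth]; neg <- scores[!truth]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(pairs)
  }
  set.seed(47)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    truth <- runif(n) < 0.6
    if (!any(truth) || all(truth)) next
    scores <- round(runif(n), 2)  # force ties
    expect_equal(pooled_roc(scores, truth)$auc, brute_auc(scores, truth))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(53)
  truth <- runif(500) < 0.7
  scores <- runif(500)
  a <- pooled_roc(scores, truth)$auc
  expect_equal(pooled_roc(qlogis(scores), truth)$auc, a)
  expect_equal(pooled_roc(scores^3, truth)$auc, a)
})

test_that("perfectly separated scores give AUC one", {
  truth <- c(rep(TRUE, 6), rep(FALSE, 6))
  expect_equal(pooled_roc(c(runif(6, 0.8, 1), runif(6, 0, 0.2)), truth)$auc, 1)
  expect_error(pooled_roc(runif(5), rep(TRUE, 5)),
               class = "sleepagree_input_error")
})

test_that("the sweep agrees with an independent ROC implementation", {
  set.seed(59)
  truth <- runif(400) < 0.74
  scores <- plogis(rnorm(400, ifelse(truth, 1, 0)))
  ours <- pooled_roc(scores, truth)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(response = truth,
                                              predictor = scores,
                                              quiet = TRUE)))
  expect_equal(ours, as.numeric(ref))
})

test_that("the cohort summary mirrors the per-subject battery", {
  d <- tibble::tibble(
    subject = rep(c("a", "b", "c"), each = 100),
    truth = rep(rep(c(TRUE, FALSE), c(74, 26)), 3),
    pred = rep(rep(c(TRUE, FALSE, TRUE, FALSE), c(70, 4, 10, 16)), 3),
    score = rep(plogis(rnorm(100, 0.5)), 3)
  )
  cs <- cohort_class_summary(d)
  expect_equal(nrow(cs$per_subject), 3)
  # identical subjects: zero SD everywhere
  expect_true(all(cs$summary$sd == 0))
  # PABAK mean is exactly 2 x accuracy mean - 1, by linearity
  acc <- cs$summary$mean[cs$summary$metric == "accuracy"]
  pab <- cs$summary$mean[cs$summary$metric == "pabak"]
  expect_equal(pab, 2 * acc - 1)
  expect_setequal(
    cs$summary$metric,
    c("sensitivity", "specificity", "accuracy", "balanced_accuracy",
      "precision", "kappa", "pabak", "dprime"))
  expect_true(cs$auc >= 0 && cs$auc <= 1)
})
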