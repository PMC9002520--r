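# Small in-code fixtures shared across test files.

# A transition matrix that never leaves the given stage.
absorbing_matrix <- function(stage = "W") {
  p <- matrix(0, 5, 5, dimnames = list(STAGES <- c("W", "N1", "N2", "N3", "REM"),
                                       STAGES))
  diag(p) <- 1
  p
}

# Two-state W/N2 chain with symmetric switching probability `q`.
two_state_matrix <- function(q = 0.1) {
  p <- absorbing_matrix()
  p["W", "W"] <- 1 - q; p["W", "N2"] <- q
  p["N2", "N2"] <- 1 - q; p["N2", "W"] <- q
  p
}

stage_distribution <- function(stage) {
  setNames(as.numeric(c("W", "N1", "N2", "N3", "REM") == stage),
           c("W", "N1", "N2", "N3", "REM"))
}

# Minimal hand-built cohort: `n` subjects whose device prediction can be made
# to agree exactly with the consensus truth (dev_exact = TRUE) or perturbed.
tiny_cohort <- function(n_subjects = 4, n_epochs = 120, seed = 1,
                        dev_exact = TRUE) {
  set.seed(seed)
  epochs <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    hyp <- gen_hypnogram(hypnogram_config(time_in_bed = n_epochs,
                                          sol_mean = 5, sol_sd = 2))
    panel <- gen_scorer_panel(hyp, error_rate = 0.1)
    cons <- consensus(panel$scorer1, panel$scorer2, panel$scorer3, panel$expert)
    asleep <- to_binary(cons) == "sleep"
    ref_hr <- 66 + 4 * sin(2 * pi * seq_len(n_epochs) / n_epochs) +
      ifelse(asleep, -2, 2)
    ref_br <- 15 + 0.8 * sin(2 * pi * seq_len(n_epochs) / n_epochs)
    tibble::tibble(
      subject_id = sprintf("s%02d", i),
      epoch_index = hyp$epoch,
      epoch_start_s = hyp$epoch * 30,
      stage_truth = panel$truth,
      stage_scorer1 = panel$scorer1, stage_scorer2 = panel$scorer2,
      stage_scorer3 = panel$scorer3, stage_expert = panel$expert,
      ref_hr = ref_hr,
      dev_hr = if (dev_exact) ref_hr else ref_hr + rnorm(n_epochs),
      ref_br = ref_br,
      dev_br = if (dev_exact) ref_br else ref_br + rnorm(n_epochs, sd = 0.5),
      dev_score = ifelse(asleep, 0.9, 0.1),
      dev_pred_sleep = asleep,
      ref_move = as.numeric(!asleep), dev_move = as.numeric(!asleep),
      hr_covered = TRUE, br_covered = TRUE, psg_artifact = FALSE
    )
  })
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n_subjects)),
    age = 30 + seq_len(n_subjects), sex = rep(c("F", "M"),
                                              length.out = n_subjects),
    bmi = 24 + seq_len(n_subjects) / 2, ahi = 2
  )
  structure(list(subjects = subjects, epochs = epochs, config = NULL),
            class = "sleep_cohort")
}
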