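rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Generate a synthetic validation cohort
#'
#' Simulates `n_subjects` subject-nights with the full structure the agreement
#' pipeline consumes: covariates (age, sex, BMI, AHI), a true hypnogram with a
#' three-technician scorer panel and expert, reference and device HR/BR epoch
#' series, device sleep score and sleep/wake prediction, movement channels,
#' PSG artifact mask, and the injected device parameters for recovery tests.
#' Covariates and per-subject parameters are drawn under the master seed;
#' subject i's series use seed `seed + i`, so any subject-night can be
#' regenerated independently.
#'
#' @param config A [cohort_config()].
#' @return Object of class `sleep_cohort`: a list with `subjects` (one row per
#'   subject: covariates, time in bed, and injected true parameters),
#'   `epochs` (one row per subject-epoch, the column dialect of
#'   [write_cohort()]), and `config`.
#' @examples
#' coh <- gen_cohort(cohort_config(n_subjects = 2, seed = 7))
#' dplyr::count(coh$epochs, subject_id)
#' @export
gen_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  set.seed(config$seed)

  alp <- lognormal_params(config$ahi_mean, config$ahi_sd)
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n)),
    age = round(rtrunc_norm(n, config$age_mean, config$age_sd,
                            config$age_range[1], config$age_range[2]), 1),
    sex = ifelse(runif(n) < config$prop_female, "F", "M"),
    bmi = round(rtrunc_norm(n, config$bmi_mean, config$bmi_sd, lower = 15), 1),
    ahi = round(rlnorm(n, alp$meanlog, alp$sdlog), 1),
    tib_epochs = pmin(pmax(as.integer(round(rnorm(n, config$tib_mean, config$tib_sd))),
                           config$tib_range[1]), config$tib_range[2]),
    hr_shift = rnorm(n, 0, config$hr_subject_sd),
    br_shift = rnorm(n, 0, config$br_subject_sd),
    hr_bias_true = config$device$hr_bias + rnorm(n, 0, config$hr_bias_subject_sd),
    br_bias_true = config$device$br_bias + rnorm(n, 0, config$br_bias_subject_sd)
  )
  subjects$hr_noise_sd_true <- pmax(
    config$device$hr_noise_sd +
      config$bmi_noise_coupling * (subjects$bmi - config$bmi_mean) +
      config$female_noise_coupling * (subjects$sex == "F"),
    0.3
  )
  subjects$br_noise_sd_true <- config$device$br_noise_sd

  one_subject <- function(i) {
    sub <- subjects[i, ]
    seed_i <- config$seed + i
    hcfg <- config$hypnogram
    hcfg$time_in_bed <- sub$tib_epochs
    vcfg <- config$vitals
    vcfg$hr_baseline <- vcfg$hr_baseline + sub$hr_shift
    vcfg$br_baseline <- pmax(vcfg$br_baseline + sub$br_shift, 4)
    dcfg <- config$device
    dcfg$hr_bias <- sub$hr_bias_true
    dcfg$br_bias <- sub$br_bias_true
    dcfg$hr_noise_sd <- sub$hr_noise_sd_true
    dcfg$br_noise_sd <- sub$br_noise_sd_true

    set.seed(seed_i)
    hyp <- gen_hypnogram(hcfg)
    panel <- gen_scorer_panel(hyp, config$scorer_error_rate)
    vit <- gen_reference_vitals(hyp, vcfg)
    dev <- gen_device_observation(vit$epochs, hyp, dcfg)
    artifact <- runif(nrow(hyp)) < config$artifact_prob

    tibble::tibble(
      subject_id = sub$subject_id,
      epoch_index = hyp$epoch,
      epoch_start_s = hyp$epoch * 30,
      stage_truth = panel$truth,
      stage_scorer1 = panel$scorer1,
      stage_scorer2 = panel$scorer2,
      stage_scorer3 = panel$scorer3,
      stage_expert = panel$expert,
      ref_hr = vit$epochs$ref_hr,
      dev_hr = dev$dev_hr,
      ref_br = vit$epochs$ref_br,
      dev_br = dev$dev_br,
      dev_score = dev$dev_score,
      dev_pred_sleep = dev$dev_pred_sleep,
      ref_move = dev$ref_move,
      dev_move = dev$dev_move,
      hr_covered = dev$hr_covered,
      br_covered = dev$br_covered,
      psg_artifact = artifact
    )
  }

  epochs <- purrr::map_dfr(seq_len(n), one_subject)
  subjects$shift_epochs_true <- vapply(
    subjects$tib_epochs, function(m) clock_shift_epochs(config$device, m),
    integer(1)
  )
  structure(list(subjects = subjects, epochs = epochs, config = config),
            class = "sleep_cohort")
}

#' @export
print.sleep_cohort <- function(x, ...) {
  cat(sprintf("<sleep_cohort> %d subjects, %d epochs (seed %d)\n",
              nrow(x$subjects), nrow(x$epochs), x$config$seed))
  invisible(x)
}

epoch_col_spec <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    epoch_index = readr::col_integer(),
    epoch_start_s = readr::col_double(),
    stage_truth = readr::col_character(),
    stage_scorer1 = readr::col_character(),
    stage_scorer2 = readr::col_character(),
    stage_scorer3 = readr::col_character(),
    stage_expert = readr::col_character(),
    ref_hr = readr::col_double(),
    dev_hr = readr::col_double(),
    ref_br = readr::col_double(),
    dev_br = readr::col_double(),
    dev_score = readr::col_double(),
    dev_pred_sleep = readr::col_logical(),
    ref_move = readr::col_double(),
    dev_move = readr::col_double(),
    hr_covered = readr::col_logical(),
    br_covered = readr::col_logical(),
    psg_artifact = readr::col_logical()
  )
}

#' Write a cohort to a directory
#'
#' Writes `subjects.csv`, one `epochs/<subject_id>.csv` per subject,
#' `truth.json` (the injected per-subject parameters) and `config.yaml`.
#'
#' @param cohort A `sleep_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sleep_cohort"))
  dir.create(file.path(dir, "epochs"), recursive = TRUE, showWarnings = FALSE)
  covars <- c("subject_id", "age", "sex", "bmi", "ahi", "tib_epochs")
  readr::write_csv(cohort$subjects[covars], file.path(dir, "subjects.csv"))
  truth_cols <- setdiff(names(cohort$subjects), covars[-1])
  jsonlite::write_json(cohort$subjects[truth_cols], file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  for (id in cohort$subjects$subject_id) {
    readr::write_csv(dplyr::filter(cohort$epochs, .data$subject_id == id),
                     file.path(dir, "epochs", paste0(id, ".csv")))
  }
  cfg <- cohort$config
  cfg$hypnogram$transition <- as.vector(t(cfg$hypnogram$transition))
  yaml::write_yaml(rapply(unclass(cfg), unclass, how = "replace"),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read one epochs table, validating the dialect
#'
#' Reads a per-subject `epochs.csv` as written by [write_cohort()]. Missing
#' columns, wrongly typed values and invalid stage labels are rejected with
#' the offending line numbers; nothing is silently coerced.
#'
#' @param path Path to an epochs CSV file.
#' @return Tibble in the epochs dialect, stage columns as factors.
#' @export
read_epochs <- function(path) {
  spec <- epoch_col_spec()
  x <- suppressWarnings(readr::read_csv(path, col_types = spec,
                                        progress = FALSE))
  missing <- setdiff(names(spec$cols), names(x))
  if (length(missing)) {
    abort(sprintf("Epochs file %s is missing columns: %s.",
                  path, paste(missing, collapse = ", ")),
          class = "sleepagree_io_error")
  }
  probs <- readr::problems(x)
  if (nrow(probs)) {
    abort(sprintf("Malformed rows in %s (lines %s).", path,
                  paste(unique(probs$row), collapse = ", ")),
          class = "sleepagree_io_error")
  }
  for (col in grep("^stage_", names(x), value = TRUE)) {
    bad <- !is.na(x[[col]]) & !(x[[col]] %in% STAGES)
    if (any(bad)) {
      abort(sprintf("Invalid stage labels in %s column %s (lines %s).",
                    path, col, paste(which(bad) + 1L, collapse = ", ")),
            class = "sleepagree_io_error")
    }
    x[[col]] <- factor(x[[col]], levels = STAGES)
  }
  x
}

#' Read a cohort directory
#'
#' Inverse of [write_cohort()] for the subject and epoch tables (the injected
#' truth parameters are reattached from `truth.json` when present).
#'
#' @param dir Directory written by [write_cohort()].
#' @return Object of class `sleep_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  subjects <- readr::read_csv(file.path(dir, "subjects.csv"),
                              col_types = readr::cols(), progress = FALSE)
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    truth <- tibble::as_tibble(jsonlite::read_json(truth_path, simplifyVector = TRUE))
    subjects <- dplyr::left_join(subjects, truth, by = "subject_id")
  }
  files <- file.path(dir, "epochs", paste0(subjects$subject_id, ".csv"))
  epochs <- purrr::map_dfr(files, read_epochs)
  structure(list(subjects = subjects, epochs = epochs, config = NULL),
            class = "sleep_cohort")
}
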