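# Synthetic cohort generator: couples latent pain-sensitivity class to PAF,
# corticomotor modulation and diary trajectories, per the study design.

#' Cohort configuration
#'
#' Parameters of the synthetic cohort. Defaults encode the planted-effect
#' study conditions: 150 participants split 100/50 in enrollment order, a
#' 1 Hz class-conditional PAF gap (high-pain class slower), and depressor
#' probabilities of 0.75 (high) vs 0.25 (low).
#'
#' @param n_participants Cohort size (>= 10).
#' @param train_fraction Fraction (0, 1) forming the training set, taken in
#'   enrollment order.
#' @param seed Master seed; all participant-level randomness derives from it.
#' @param p_high Prevalence of the high-pain-sensitive class.
#' @param paf_mean_high,paf_mean_low Class-conditional mean PAF (Hz) of the
#'   high- and low-pain-sensitive classes; must lie in [8, 12].
#' @param paf_sd Class-conditional PAF SD (Hz); draws clipped to [8, 12].
#' @param p_depressor_given_high,p_depressor_given_low Probability a
#'   participant of each class is a corticomotor depressor.
#' @param diary_class_params Named list (`high`, `low`) of
#'   [trajectory_params()].
#' @param diary_missing_rate Diary timepoint missingness, [0, 1).
#' @param p_female Probability of female sex (covariate, class-independent
#'   by default).
#' @param eeg An [eeg_sim_params()].
#' @param map A [map_sim_params()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 150, train_fraction = 2 / 3,
                          seed = 1, p_high = 0.5,
                          paf_mean_high = 9.5, paf_mean_low = 10.5,
                          paf_sd = 0.5,
                          p_depressor_given_high = 0.75,
                          p_depressor_given_low = 0.25,
                          diary_class_params = default_trajectory_classes(),
                          diary_missing_rate = 0.05,
                          p_female = 70 / 159,
                          eeg = eeg_sim_params(),
                          map = map_sim_params()) {
  probs <- c(
    p_high = p_high, p_depressor_given_high = p_depressor_given_high,
    p_depressor_given_low = p_depressor_given_low, p_female = p_female
  )
  bad <- probs[probs < 0 | probs > 1]
  if (length(bad) > 0) {
    abort(paste0("probability out of [0, 1]: ", paste(names(bad), collapse = ", ")))
  }
  if (n_participants < 10) abort("`n_participants` must be at least 10")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly in (0, 1)")
  }
  for (m in c(paf_mean_high, paf_mean_low)) {
    if (m < 8 || m > 12) abort("`paf_mean_high`/`paf_mean_low` must lie in [8, 12]")
  }
  if (diary_missing_rate < 0 || diary_missing_rate >= 1) {
    abort("`diary_missing_rate` must lie in [0, 1)")
  }
  if (!all(c("high", "low") %in% names(diary_class_params))) {
    abort("`diary_class_params` needs elements `high` and `low`")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      train_fraction = train_fraction, seed = as.integer(seed),
      p_high = p_high, paf_mean_high = paf_mean_high,
      paf_mean_low = paf_mean_low, paf_sd = paf_sd,
      p_depressor_given_high = p_depressor_given_high,
      p_depressor_given_low = p_depressor_given_low,
      diary_class_params = diary_class_params,
      diary_missing_rate = diary_missing_rate, p_female = p_female,
      eeg = eeg, map = map
    ),
    class = "cohort_config"
  )
}

# Deterministic per-participant, per-stream child seeds below 2^31.
.child_seed <- function(master, participant, stream) {
  streams <- c(eeg0 = 1L, eeg2 = 2L, eeg5 = 3L, map = 4L, diary = 5L,
               latent = 6L)
  as.integer(
    (as.numeric(master) * 7919 + as.numeric(participant) * 104729 +
       streams[[stream]] * 337) %% 2147483562
  ) + 1L
}

#' Generate a synthetic cohort
#'
#' Draws each participant's latent pain-sensitivity class, then their
#' class-conditional PAF (EEG recordings on days 0, 2, 5 share the planted
#' PAF, with independent noise), facilitator/depressor status (motor maps on
#' days 0, 2, 5), a days-1-30 twice-daily pain diary from the class
#' trajectory, and class-independent covariates (sex, Pain Catastrophizing
#' Scale totals). Deterministic for a given config (which includes the seed).
#'
#' @param config A [cohort_config()].
#' @param eeg_days Which EEG sessions to synthesise (default days 0, 2 and
#'   5; pass `0` to generate only the baseline session the classifier uses).
#' @param eeg_channels Optional channel subset passed to [simulate_eeg()]
#'   (e.g. a sensor ROI when only the ROI pathway will be used).
#' @param keep_recordings Keep raw EEG/map-trial objects (default TRUE).
#' @return A list of class `synthetic_cohort`: `participants` (tibble with
#'   id, set, true class, planted PAF, depressor flag, modulation factor,
#'   covariates), `recordings` (per participant, per EEG day), `maps`
#'   (per participant: day 0/2/5 `map_grid`s), `diaries` (per participant),
#'   and the `config`.
#' @export
generate_cohort <- function(config = cohort_config(), eeg_days = c(0, 2, 5),
                            eeg_channels = NULL, keep_recordings = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  n_train <- round(n * config$train_fraction)
  set.seed(.child_seed(config$seed, 0L, "latent"))
  cls <- ifelse(runif(n) < config$p_high, "high", "low")
  paf_mean <- ifelse(cls == "high", config$paf_mean_high, config$paf_mean_low)
  true_paf <- pmin(12, pmax(8, rnorm(n, paf_mean, config$paf_sd)))
  p_dep <- ifelse(cls == "high", config$p_depressor_given_high,
                  config$p_depressor_given_low)
  depressor <- runif(n) < p_dep
  sex <- ifelse(runif(n) < config$p_female, "female", "male")
  pcs_total <- pmin(52, pmax(0, round(rnorm(n, 12, 8))))
  pcs_helplessness <- pmin(24, pmax(0, round(pcs_total * 0.45 + rnorm(n, 0, 2))))

  participants <- tibble(
    participant = seq_len(n),
    set = ifelse(seq_len(n) <= n_train, "train", "test"),
    true_class = cls, true_paf = true_paf, depressor = depressor,
    sex = sex, pcs_total = pcs_total, pcs_helplessness = pcs_helplessness
  )

  recordings <- NULL
  if (keep_recordings && length(eeg_days) > 0) {
    streams <- c(`0` = "eeg0", `2` = "eeg2", `5` = "eeg5")
    recordings <- purrr::map(seq_len(n), function(i) {
      recs <- purrr::map(eeg_days, function(d) {
        simulate_eeg(
          true_paf[i], config$eeg,
          seed = .child_seed(config$seed, i, streams[[as.character(d)]]),
          channels = eeg_channels
        )
      })
      setNames(recs, paste0("day", eeg_days))
    })
  }

  maps <- purrr::map(seq_len(n), function(i) {
    sim <- simulate_maps(depressor[i], config$map,
                         seed = .child_seed(config$seed, i, "map"))
    grids <- purrr::map(c(0L, 2L, 5L), function(d) {
      build_map(sim$trials[sim$trials$day == d, ], session_day = d)
    })
    list(day0 = grids[[1]], day2 = grids[[2]], day5 = grids[[3]],
         modulation_factor = sim$modulation_factor)
  })
  participants$modulation_factor <- map_dbl(maps, "modulation_factor")

  diaries <- purrr::map(seq_len(n), function(i) {
    simulate_diary(
      config$diary_class_params[[cls[i]]],
      missing_rate = config$diary_missing_rate,
      seed = .child_seed(config$seed, i, "diary")
    )
  })

  structure(
    list(participants = participants, recordings = recordings, maps = maps,
         diaries = diaries, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- nrow(x$participants)
  cat(sprintf(
    "<synthetic_cohort> %d participants (%d train / %d test), %d high-pain class\n",
    n, sum(x$participants$set == "train"), sum(x$participants$set == "test"),
    sum(x$participants$true_class == "high")
  ))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Serialises maps and diaries as CSV, participant ground truth as JSON and,
#' optionally, EEG recordings as per-participant CSV matrices with a JSON
#' sidecar (sampling rate, labels). Schema version recorded in
#' `cohort.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param include_eeg Write raw EEG matrices too (large; default FALSE).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, include_eeg = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$participants,
                   file.path(dir, "participants.csv"), row.names = FALSE)
  diaries <- purrr::imap(cohort$diaries, function(d, i) {
    mutate(d, participant = i, .before = 1)
  }) |> list_rbind()
  utils::write.csv(diaries, file.path(dir, "diaries.csv"), row.names = FALSE)
  maps <- purrr::imap(cohort$maps, function(m, i) {
    purrr::map(c("day0", "day2", "day5"), function(d) {
      mutate(m[[d]], participant = i, day = as.integer(sub("day", "", d)),
             .before = 1)
    }) |> list_rbind()
  }) |> list_rbind()
  utils::write.csv(maps, file.path(dir, "maps.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(schema_version = "1.0", n_participants = nrow(cohort$participants),
         seed = cohort$config$seed),
    file.path(dir, "cohort.json"), auto_unbox = TRUE
  )
  if (include_eeg && !is.null(cohort$recordings)) {
    eeg_dir <- file.path(dir, "eeg")
    dir.create(eeg_dir, showWarnings = FALSE)
    purrr::iwalk(cohort$recordings, function(recs, i) {
      purrr::iwalk(recs, function(rec, day) {
        base <- file.path(eeg_dir, sprintf("p%03d_%s", i, day))
        utils::write.csv(as.data.frame(t(rec$data)),
                         paste0(base, ".csv"), row.names = FALSE)
        jsonlite::write_json(
          list(sfreq = rec$sfreq, channel_labels = rec$channel_labels),
          paste0(base, ".json"), auto_unbox = TRUE
        )
      })
    })
  }
  invisible(dir)
}
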