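# Shared fixtures, built in code.

# A power_spectrum tibble from bare vectors.
make_spectrum <- function(freq, power, channel = "signal") {
  corticomark:::as_power_spectrum(
    tibble::tibble(channel = channel, freq = freq, power = power)
  )
}

# Fast EEG simulation settings used throughout the suite (63 channels, 2 min).
fast_eeg <- function(...) eeg_sim_params(duration = 120, sfreq = 125, ...)

# A small cohort configuration for structural tests.
small_cohort_config <- function(n = 12, seed = 1, ...) {
  cohort_config(
    n_participants = n, seed = seed,
    eeg = eeg_sim_params(duration = 20, sfreq = 125), ...
  )
}

# Battery settings: the reduced problem sizes used for repeated-seed
# end-to-end runs (sensor-ROI pathway, 60 s recordings).
battery_config <- function(seed, null_cohort = FALSE, ...) {
  base <- if (null_cohort) {
    cohort_config(
      seed = seed, paf_mean_high = 10, paf_mean_low = 10,
      p_depressor_given_high = 0.5, p_depressor_given_low = 0.5,
      diary_class_params = list(
        high = default_trajectory_classes()$high,
        low = default_trajectory_classes()$high
      ),
      eeg = eeg_sim_params(duration = 60, sfreq = 125)
    )
  } else {
    cohort_config(seed = seed, eeg = eeg_sim_params(duration = 60, sfreq = 125))
  }
  pipeline_config(
    cohort = base, paf_source = "roi",
    families = "logistic_regression", gmm_starts = 10, n_boot = 0,
    seed = seed, ...
  )
}

# Simulated diaries for two separated trajectory classes.
two_class_diaries <- function(n = 100, seed = 1, sep_sd = 4,
                              missing_rate = 0.05) {
  base <- default_trajectory_classes()
  hi <- trajectory_params(
    intercept = base$low$intercept + sep_sd * base$low$within_noise_sd,
    slope = base$high$slope, quadratic = base$high$quadratic
  )
  cls <- rep(c("high", "low"), length.out = n)
  diaries <- lapply(seq_len(n), function(i) {
    simulate_diary(if (cls[i] == "high") hi else base$low,
                   missing_rate = missing_rate, seed = seed * 1000 + i)
  })
  list(diaries = diaries, truth = cls)
}

# Adjusted Rand index between two partitions (for recovery checks).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
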