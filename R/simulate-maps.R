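# Synthetic TMS motor maps with planted facilitation/depression.

#' Motor-map simulation parameters
#'
#' @param grid_shape Integer rows x cols of the 1 cm stimulation lattice.
#' @param hotspot_center Grid coordinate (row, col, 0-based) of the map peak.
#' @param spatial_sd Gaussian spatial spread of the representation, cm.
#' @param base_amplitude Peak mean MEP amplitude at the hotspot, mV.
#' @param facilitation_factor_range,depression_factor_range Ranges of the
#'   multiplicative day-5 modulation factor for facilitators (> 1) and
#'   depressors (< 1).
#' @param trial_noise_sd Per-trial amplitude noise, mV.
#' @param trials_per_site Stimulation trials delivered per site.
#' @param day2_log_carryover Fraction of the (log) day-5 modulation already
#'   expressed at day 2 — planted modulation is persistent across sessions.
#' @param day2_log_noise SD of session-specific log-modulation noise at day 2.
#' @return A list of class `map_sim_params`.
#' @export
map_sim_params <- function(grid_shape = c(8, 8), hotspot_center = c(3, 3),
                           spatial_sd = 1.5, base_amplitude = 0.5,
                           facilitation_factor_range = c(1.15, 1.6),
                           depression_factor_range = c(0.5, 0.85),
                           trial_noise_sd = 0.03, trials_per_site = 5,
                           day2_log_carryover = 0.6, day2_log_noise = 0.05) {
  if (any(depression_factor_range >= 1) || any(facilitation_factor_range <= 1)) {
    abort("depression factors must be < 1 and facilitation factors > 1")
  }
  if (base_amplitude <= 0) abort("`base_amplitude` must be positive")
  structure(
    list(
      grid_shape = as.integer(grid_shape), hotspot_center = hotspot_center,
      spatial_sd = spatial_sd, base_amplitude = base_amplitude,
      facilitation_factor_range = facilitation_factor_range,
      depression_factor_range = depression_factor_range,
      trial_noise_sd = trial_noise_sd,
      trials_per_site = as.integer(trials_per_site),
      day2_log_carryover = day2_log_carryover,
      day2_log_noise = day2_log_noise
    ),
    class = "map_sim_params"
  )
}

#' Simulate a participant's motor-map sessions
#'
#' Generates day 0, 2 and 5 trial tables on the stimulation lattice. The
#' day-0 mean map is a truncated spatial Gaussian around the hotspot. A
#' depressor's day-5 map is the day-0 profile times a factor drawn from
#' `depression_factor_range`; a facilitator's from
#' `facilitation_factor_range`. Day 2 expresses a configurable fraction of
#' the day-5 log-modulation (persistent planted modulation), plus small
#' session noise. Per-trial noise is truncated at zero.
#'
#' @param depressor Logical: plant depression (TRUE) or facilitation.
#' @param params A [map_sim_params()].
#' @param seed Integer seed.
#' @return A list with `trials` (tibble: `day`, `row`, `col`, `trial`,
#'   `amplitude`) and `modulation_factor` (the planted day-5 factor).
#' @export
simulate_maps <- function(depressor, params = map_sim_params(), seed = 1) {
  stopifnot(inherits(params, "map_sim_params"))
  set.seed(seed)
  nr <- params$grid_shape[1]
  nc <- params$grid_shape[2]
  sites <- expand_grid(row = 0:(nr - 1), col = 0:(nc - 1))
  d2 <- (sites$row - params$hotspot_center[1])^2 +
    (sites$col - params$hotspot_center[2])^2
  profile <- params$base_amplitude * exp(-d2 / (2 * params$spatial_sd^2))
  rng <- if (depressor) params$depression_factor_range else
    params$facilitation_factor_range
  f5 <- runif(1, rng[1], rng[2])
  f2 <- exp(params$day2_log_carryover * log(f5) +
              rnorm(1, 0, params$day2_log_noise))
  day_factor <- c(`0` = 1, `2` = f2, `5` = f5)
  trials <- purrr::imap(day_factor, function(fac, day) {
    amp <- rep(profile * fac, each = params$trials_per_site)
    amp <- pmax(0, amp + rnorm(length(amp), 0, params$trial_noise_sd))
    tibble(
      day = as.integer(day),
      row = rep(sites$row, each = params$trials_per_site),
      col = rep(sites$col, each = params$trials_per_site),
      trial = rep(seq_len(params$trials_per_site), times = nrow(sites)),
      amplitude = amp
    )
  }) |> list_rbind()
  list(trials = trials, modulation_factor = f5)
}
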