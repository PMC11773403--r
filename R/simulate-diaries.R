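# Synthetic electronic pain diaries drawn from latent trajectory classes.

#' Trajectory class parameters
#'
#' Quadratic mean trajectory of the 0-20 combined pain score (chewing +
#' yawning) over days, with a participant-level random intercept and
#' within-participant noise.
#'
#' @param intercept,slope,quadratic Polynomial coefficients in pain units
#'   (0-20 scale), per day and per day squared.
#' @param within_noise_sd Within-participant (timepoint) noise SD.
#' @param between_sd Between-participant random-intercept SD.
#' @return A list of class `trajectory_params`.
#' @export
trajectory_params <- function(intercept, slope, quadratic,
                              within_noise_sd = 1.5, between_sd = 1.5) {
  if (intercept < 0) abort("`intercept` must be nonnegative")
  if (within_noise_sd <= 0) abort("`within_noise_sd` must be positive")
  structure(
    list(
      intercept = intercept, slope = slope, quadratic = quadratic,
      within_noise_sd = within_noise_sd, between_sd = between_sd
    ),
    class = "trajectory_params"
  )
}

#' Default high/low pain-sensitive trajectory classes
#'
#' Progressively developing pain peaking in the second week for the
#' high-sensitive class; a shallow mild course for the low-sensitive class.
#'
#' @return A named list with elements `high` and `low`.
#' @export
default_trajectory_classes <- function() {
  list(
    high = trajectory_params(0.5, 1.6, -0.04),
    low = trajectory_params(0.2, 0.45, -0.012)
  )
}

# Timepoint grid: days 1-30, 10 am and 7 pm encoded as day + 0 / 0.375.
.diary_times <- function(days = 1:30) {
  expand_grid(day = days, time = c("10:00", "19:00")) |>
    mutate(t = .data$day + ifelse(.data$time == "19:00", 0.375, 0))
}

#' Simulate a participant's pain diary
#'
#' Draws twice-daily (10 am, 7 pm) chewing and yawning pain scores for days
#' 1-30 from the participant's class trajectory: combined latent score =
#' intercept + slope*t + quadratic*t^2 + random intercept + noise, rounded
#' and clipped to 0-20, then split into two 0-10 integer activity scores
#' (ceiling/floor halves). Missing timepoints (both activities) are dropped
#' completely at random at `missing_rate` and flagged, never zero-filled.
#'
#' @param class_params A [trajectory_params()].
#' @param missing_rate Probability each timepoint is missing, in [0, 1).
#' @param seed Integer seed.
#' @param days Diary days (default 1-30).
#' @return A tibble with columns `day`, `time`, `activity`, `score`,
#'   `missing` (logical; `score` is `NA` when missing).
#' @export
simulate_diary <- function(class_params, missing_rate = 0.05, seed = 1,
                           days = 1:30) {
  stopifnot(inherits(class_params, "trajectory_params"))
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1)")
  }
  set.seed(seed)
  tp <- .diary_times(days)
  b <- rnorm(1, 0, class_params$between_sd)
  latent <- class_params$intercept + class_params$slope * tp$t +
    class_params$quadratic * tp$t^2 + b +
    rnorm(nrow(tp), 0, class_params$within_noise_sd)
  total <- pmin(20, pmax(0, round(latent)))
  miss <- runif(nrow(tp)) < missing_rate
  chew <- ceiling(total / 2)
  yawn <- floor(total / 2)
  k <- nrow(tp)
  out <- tibble(
    day = rep(tp$day, each = 2),
    time = rep(tp$time, each = 2),
    activity = rep(c("chewing", "yawning"), times = k),
    score = as.vector(rbind(chew, yawn)),
    missing = rep(miss, each = 2)
  )
  out$score[out$missing] <- NA_integer_
  out
}
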