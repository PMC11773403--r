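# Pain-diary scores, trajectory matrices and imputation.

#' Combined pain score at each diary timepoint
#'
#' The primary outcome: chewing + yawning pain (0-20) per timepoint. Missing
#' when either activity score is missing (pre-imputation).
#'
#' @param diary A diary tibble (`day`, `time`, `activity`, `score`) as from
#'   [simulate_diary()] or read from the diary CSV schema.
#' @param activities The two activities to sum (default chewing, yawning).
#' @return A tibble `day`, `time`, `t` (numeric timepoint: day + 0/0.375 for
#'   10 am / 7 pm), `score` (0-20 or `NA`).
#' @export
compute_pain_scores <- function(diary, activities = c("chewing", "yawning")) {
  diary <- as_tibble(diary)
  unknown <- setdiff(activities, unique(diary$activity))
  if (length(unknown) > 0) {
    abort(paste0("activity not present in diary: ", paste(unknown, collapse = ", ")))
  }
  d <- diary[diary$activity %in% activities, ]
  t_num <- d$day + ifelse(d$time == "19:00", 0.375, 0)
  tf <- factor(t_num, levels = sort(unique(t_num)))
  # per-timepoint sum with NA propagation; NA when an activity row is absent
  per_act <- vapply(activities, function(a) {
    out <- rep(NA_real_, nlevels(tf))
    sel <- d$activity == a
    out[as.integer(tf[sel])] <- d$score[sel]
    out
  }, numeric(nlevels(tf)))
  tt <- as.numeric(levels(tf))
  first <- !duplicated(tf)
  ord <- order(t_num[first])
  tibble(
    day = d$day[first][ord], time = d$time[first][ord], t = tt,
    score = rowSums(per_act)
  )
}

#' Participant-by-timepoint trajectory matrix
#'
#' Stacks combined pain scores into a participant x timepoint matrix over a
#' day span (default days 1-7, the window when pain is most prominent; the
#' 30-day variant is used for robustness labeling).
#'
#' @param diaries List of diary tibbles, one per participant (names or
#'   positions are participant ids).
#' @param days Day span to keep (default 1:7 -> 14 twice-daily columns).
#' @return A list of class `trajectory_matrix`: `scores` (matrix, possibly
#'   with `NA`), `t` (numeric timepoints), `participant` (ids).
#' @export
trajectory_matrix <- function(diaries, days = 1:7) {
  rows <- purrr::map(diaries, function(d) {
    ps <- compute_pain_scores(d) |> filter(.data$day %in% days)
    setNames(ps$score, format(ps$t))
  })
  tgrid <- .diary_times(days)$t
  m <- do.call(rbind, purrr::map(rows, function(r) r[format(tgrid)]))
  ids <- names(diaries) %||% seq_along(diaries)
  structure(
    list(scores = unname(m), t = tgrid, participant = ids),
    class = "trajectory_matrix"
  )
}

#' Impute missing diary timepoints
#'
#' `mode = "linear_interpolate"` fills interior gaps by linear interpolation
#' over the timepoint axis and edge gaps by carrying the nearest observed
#' value; `mode = "none"` leaves missing values in place. Participants with
#' fewer than two observed timepoints are dropped with a warning (they
#' cannot be interpolated).
#'
#' @param tm A [trajectory_matrix()].
#' @param mode `"linear_interpolate"` or `"none"`.
#' @return An imputed `trajectory_matrix`.
#' @export
impute_trajectories <- function(tm, mode = c("linear_interpolate", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tm, "trajectory_matrix"))
  if (mode == "none") return(tm)
  n_obs <- rowSums(!is.na(tm$scores))
  drop <- n_obs < 2
  if (any(drop)) {
    warn(sprintf(
      "excluding %d participant(s) with fewer than 2 observed timepoints",
      sum(drop)
    ))
    tm$scores <- tm$scores[!drop, , drop = FALSE]
    tm$participant <- tm$participant[!drop]
  }
  tm$scores <- t(apply(tm$scores, 1, function(y) {
    if (!anyNA(y)) return(y)
    approx(tm$t, y, xout = tm$t, method = "linear", rule = 2)$y
  }))
  tm
}
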