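# TMS motor-map metrics: MEP amplitude extraction, map construction, active
# sites, map volume/area, facilitator/depressor classification.

#' Peak-to-peak MEP amplitude from an EMG trace
#'
#' Computes the peak-to-peak amplitude (max minus min) of an EMG trace within
#' a post-stimulus latency window.
#'
#' @param trace Numeric vector of EMG samples, mV.
#' @param sfreq Sampling rate, Hz.
#' @param stimulus_index Sample index of the TMS pulse (1-based).
#' @param latency_window Length-2 numeric, post-stimulus window in ms
#'   (default 5-50 ms, a conventional MEP window; configurable).
#' @return Amplitude in mV (0 for a flat trace).
#' @export
extract_mep_amplitude <- function(trace, sfreq, stimulus_index,
                                  latency_window = c(5, 50)) {
  if (stimulus_index < 1 || stimulus_index > length(trace)) {
    abort("`stimulus_index` must lie inside the trace")
  }
  idx <- stimulus_index + round(latency_window / 1000 * sfreq)
  if (idx[2] > length(trace) || idx[1] < 1) {
    abort(sprintf(
      "latency window [%g, %g] ms extends outside the trace (samples %d-%d of %d)",
      latency_window[1], latency_window[2], idx[1], idx[2], length(trace)
    ))
  }
  win <- trace[idx[1]:idx[2]]
  max(win) - min(win)
}

#' Build a motor map from per-site trial amplitudes
#'
#' Averages MEP amplitudes over trials at each grid site of a 1 cm-spaced
#' stimulation lattice.
#'
#' @param trials A data frame with columns `row`, `col` (integer lattice
#'   coordinates) and `amplitude` (mV, one row per trial). Duplicate site
#'   entries are merged (with a warning) by pooling their trials.
#' @param session_day Session label (0, 2 or 5).
#' @return A tibble of class `map_grid` with columns `row`, `col`,
#'   `amplitude` (per-site mean, mV) and attribute `session_day`.
#' @export
build_map <- function(trials, session_day = NA_integer_) {
  trials <- as_tibble(trials)
  req <- c("row", "col", "amplitude")
  if (!all(req %in% names(trials))) {
    abort("`trials` needs columns row, col, amplitude")
  }
  if (any(trials$amplitude < 0)) abort("MEP amplitudes must be nonnegative")
  o <- order(trials$row, trials$col)
  r <- trials$row[o]
  cl <- trials$col[o]
  a <- trials$amplitude[o]
  grp <- cumsum(!duplicated(data.frame(r, cl)))
  amp <- as.vector(rowsum(a, grp)) / tabulate(grp)
  first <- !duplicated(grp)
  map <- tibble(row = r[first], col = cl[first], amplitude = amp)
  class(map) <- c("map_grid", class(map))
  attr(map, "session_day") <- session_day
  map
}

#' Active sites of a motor map
#'
#' Default rule: a site is active when its mean MEP amplitude is at least
#' `threshold` times the map's maximum site amplitude (10%-of-max, a
#' conventional motor-mapping criterion; the study leaves the rule to its
#' supplement). An all-zero map has no active sites.
#'
#' @param map A `map_grid` from [build_map()].
#' @param threshold Fraction of the maximum site amplitude (default 0.1).
#'   `threshold = 0` marks every covered site active.
#' @return The active subset of `map` rows, as a tibble.
#' @export
active_sites <- function(map, threshold = 0.1) {
  if (nrow(map) == 0) abort("map is empty")
  mx <- max(map$amplitude)
  if (mx == 0) return(map[0, ])
  map[map$amplitude >= threshold * mx, ]
}

#' Map volume and map area
#'
#' Map volume is the sum of mean MEP amplitudes over active sites (mV·sites);
#' map area is the count of active sites.
#'
#' @inheritParams active_sites
#' @return A single number.
#' @export
map_volume <- function(map, threshold = 0.1) {
  sum(active_sites(map, threshold)$amplitude)
}

#' @rdname map_volume
#' @export
map_area <- function(map, threshold = 0.1) {
  nrow(active_sites(map, threshold))
}

#' Classify corticomotor excitability change
#'
#' Computes the day-5 minus day-0 change in a map metric and classifies the
#' participant as a facilitator (strict increase) or depressor (decrease;
#' ties count as depression — "increase" is read strictly, and the
#' non-increasing class is the risk class).
#'
#' @param map_day0,map_day5 `map_grid` objects for the two sessions.
#' @param metric `"volume"` or `"area"`.
#' @param threshold Active-site threshold passed to the metric.
#' @return A one-row tibble: `metric_day0`, `metric_day5`, `delta`,
#'   `cme_class` (`"facilitator"`/`"depressor"`), `metric`.
#' @export
classify_cme <- function(map_day0, map_day5, metric = c("volume", "area"),
                         threshold = 0.1) {
  metric <- match.arg(metric)
  if (is.null(map_day0) || is.null(map_day5)) {
    abort("both day-0 and day-5 maps are required")
  }
  fn <- if (metric == "volume") map_volume else map_area
  m0 <- fn(map_day0, threshold)
  m5 <- fn(map_day5, threshold)
  delta <- m5 - m0
  tibble(
    metric = metric, metric_day0 = m0, metric_day5 = m5, delta = delta,
    cme_class = if (delta > 0) "facilitator" else "depressor"
  )
}

#' Normalise a motor map
#'
#' Expresses each site amplitude as a percentage of the maximum site
#' amplitude (maximum site = 100). Idempotent up to scale.
#'
#' @param map A `map_grid`.
#' @return A `map_grid` with amplitudes in [0, 100].
#' @export
normalize_map <- function(map) {
  mx <- max(map$amplitude)
  if (mx <= 0) abort("cannot normalise an all-zero map")
  map$amplitude <- 100 * map$amplitude / mx
  map
}
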