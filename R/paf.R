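# Peak alpha frequency estimation: component-space and sensor-ROI pathways.

# Indices of strict local maxima of a numeric vector (interior points).
.local_maxima <- function(p) {
  n <- length(p)
  if (n < 3) return(integer(0))
  which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] > p[3:n]) + 1L
}

# Prominence of a local maximum inside a window: height above the higher of
# the two flanking minima (window-bounded).
.prominence <- function(p, i) {
  left <- if (i > 1) min(p[1:(i - 1)]) else p[i]
  right <- if (i < length(p)) min(p[(i + 1):length(p)]) else p[i]
  p[i] - max(left, right)
}

#' Estimate peak alpha frequency from a power spectrum
#'
#' Two estimators over a frequency window: `"peak"` returns the frequency of
#' the highest local maximum inside the window (absent, with a QC flag, when
#' no interior local maximum exists); `"cog"` returns the spectral centre of
#' gravity, `sum(f * P(f)) / sum(P(f))` over the window bins. Both are
#' invariant to overall spectral scaling.
#'
#' @param spectrum A `power_spectrum` tibble (single channel/component, or
#'   use `channel` to pick one).
#' @param window Length-2 numeric, frequency window in Hz (default
#'   `c(8, 12)`; the 9-11 Hz variant is used in robustness analyses).
#' @param method `"cog"` (default, robust to plateau peaks) or `"peak"`.
#' @param channel Which channel/component of `spectrum` to use; defaults to
#'   the only one present.
#' @return A one-row tibble of class `paf_estimate`: `paf` (Hz, `NA` when no
#'   qualifying peak), `method`, `window_low`, `window_high`, `source`,
#'   `source_id`, `qc_flag`.
#' @export
estimate_paf <- function(spectrum, window = c(8, 12), method = c("cog", "peak"),
                         channel = NULL) {
  method <- match.arg(method)
  spectrum <- as_power_spectrum(spectrum)
  if (is.null(channel)) {
    chans <- unique(spectrum$channel)
    if (length(chans) != 1) {
      abort("`spectrum` has several channels; pick one with `channel`")
    }
    channel <- chans
  }
  sp <- spectrum[spectrum$channel == channel, ]
  if (length(window) != 2 || diff(window) <= 0) {
    abort("`window` must be an increasing length-2 interval")
  }
  inside <- sp$freq >= window[1] & sp$freq <= window[2]
  if (!any(inside)) abort("`window` contains no spectrum bins (empty window)")
  f <- sp$freq[inside]
  p <- sp$power[inside]
  qc <- NA_character_
  if (method == "cog") {
    if (sum(p) <= 0) {
      paf <- NA_real_
      qc <- "zero_power_in_window"
    } else {
      paf <- sum(f * p) / sum(p)
    }
  } else {
    lm <- .local_maxima(p)
    if (length(lm) == 0) {
      paf <- NA_real_
      qc <- "no_local_maximum_in_window"
    } else {
      paf <- f[lm[which.max(p[lm])]]
    }
  }
  out <- tibble(
    paf = paf, method = method,
    window_low = window[1], window_high = window[2],
    source = "spectrum", source_id = as.character(channel), qc_flag = qc
  )
  class(out) <- c("paf_estimate", class(out))
  out
}

#' Select the sensorimotor alpha component
#'
#' Ranks components by a combined score: rank of alpha-peak prominence
#' (within `window`) plus rank of topography similarity (cosine similarity
#' between the absolute component topography and a sensorimotor spatial
#' template). Components whose best alpha local maximum has prominence below
#' `prominence_floor` times the windowed power range do not qualify. Ties on
#' the combined rank go to the higher alpha prominence.
#'
#' @param decomp A [decompose_components()] result.
#' @param spectra Per-component spectra from [component_spectra()] (computed
#'   if omitted).
#' @param template Named channel weight vector; default
#'   [sensorimotor_template()] over the decomposition's channels.
#' @param window Alpha window in Hz.
#' @param prominence_floor Fraction of the windowed power range a peak's
#'   prominence must exceed to count as a "clear" alpha peak.
#' @param rel_height Additionally, the peak must rise to at least this
#'   multiple of the local background (the linear interpolation between the
#'   window-edge powers at the peak frequency); rejects the shallow wiggles
#'   of a peakless aperiodic spectrum.
#' @return A list: `component` (id such as `"IC3"`, or `NA` with
#'   `qc_flag = "no_alpha_component"`), and a `scores` tibble with one row
#'   per component (`prominence`, `similarity`, ranks, `qualifies`).
#' @export
select_sensorimotor_component <- function(decomp, spectra = NULL,
                                          template = NULL,
                                          window = c(8, 12),
                                          prominence_floor = 0.05,
                                          rel_height = 1.5) {
  stopifnot(inherits(decomp, "component_decomposition"))
  spectra <- spectra %||% component_spectra(decomp)
  if (is.null(template)) {
    if (is.null(decomp$channel_labels)) {
      abort("channel labels/positions are required for topography scoring")
    }
    template <- sensorimotor_template(decomp$channel_labels)
  }
  ncomp <- nrow(decomp$unmixing)
  ids <- paste0("IC", seq_len(ncomp))
  if (!all(ids %in% unique(spectra$channel))) {
    abort("`spectra` is not aligned with the decomposition")
  }
  rows <- purrr::map(seq_len(ncomp), function(j) {
    sp <- spectra[spectra$channel == ids[j], ]
    inside <- sp$freq >= window[1] & sp$freq <= window[2]
    p <- sp$power[inside]
    f <- sp$freq[inside]
    lm <- .local_maxima(p)
    rng <- diff(range(p))
    if (length(lm) == 0 || rng == 0) {
      prom <- 0
      pk <- NA_real_
      qual <- FALSE
    } else {
      proms <- vapply(lm, function(i) .prominence(p, i), numeric(1))
      best <- which.max(proms)
      prom <- proms[best]
      pk <- f[lm[best]]
      # local background trend: least-squares line over the window bins,
      # evaluated at the peak (robust to single-bin dips)
      fit <- lm(p ~ f)
      baseline <- unname(coef(fit)[1] + coef(fit)[2] * f[lm[best]])
      qual <- prom > prominence_floor * rng &&
        p[lm[best]] > rel_height * max(baseline, 0)
    }
    topo <- abs(decomp$topographies[, j])
    sim <- sum(topo * template) / sqrt(sum(topo^2) * sum(template^2))
    tibble(
      component = ids[j], alpha_peak = pk, prominence = prom,
      similarity = sim, qualifies = qual
    )
  })
  scores <- list_rbind(rows)
  scores$prominence_rank <- rank(scores$prominence, ties.method = "average")
  scores$similarity_rank <- rank(scores$similarity, ties.method = "average")
  scores$combined <- scores$prominence_rank + scores$similarity_rank
  if (!any(scores$qualifies)) {
    return(list(component = NA_character_, qc_flag = "no_alpha_component",
                scores = scores))
  }
  q <- scores[scores$qualifies, ]
  q <- q[order(-q$combined, -q$prominence), ]
  list(component = q$component[1], qc_flag = NA_character_, scores = scores)
}

#' Sensor-ROI peak alpha frequency
#'
#' Averages the spectra of a region of interest (mean power across ROI
#' channels per frequency bin), then applies [estimate_paf()].
#'
#' @param spectrum A multi-channel `power_spectrum`.
#' @param roi_labels Channel labels defining the ROI; must all be present.
#' @inheritParams estimate_paf
#' @return A `paf_estimate` tibble with `source = "sensor_roi"`.
#' @export
sensor_roi_paf <- function(spectrum, roi_labels = sensorimotor_channels(),
                           window = c(8, 12), method = c("cog", "peak")) {
  method <- match.arg(method)
  spectrum <- as_power_spectrum(spectrum)
  missing <- setdiff(roi_labels, unique(spectrum$channel))
  if (length(missing) > 0) {
    abort(paste0("ROI label(s) not in spectrum: ", paste(missing, collapse = ", ")))
  }
  roi <- spectrum[spectrum$channel %in% roi_labels, ]
  nf <- length(unique(roi$freq))
  # channels share one frequency grid (sorted channel-major), so the ROI
  # mean is a row mean of the reshaped power matrix
  pw <- matrix(roi$power, nrow = nf)
  avg <- tibble(channel = "roi_mean", freq = roi$freq[seq_len(nf)],
                power = rowMeans(pw))
  est <- estimate_paf(as_power_spectrum(avg), window = window, method = method)
  est$source <- "sensor_roi"
  est$source_id <- paste(roi_labels, collapse = ",")
  est
}

#' Full PAF pathway from a raw recording
#'
#' Preprocesses the recording, then estimates sensorimotor PAF either in
#' component space (ICA + alpha/topography component selection, the primary
#' pathway) or from a sensor ROI average.
#'
#' @param recording An [eeg_recording()].
#' @param source `"component"` or `"roi"`.
#' @param window,method Passed to [estimate_paf()].
#' @param roi_labels ROI for the sensor pathway.
#' @param n_components,ica_seed Component pathway controls.
#' @param preprocess Apply [preprocess_eeg()] first (default TRUE).
#' @return A `paf_estimate` tibble.
#' @export
paf_from_recording <- function(recording, source = c("component", "roi"),
                               window = c(8, 12), method = c("cog", "peak"),
                               roi_labels = sensorimotor_channels(),
                               n_components = NULL, ica_seed = 1,
                               preprocess = TRUE) {
  source <- match.arg(source)
  method <- match.arg(method)
  if (source == "roi") {
    keep <- match(roi_labels, recording$channel_labels)
    if (anyNA(keep)) {
      abort(paste0("ROI label(s) not in recording: ",
                   paste(roi_labels[is.na(keep)], collapse = ", ")))
    }
    rec <- eeg_recording(
      recording$data[keep, , drop = FALSE], recording$sfreq,
      recording$channel_labels[keep]
    )
    if (preprocess) rec <- preprocess_eeg(rec)
    spec <- compute_spectrum(rec)
    return(sensor_roi_paf(spec, roi_labels, window, method))
  }
  if (preprocess) recording <- preprocess_eeg(recording)
  decomp <- decompose_components(recording, n_components = n_components,
                                 seed = ica_seed)
  spectra <- component_spectra(decomp)
  # the "clear alpha peak" selection criterion always refers to the full
  # alpha band; `window` only varies the estimation
  sel <- select_sensorimotor_component(decomp, spectra, window = c(8, 12))
  if (is.na(sel$component)) {
    out <- tibble(
      paf = NA_real_, method = method, window_low = window[1],
      window_high = window[2], source = "component",
      source_id = NA_character_, qc_flag = sel$qc_flag
    )
    class(out) <- c("paf_estimate", class(out))
    return(out)
  }
  est <- estimate_paf(spectra, window = window, method = method,
                      channel = sel$component)
  est$source <- "component"
  est$source_id <- sel$component
  est
}
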