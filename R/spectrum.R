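# Resting EEG container and Welch spectral estimation.

#' Construct an EEG recording
#'
#' Bundles a channels-by-samples matrix with its sampling rate and channel
#' labels into an `eeg_recording` object, the input type of the PAF pathway.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param sfreq Sampling frequency in Hz.
#' @param channel_labels Character vector, one unique label per row of `data`.
#' @param channel_positions Optional data frame with columns `channel`, `x`,
#'   `y` giving planar scalp coordinates. Defaults to [standard_montage()]
#'   rows matching `channel_labels`, where available.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channel_labels,
                          channel_positions = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data)) {
    abort("`data` must be a numeric matrix without NA")
  }
  if (length(channel_labels) != nrow(data)) {
    abort("`channel_labels` must have one entry per channel (row)")
  }
  if (anyDuplicated(channel_labels)) abort("`channel_labels` must be unique")
  if (!is.numeric(sfreq) || length(sfreq) != 1 || sfreq <= 0) {
    abort("`sfreq` must be a positive scalar")
  }
  if (is.null(channel_positions)) {
    mon <- standard_montage()
    channel_positions <- mon[mon$channel %in% channel_labels, ]
  }
  structure(
    list(
      data = data, sfreq = sfreq,
      channel_labels = as.character(channel_labels),
      channel_positions = channel_positions
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq
  ))
  invisible(x)
}

#' Minimal EEG preprocessing
#'
#' De-means each channel and applies a zero-phase band-pass (default
#' 1-40 Hz): the squared-magnitude response of an order-`order` Butterworth
#' band-pass, applied in the frequency domain (the same amplitude response
#' as a forward-backward time-domain filter, with no phase distortion).
#' Deliberately minimal: the PAF measure is robust to light preprocessing.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band edges in Hz.
#' @param order Butterworth order.
#' @return A filtered `eeg_recording`.
#' @export
preprocess_eeg <- function(recording, low = 1, high = 40, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  ny <- recording$sfreq / 2
  if (high >= ny) abort("`high` must be below the Nyquist frequency")
  x <- recording$data - rowMeans(recording$data)
  n <- ncol(x)
  nfft <- stats::nextn(n, 2)
  f <- .fft_freqs(nfft, recording$sfreq)
  f_safe <- pmax(f, 1e-6)
  h2 <- (1 / (1 + (low / f_safe)^(2 * order))) *
    (1 / (1 + (f_safe / high)^(2 * order)))
  xp <- rbind(t(x), matrix(0, nfft - n, nrow(x)))
  ft <- mvfft(xp) * h2
  recording$data <- t(Re(mvfft(ft, inverse = TRUE)) / nfft)[, seq_len(n),
                                                            drop = FALSE]
  recording
}

#' Welch power spectral density
#'
#' Segment-averaged periodogram (Welch's method) per channel: Hann-tapered
#' segments, de-meaned, with configurable overlap. One-sided density
#' normalisation, so a stationary signal's band power is the integral of the
#' returned density.
#'
#' @param recording An [eeg_recording()], or a plain numeric vector together
#'   with `sfreq`.
#' @param segment_seconds Segment length in seconds; frequency resolution is
#'   `1/segment_seconds` (default 4 s -> 0.25 Hz).
#' @param overlap Fractional overlap between consecutive segments.
#' @param sfreq Sampling rate, required when `recording` is a bare vector.
#' @return A tibble of class `power_spectrum` with columns `channel`, `freq`
#'   (Hz, ascending), `power` (uV^2/Hz).
#' @export
compute_spectrum <- function(recording, segment_seconds = 4, overlap = 0.5,
                             sfreq = NULL) {
  if (inherits(recording, "eeg_recording")) {
    x <- recording$data
    sfreq <- recording$sfreq
    labels <- recording$channel_labels
  } else if (is.numeric(recording)) {
    if (is.null(sfreq)) abort("`sfreq` is required for a bare numeric input")
    x <- matrix(recording, nrow = 1)
    labels <- "signal"
  } else {
    abort("`recording` must be an eeg_recording or numeric vector")
  }
  nseg <- round(segment_seconds * sfreq)
  n <- ncol(x)
  if (n < 2 * nseg) {
    abort(sprintf(
      "recording too short for Welch estimation: need >= %d samples (2 segments of %g s), got %d",
      2 * nseg, segment_seconds, n
    ))
  }
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1)) # Hann
  u <- sum(w^2)
  nf <- nseg %/% 2 + 1L
  freqs <- (seq_len(nf) - 1L) * sfreq / nseg
  spec <- matrix(0, nrow(x), nf)
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, w, `*`)
    ft <- t(mvfft(t(seg)))[, seq_len(nf), drop = FALSE]
    p <- (Mod(ft)^2) / (sfreq * u)
    # one-sided: double everything except DC (and Nyquist when nseg even)
    p[, -1] <- 2 * p[, -1]
    if (nseg %% 2 == 0) p[, nf] <- p[, nf] / 2
    spec <- spec + p
  }
  spec <- spec / length(starts)
  out <- tibble(
    channel = rep(labels, each = nf),
    freq = rep(freqs, times = nrow(x)),
    power = as.vector(t(spec))
  )
  class(out) <- c("power_spectrum", class(out))
  attr(out, "resolution") <- sfreq / nseg
  out
}

# Coerce a (freq, power[, channel]) data frame into a power_spectrum tibble.
as_power_spectrum <- function(df) {
  df <- as_tibble(df)
  if (!all(c("freq", "power") %in% names(df))) {
    abort("a spectrum needs `freq` and `power` columns")
  }
  if (!"channel" %in% names(df)) df$channel <- "signal"
  if (any(df$power < 0)) abort("spectral power must be nonnegative")
  ord <- order(df$channel, df$freq)
  if (is.unsorted(ord)) df <- df[ord, ]
  class(df) <- unique(c("power_spectrum", class(df)))
  df
}
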