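# Seeded symmetric fixed-point ICA (tanh contrast) with PCA reduction.
# Used to isolate the sensorimotor alpha component from multichannel EEG.

#' Independent component decomposition of an EEG recording
#'
#' PCA-whitens the channel data and runs symmetric fixed-point ICA with a
#' tanh contrast, returning the unmixing matrix, component time series and
#' component topographies (columns of the mixing matrix). Deterministic for
#' a given seed. The decomposition satisfies the reconstruction identity
#' `unmixing %*% data == component_timeseries` exactly.
#'
#' @param recording An [eeg_recording()], ideally after [preprocess_eeg()].
#' @param n_components Number of components to extract (default
#'   `min(20, n_channels)`); PCA keeps the leading directions first.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param seed Seed for the random orthonormal start.
#' @return A list of class `component_decomposition` with elements
#'   `unmixing` (components x channels), `timeseries` (components x samples,
#'   unit variance), `topographies` (channels x components),
#'   `channel_labels`, `converged`.
#' @export
decompose_components <- function(recording, n_components = NULL,
                                 max_iter = 100, tol = 1e-4, seed = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$data
  nch <- nrow(x)
  n_components <- n_components %||% min(20L, nch)
  if (n_components > nch) abort("cannot extract more components than channels")
  x <- x - rowMeans(x)
  cv <- tcrossprod(x) / ncol(x)
  eig <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_components)
  d <- eig$values[keep]
  d[d < .Machine$double.eps] <- .Machine$double.eps
  E <- eig$vectors[, keep, drop = FALSE]
  wh <- diag(1 / sqrt(d), n_components) %*% t(E) # whitening (comp x chan)
  z <- wh %*% x

  set.seed(seed)
  # deflationary one-unit fixed-point iteration with Gram-Schmidt
  # orthogonalisation: extracts the most non-Gaussian directions first and
  # converges per unit even when the remaining subspace is near-Gaussian
  n_samp <- ncol(z)
  w <- matrix(0, n_components, n_components)
  n_conv <- 0L
  it_total <- 0L
  for (j in seq_len(n_components)) {
    wj <- rnorm(n_components)
    if (j > 1) {
      prev <- w[seq_len(j - 1), , drop = FALSE]
      wj <- drop(wj - crossprod(prev, prev %*% wj))
    }
    wj <- wj / sqrt(sum(wj^2))
    for (it in seq_len(max_iter)) {
      it_total <- it_total + 1L
      u <- drop(wj %*% z)
      g <- tanh(u)
      wn <- drop(z %*% g) / n_samp - mean(1 - g^2) * wj
      if (j > 1) {
        prev <- w[seq_len(j - 1), , drop = FALSE]
        wn <- drop(wn - crossprod(prev, prev %*% wn))
      }
      nrm <- sqrt(sum(wn^2))
      if (nrm < 1e-12) break
      wn <- wn / nrm
      done <- abs(abs(sum(wn * wj)) - 1) < tol
      wj <- wn
      if (done) {
        n_conv <- n_conv + 1L
        break
      }
    }
    w[j, ] <- wj
  }
  converged <- n_conv == n_components
  it <- it_total
  unmix <- w %*% wh # components x channels
  ts <- unmix %*% x # unit variance by construction of whitening
  # mixing (topographies): pseudo-inverse through the PCA basis
  mix <- E %*% diag(sqrt(d), n_components) %*% t(w) # channels x components
  structure(
    list(
      unmixing = unmix, timeseries = ts, topographies = mix,
      channel_labels = recording$channel_labels, sfreq = recording$sfreq,
      converged = converged, n_iter = it
    ),
    class = "component_decomposition"
  )
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf(
    "<component_decomposition> %d components from %d channels (%s)\n",
    nrow(x$unmixing), length(x$channel_labels),
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' Per-component power spectra
#'
#' Welch spectra of each component time series of a decomposition.
#'
#' @param decomp A [decompose_components()] result.
#' @inheritParams compute_spectrum
#' @return A `power_spectrum` tibble whose `channel` column holds component
#'   ids (`"IC1"`, `"IC2"`, ...).
#' @export
component_spectra <- function(decomp, segment_seconds = 4, overlap = 0.5) {
  stopifnot(inherits(decomp, "component_decomposition"))
  rec <- eeg_recording(
    decomp$timeseries, decomp$sfreq,
    paste0("IC", seq_len(nrow(decomp$timeseries)))
  )
  compute_spectrum(rec, segment_seconds, overlap)
}
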