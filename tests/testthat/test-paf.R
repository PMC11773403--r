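# PAF estimators, component selection and the two estimation pathways.

test_that("centre of gravity matches hand-computed and brute-force weighted means", {
  # hand example: P = {9: 1, 10: 2, 11: 1} -> (9 + 20 + 11) / 4 = 10
  sp <- make_spectrum(c(9, 10, 11), c(1, 2, 1))
  expect_equal(estimate_paf(sp, method = "cog")$paf, 10)
  # brute-force oracle on arbitrary random spectra
  set.seed(1)
  for (i in 1:25) {
    freq <- seq(0, 40, by = 0.25)
    power <- runif(length(freq))
    sp <- make_spectrum(freq, power)
    w <- c(8, 12)
    est <- estimate_paf(sp, window = w, method = "cog")$paf
    inside <- freq >= w[1] & freq <= w[2]
    oracle <- sum(freq[inside] * power[inside]) / sum(power[inside])
    expect_equal(est, oracle, tolerance = 1e-10)
  }
})

test_that("point-mass and symmetric spectra give exact estimates for both methods", {
  freq <- seq(8, 12, by = 0.25)
  point <- ifelse(freq == 10, 5, 0)
  sp <- make_spectrum(freq, point)
  expect_equal(estimate_paf(sp, method = "cog")$paf, 10)
  expect_equal(estimate_paf(sp, method = "peak")$paf, 10)
  sym <- dnorm(freq, 10, 0.8)
  expect_equal(estimate_paf(make_spectrum(freq, sym), method = "cog")$paf, 10)
})

test_that("estimates are invariant to overall spectral scaling", {
  set.seed(3)
  freq <- seq(1, 40, by = 0.25)
  power <- runif(length(freq)) + dnorm(freq, 10.3, 0.5)
  for (m in c("cog", "peak")) {
    a <- estimate_paf(make_spectrum(freq, power), method = m)$paf
    b <- estimate_paf(make_spectrum(freq, power * 1000), method = m)$paf
    expect_equal(a, b)
  }
})

test_that("peak method flags spectra with no local maximum; empty window errors", {
  freq <- seq(8, 12, by = 0.5)
  mono <- rev(seq_along(freq)) # strictly decreasing: no interior maximum
  est <- estimate_paf(make_spectrum(freq, mono), method = "peak")
  expect_true(is.na(est$paf))
  expect_equal(est$qc_flag, "no_local_maximum_in_window")
  expect_error(estimate_paf(make_spectrum(freq, mono), window = c(20, 21)),
               "empty window")
})

test_that("sensor-ROI PAF reduces to the single-channel estimate and rejects unknown labels", {
  freq <- seq(1, 40, by = 0.25)
  set.seed(4)
  power <- runif(length(freq)) + dnorm(freq, 9.7, 0.5)
  multi <- corticomark:::as_power_spectrum(dplyr::bind_rows(
    tibble::tibble(channel = "C3", freq = freq, power = power),
    tibble::tibble(channel = "C4", freq = freq, power = power)
  ))
  single <- estimate_paf(make_spectrum(freq, power), method = "cog")$paf
  expect_equal(sensor_roi_paf(multi, "C3")$paf, single)
  # identical spectra in the ROI: mean equals any member
  expect_equal(sensor_roi_paf(multi, c("C3", "C4"))$paf, single)
  expect_error(sensor_roi_paf(multi, c("C3", "XX9")), "XX9")
})

test_that("component selection picks the alpha component and flags its absence", {
  # constructed decomposition: component 2 carries a 10 Hz peak with central
  # topography; components 1 and 3 are noise
  labels <- standard_montage()$channel
  tmpl <- sensorimotor_template(labels)
  set.seed(5)
  topo <- cbind(rnorm(63), tmpl + rnorm(63, 0, 0.05), rnorm(63))
  decomp <- structure(
    list(unmixing = matrix(0, 3, 63), timeseries = NULL, topographies = topo,
         channel_labels = labels, sfreq = 125),
    class = "component_decomposition"
  )
  freq <- seq(0, 40, by = 0.25)
  flat <- rep(1, length(freq))
  alpha <- flat + 8 * dnorm(freq, 10, 0.5)
  spectra <- corticomark:::as_power_spectrum(dplyr::bind_rows(
    tibble::tibble(channel = "IC1", freq = freq, power = flat),
    tibble::tibble(channel = "IC2", freq = freq, power = alpha),
    tibble::tibble(channel = "IC3", freq = freq, power = flat)
  ))
  sel <- select_sensorimotor_component(decomp, spectra)
  expect_equal(sel$component, "IC2")

  no_alpha <- corticomark:::as_power_spectrum(dplyr::bind_rows(
    tibble::tibble(channel = "IC1", freq = freq, power = flat),
    tibble::tibble(channel = "IC2", freq = freq, power = flat),
    tibble::tibble(channel = "IC3", freq = freq, power = flat)
  ))
  sel2 <- select_sensorimotor_component(decomp, no_alpha)
  expect_true(is.na(sel2$component))
  expect_equal(sel2$qc_flag, "no_alpha_component")
})

test_that("between qualifying components, ranks decide and prominence breaks ties", {
  labels <- standard_montage()$channel
  tmpl <- sensorimotor_template(labels)
  occ <- numeric(63)
  occ[grep("^O|^PO", labels)] <- 1
  freq <- seq(0, 40, by = 0.25)
  flat <- rep(1, length(freq))
  peak <- function(a) flat + a * dnorm(freq, 10, 0.5)
  mk_decomp <- function(topo) structure(
    list(unmixing = matrix(0, ncol(topo), 63), timeseries = NULL,
         topographies = topo, channel_labels = labels, sfreq = 125),
    class = "component_decomposition"
  )
  mk_spectra <- function(powers) corticomark:::as_power_spectrum(
    dplyr::bind_rows(lapply(seq_along(powers), function(i) {
      tibble::tibble(channel = paste0("IC", i), freq = freq,
                     power = powers[[i]])
    }))
  )
  # dominant on both criteria -> must win under any monotone rank combination
  sel <- select_sensorimotor_component(
    mk_decomp(cbind(tmpl, occ)), mk_spectra(list(peak(10), peak(6)))
  )
  expect_equal(sel$component, "IC1")
  # equal topography ranks (identical topographies): higher prominence wins
  sel2 <- select_sensorimotor_component(
    mk_decomp(cbind(tmpl, tmpl)), mk_spectra(list(peak(6), peak(10)))
  )
  expect_equal(sel2$component, "IC2")
  # identical spectra (prominence tie): topography decides
  sel3 <- select_sensorimotor_component(
    mk_decomp(cbind(occ, tmpl)), mk_spectra(list(peak(8), peak(8)))
  )
  expect_equal(sel3$component, "IC2")
})

test_that("planted PAF is recovered by the component pathway and tracks the ROI pathway", {
  p <- fast_eeg()
  planted <- c(8.5, 9.5, 10.5, 11.5, 9, 10, 11, 9.8)
  ests <- vapply(seq_along(planted), function(i) {
    rec <- simulate_eeg(planted[i], p, seed = 100 + i)
    c(paf_from_recording(rec, source = "component")$paf,
      paf_from_recording(rec, source = "roi")$paf)
  }, numeric(2))
  expect_true(all(abs(ests[1, ] - planted) <= 0.2))
  expect_gt(cor(ests[1, ], ests[2, ]), 0.8)
  expect_gt(cor(ests[2, ], planted), 0.8)
})

test_that("a recording with no alpha oscillation yields no qualifying component", {
  # background-only recording: 1/f noise, no shared alpha source
  set.seed(11)
  n <- 120 * 125
  nfft <- stats::nextn(n, 2)
  f <- corticomark:::.fft_freqs(nfft, 125)
  amp <- pmax(f, 1)^(-0.5)
  amp[1] <- 0
  z <- corticomark:::.synth_spectra(nfft, 63, amp)
  x <- t(Re(mvfft(z, inverse = TRUE)) / nfft)[, 1:n]
  rec <- eeg_recording(x, 125, standard_montage()$channel)
  est <- paf_from_recording(rec, source = "component")
  expect_true(is.na(est$paf))
  expect_equal(est$qc_flag, "no_alpha_component")
})

test_that("ICA decomposition satisfies the reconstruction identity and is seeded", {
  p <- eeg_sim_params(duration = 30, sfreq = 125)
  rec <- preprocess_eeg(simulate_eeg(10, p, seed = 9))
  d1 <- decompose_components(rec, n_components = 10, seed = 3)
  d2 <- decompose_components(rec, n_components = 10, seed = 3)
  expect_identical(d1$unmixing, d2$unmixing)
  x <- rec$data - rowMeans(rec$data)
  expect_equal(d1$unmixing %*% x, d1$timeseries, tolerance = 1e-10)
  expect_lte(nrow(d1$unmixing), nrow(rec$data))
})
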