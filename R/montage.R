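# 63-channel 10-10 montage with approximate planar coordinates.
#
# Coordinates are derived from the label grammar (row letter block -> y,
# digit + hemisphere -> x) and are approximate: they preserve the relative
# geometry of the extended 10-20 layout, which is all the topography scoring
# uses (cosine similarity against a spatial template). They are not digitised
# electrode positions.

.row_y <- c(
  Fp = 1.0, AF = 0.8, F = 0.6, FT = 0.4, FC = 0.4, T = 0.0, C = 0.0,
  TP = -0.4, CP = -0.4, P = -0.6, PO = -0.8, O = -1.0
)

.parse_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) == 0) abort(paste0("unparseable channel label: ", label))
  list(row = m[2], pos = m[3])
}

#' Standard 63-channel montage
#'
#' Returns the default 63-label extended 10-20 montage with approximate
#' planar scalp coordinates (nose up, left negative x).
#'
#' @return A tibble with columns `channel`, `x`, `y`.
#' @export
standard_montage <- function() {
  cached <- .corticomark_cache$montage
  if (!is.null(cached)) return(cached)
  labels <- c(
    "Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2", "FT9", "FT10", "Fpz"
  )
  stopifnot(length(labels) == 63L, !anyDuplicated(labels))
  coords <- purrr::map(labels, function(lab) {
    p <- .parse_label(lab)
    y <- .row_y[[p$row]]
    if (identical(p$pos, "z")) {
      x <- 0
    } else {
      d <- as.integer(p$pos)
      # lateral ring index: 1,3,5,7,9 left; 2,4,6,8,10 right
      ring <- ceiling(d / 2)
      # temporal labels (T7/T8, FT9/FT10 etc.) sit on outer rings
      if (p$row %in% c("T", "TP", "FT") && d %in% c(7L, 8L)) ring <- 4
      x <- 0.25 * ring * if (d %% 2 == 1L) -1 else 1
    }
    tibble(channel = lab, x = x, y = y)
  })
  out <- list_rbind(coords)
  .corticomark_cache$montage <- out
  out
}

.corticomark_cache <- new.env(parent = emptyenv())

#' Default sensorimotor channel set
#'
#' Left-central electrodes overlying sensorimotor cortex, used as the default
#' sensor region of interest and to anchor the sensorimotor topography
#' template (the study stimulated left M1 and recorded the right masseter).
#'
#' @return Character vector of channel labels.
#' @export
sensorimotor_channels <- function() {
  c("C3", "C1", "C5", "FC3", "FC1", "CP3", "CP1")
}

#' Sensorimotor topography template
#'
#' A per-channel spatial weight vector peaking over left sensorimotor cortex:
#' a Gaussian in planar montage coordinates centred midway between C3 and CP3.
#' Used as the fixed template for component topography scoring.
#'
#' @param channels Character vector of channel labels (subset of
#'   [standard_montage()]).
#' @param sigma Gaussian spatial scale in montage units.
#' @return Named numeric vector of nonnegative weights, one per channel.
#' @export
sensorimotor_template <- function(channels = standard_montage()$channel,
                                  sigma = 0.35) {
  mon <- standard_montage()
  missing <- setdiff(channels, mon$channel)
  if (length(missing) > 0) {
    abort(paste0("unknown channel label(s): ", paste(missing, collapse = ", ")))
  }
  mon <- mon[match(channels, mon$channel), ]
  c3 <- standard_montage()
  ctr <- colMeans(c3[c3$channel %in% c("C3", "CP3"), c("x", "y")])
  w <- exp(-((mon$x - ctr[["x"]])^2 + (mon$y - ctr[["y"]])^2) / (2 * sigma^2))
  setNames(w, channels)
}
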