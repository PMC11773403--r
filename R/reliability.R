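# Test-retest reliability: two-way random-effects absolute-agreement ICC
# and Cohen's kappa for session-to-session class agreement.

.icc_band <- function(icc) {
  dplyr::case_when(
    is.na(icc) ~ NA_character_,
    icc < 0.5 ~ "poor",
    icc < 0.75 ~ "moderate",
    icc < 0.9 ~ "good",
    TRUE ~ "excellent"
  )
}

#' Intraclass correlation across sessions
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC — the
#' conventional test-retest form, ICC(A,1) in the McGraw-Wong taxonomy —
#' computed from the two-way ANOVA mean squares, with a 95% CI from the
#' F-distribution bounds. Rows with missing cells are dropped listwise with
#' a warning.
#'
#' @param measurements Numeric matrix or data frame, subjects x sessions
#'   (>= 5 subjects, >= 2 sessions).
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble of class `reliability_report`: `icc`, `ci_low`,
#'   `ci_high`, `band` (poor < 0.5, moderate 0.5-0.75, good 0.75-0.9,
#'   excellent > 0.9), `n_subjects`, `n_sessions`, `qc_flag`.
#' @export
icc <- function(measurements, conf = 0.95) {
  m <- as.matrix(measurements)
  cc <- complete.cases(m)
  if (!all(cc)) {
    warn(sprintf("dropping %d subject(s) with missing sessions", sum(!cc)))
    m <- m[cc, , drop = FALSE]
  }
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) abort("need at least 2 sessions")
  if (n < 5) abort("need at least 5 subjects")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1) # between-subject
  msc <- n * sum((col_m - grand)^2) / (k - 1) # between-session
  mse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps && mse <= .Machine$double.eps) {
    out <- tibble(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  band = NA_character_, n_subjects = n, n_sessions = k,
                  qc_flag = "zero_between_subject_variance")
    class(out) <- c("reliability_report", class(out))
    return(out)
  }
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  est <- (msr - mse) / denom
  # McGraw & Wong (1996) CI for ICC(A,1)
  alpha <- 1 - conf
  if (mse <= .Machine$double.eps) {
    lo <- hi <- est # degenerate perfect agreement
  } else {
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_star <- qf(1 - alpha / 2, n - 1, v)
    lo <- n * (msr - f_star * mse) /
      (f_star * (k * msc + (k * n - k - n) * mse) + n * msr)
    f_star2 <- qf(1 - alpha / 2, v, n - 1)
    hi <- n * (f_star2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_star2 * msr)
  }
  out <- tibble(
    icc = est, ci_low = lo, ci_high = hi, band = .icc_band(est),
    n_subjects = n, n_sessions = k, qc_flag = NA_character_
  )
  class(out) <- c("reliability_report", class(out))
  out
}

#' Session-to-session class agreement
#'
#' Cohen's kappa and raw percent agreement between paired categorical
#' classifications (e.g. day-2 vs day-5 facilitator/depressor calls). Kappa
#' is undefined (reported `NA` with a flag) when both sessions observe a
#' single common category.
#'
#' @param classes_a,classes_b Paired classification vectors.
#' @return A one-row tibble: `kappa`, `percent_agreement`, `n`, `qc_flag`.
#' @export
class_agreement <- function(classes_a, classes_b) {
  stopifnot(length(classes_a) == length(classes_b))
  keep <- !is.na(classes_a) & !is.na(classes_b)
  a <- as.character(classes_a[keep])
  b <- as.character(classes_b[keep])
  n <- length(a)
  if (n == 0) abort("no complete pairs")
  levels <- sort(unique(c(a, b)))
  po <- mean(a == b)
  if (length(levels) < 2) {
    return(tibble(kappa = NA_real_, percent_agreement = 100 * po, n = n,
                  qc_flag = "single_category"))
  }
  ta <- table(factor(a, levels), factor(b, levels))
  pe <- sum(rowSums(ta) * colSums(ta)) / n^2
  kap <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  tibble(kappa = kap, percent_agreement = 100 * po, n = n,
         qc_flag = if (is.na(kap)) "degenerate_marginals" else NA_character_)
}

#' PAF test-retest reliability on a synthetic cohort
#'
#' Estimates each participant's PAF independently on the day-0, day-2 and
#' day-5 recordings (same planted PAF, independent noise) and returns the
#' ICC across sessions.
#'
#' @param cohort A [generate_cohort()] result with `eeg_days = c(0, 2, 5)`.
#' @param ... PAF pathway options passed to [paf_from_recording()].
#' @return A list: `report` (the [icc()] tibble), `measurements` (wide
#'   tibble participant x session).
#' @export
paf_reliability <- function(cohort, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  days <- names(cohort$recordings[[1]])
  if (length(days) < 2) abort("cohort needs at least two EEG sessions")
  m <- purrr::map(cohort$recordings, function(recs) {
    vapply(recs, function(r) paf_from_recording(r, ...)$paf, numeric(1))
  })
  wide <- do.call(rbind, m)
  list(report = icc(wide),
       measurements = as_tibble(wide) |>
         mutate(participant = seq_len(nrow(wide)), .before = 1))
}
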