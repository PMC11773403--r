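# ROC/AUC with bootstrap confidence intervals, performance bands and the
# Youden-optimal probability threshold.

.auc_band <- function(auc) {
  dplyr::case_when(
    auc >= 0.9 ~ "outstanding",
    auc >= 0.8 ~ "excellent",
    auc >= 0.7 ~ "acceptable",
    TRUE ~ "below"
  )
}

# Rank-formula AUC with ties counted one half.
.auc <- function(scores, positive) {
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' AUC is the probability a randomly chosen positive outscores a randomly
#' chosen negative, ties counting one half (the rank/Mann-Whitney formula).
#' The 95% CI is a stratified percentile bootstrap (resampling positives and
#' negatives separately). AUC bands: 0.7-0.8 acceptable, 0.8-0.9 excellent,
#' 0.9-1.0 outstanding.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Class labels; `positive` names the positive class.
#' @param positive Positive class value (default `"high"`).
#' @param n_boot Bootstrap resamples (default 2000); `0` skips the CI.
#' @param conf Confidence level.
#' @param seed Bootstrap seed.
#' @return An object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `band`, `points` (tibble `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = "high", n_boot = 2000,
                    conf = 0.95, seed = 1) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  pos <- labels == positive
  if (all(pos) || !any(pos)) {
    abort("both classes must be present to compute a ROC curve")
  }
  auc <- .auc(scores, pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- tibble(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)))
  )
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    ip <- which(pos)
    ineg <- which(!pos)
    bauc <- vapply(seq_len(n_boot), function(b) {
      bp <- sample(ip, length(ip), replace = TRUE)
      bn <- sample(ineg, length(ineg), replace = TRUE)
      s <- c(scores[bp], scores[bn])
      .auc(s, c(rep(TRUE, length(bp)), rep(FALSE, length(bn))))
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(bauc, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(
    list(
      auc = auc, ci_low = ci[1], ci_high = ci[2], band = .auc_band(auc),
      points = arrange(pts, .data$fpr, .data$tpr),
      n_pos = sum(pos), n_neg = sum(!pos)
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f (95%% CI %.3f-%.3f), %s; %d positive / %d negative\n",
    x$auc, x$ci_low, x$ci_high, x$band, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high, band = x$band,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' Youden-optimal probability threshold
#'
#' Scans candidate thresholds (the unique scores) and returns the one
#' maximising Youden's J = sensitivity + specificity - 1, classifying
#' `score >= threshold` as positive. Ties are resolved to the smallest
#' threshold achieving the maximum.
#'
#' @inheritParams roc_auc
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
optimal_threshold <- function(scores, labels, positive = "high") {
  pos <- labels == positive
  if (all(pos) || !any(pos)) abort("both classes must be present")
  cand <- sort(unique(scores))
  stats <- purrr::map(cand, function(t) {
    pred <- scores >= t
    tibble(
      threshold = t,
      sensitivity = mean(pred[pos]),
      specificity = mean(!pred[!pos])
    )
  }) |> list_rbind() |>
    mutate(youden_j = .data$sensitivity + .data$specificity - 1)
  best <- stats[stats$youden_j == max(stats$youden_j), ]
  best[1, ] # smallest threshold among maximisers
}
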