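# Two-class growth mixture model for pain trajectories: class-specific
# quadratic mean trajectories, shared participant random intercept and
# residual variance, fitted by EM over (class, random intercept) latents so
# every update is closed-form and the observed-data log-likelihood is
# nondecreasing.

.design_matrix <- function(t) cbind(1, t, t^2)

# Compound-symmetry log density pieces for one class, vectorised over
# participants with a common timepoint grid. R: residual matrix (n x T).
.cs_loglik <- function(R, sigma2, tau2) {
  T_ <- ncol(R)
  rs <- rowSums(R)
  rss <- rowSums(R^2)
  denom <- sigma2 + T_ * tau2
  qf <- (rss - tau2 * rs^2 / denom) / sigma2
  ll <- -0.5 * (T_ * log(2 * pi) + (T_ - 1) * log(sigma2) + log(denom) + qf)
  list(ll = ll, rs = rs)
}

# One EM run from given responsibilities. Y: n x T complete matrix.
.em_run <- function(Y, X, w, max_iter, tol) {
  n <- nrow(Y)
  T_ <- ncol(Y)
  K <- ncol(w)
  XtX_inv_Xt <- solve(crossprod(X)) %*% t(X)
  # init from hard/soft responsibilities with b = 0
  beta <- sapply(seq_len(K), function(k) {
    ybar <- colSums(Y * w[, k]) / sum(w[, k])
    XtX_inv_Xt %*% ybar
  })
  resid0 <- Y - t(X %*% beta[, max.col(w), drop = FALSE])
  # crude variance split: between = var of participant means, within = rest
  pm <- rowMeans(resid0)
  tau2 <- max(var(pm), 1e-3)
  sigma2 <- max(mean((resid0 - pm)^2), 1e-3)
  pi_k <- colMeans(w)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step
    comp <- vector("list", K)
    logd <- matrix(0, n, K)
    for (k in seq_len(K)) {
      R <- Y - matrix(X %*% beta[, k], n, T_, byrow = TRUE)
      comp[[k]] <- .cs_loglik(R, sigma2, tau2)
      logd[, k] <- comp[[k]]$ll + log(pi_k[k])
    }
    m <- apply(logd, 1, max)
    ll <- sum(m + log(rowSums(exp(logd - m))))
    ll_trace <- c(ll_trace, ll)
    w <- exp(logd - m)
    w <- w / rowSums(w)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    # M-step
    denom <- sigma2 + T_ * tau2
    V <- tau2 * sigma2 / denom
    Eb <- sapply(seq_len(K), function(k) tau2 * comp[[k]]$rs / denom)
    pi_k <- colMeans(w)
    sse <- 0
    eb2 <- 0
    beta_new <- beta
    for (k in seq_len(K)) {
      adj <- Y - Eb[, k]
      wk <- w[, k]
      ybar <- colSums(adj * wk) / sum(wk)
      beta_new[, k] <- XtX_inv_Xt %*% ybar
      Rk <- adj - matrix(X %*% beta_new[, k], n, T_, byrow = TRUE)
      sse <- sse + sum(wk * (rowSums(Rk^2) + T_ * V))
      eb2 <- eb2 + sum(wk * (Eb[, k]^2 + V))
    }
    beta <- beta_new
    sigma2 <- max(sse / (n * T_), 1e-8)
    tau2 <- max(eb2 / n, 0)
  }
  list(beta = beta, sigma2 = sigma2, tau2 = tau2, pi = pi_k, posterior = w,
       loglik = ll, loglik_trace = ll_trace, converged = it < max_iter)
}

#' Fit a two-class growth mixture model
#'
#' Fits a finite mixture of quadratic mean trajectories (per class) with a
#' shared participant random intercept and homoscedastic residuals by EM,
#' taking the best of `n_starts` seeded starts (k-means-initialised
#' responsibilities first, random responsibilities thereafter). The class
#' with the larger area under its mean trajectory is anchored as the
#' "high" pain-sensitive class.
#'
#' @param tm A [trajectory_matrix()], complete (impute first with
#'   [impute_trajectories()]) — participants with any missing timepoint are
#'   dropped with a warning.
#' @param n_classes Number of classes (currently fixed at 2).
#' @param n_starts Number of EM starts (default 50).
#' @param seed Seed for start initialisation.
#' @param max_iter,tol EM controls; convergence when the log-likelihood
#'   change falls below `tol`.
#' @return An object of class `gmm_fit`: class coefficients, `sigma`
#'   (residual SD), `tau` (random-intercept SD), mixing proportions,
#'   `posterior` tibble (participant, `p_high`), `loglik`, `loglik_trace`
#'   (best start), `n_starts_converged`, `degenerate` flag.
#' @export
fit_gmm <- function(tm, n_classes = 2, n_starts = 50, seed = 1,
                    max_iter = 300, tol = 1e-6) {
  stopifnot(inherits(tm, "trajectory_matrix"))
  if (n_classes != 2) abort("only the 2-class model is implemented")
  Y <- tm$scores
  keep <- complete.cases(Y)
  if (!all(keep)) {
    warn(sprintf("dropping %d participant(s) with missing timepoints; impute first to keep them",
                 sum(!keep)))
    Y <- Y[keep, , drop = FALSE]
  }
  ids <- tm$participant[keep]
  n <- nrow(Y)
  if (n < 4 * n_classes) abort("need at least 4 participants per putative class")
  if (length(tm$t) < 5) abort("need at least polynomial order + 2 timepoints")
  X <- .design_matrix(tm$t)

  set.seed(seed)
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    w <- matrix(0, n, n_classes)
    if (s == 1) {
      km <- kmeans(Y, centers = n_classes, nstart = 5)
      w[cbind(seq_len(n), km$cluster)] <- 1
    } else {
      w[cbind(seq_len(n), sample.int(n_classes, n, replace = TRUE))] <- 1
      w <- 0.8 * w + 0.2 / n_classes
    }
    runs[[s]] <- tryCatch(.em_run(Y, X, w, max_iter, tol),
                          error = function(e) NULL)
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) abort("no EM start converged; check the trajectory matrix")
  lls <- vapply(runs[ok], function(r) r$loglik, numeric(1))
  best <- runs[ok][[which.max(lls)]]

  # anchor "high" = larger area under the mean trajectory (trapezoid)
  tt <- tm$t
  auc_k <- apply(best$beta, 2, function(b) {
    mu <- .design_matrix(tt) %*% b
    sum(diff(tt) * (head(mu, -1) + tail(mu, -1)) / 2)
  })
  hi <- which.max(auc_k)
  lo <- setdiff(1:2, hi)
  # degenerate when a class is (nearly) empty or the classes are
  # indistinguishable (no participant assigned with any confidence)
  degenerate <- min(best$pi) < 2 / n ||
    diff(range(best$posterior[, hi])) < 0.05

  out <- structure(
    list(
      coefficients = tibble(
        class = c("high", "low"),
        intercept = best$beta[1, c(hi, lo)],
        slope = best$beta[2, c(hi, lo)],
        quadratic = best$beta[3, c(hi, lo)]
      ),
      sigma = sqrt(best$sigma2), tau = sqrt(best$tau2),
      mixing = setNames(best$pi[c(hi, lo)], c("high", "low")),
      posterior = tibble(participant = ids, p_high = best$posterior[, hi]),
      loglik = best$loglik, loglik_trace = best$loglik_trace,
      n_starts_converged = sum(vapply(runs[ok], function(r) r$converged,
                                      logical(1))),
      degenerate = degenerate, t = tt, n = n
    ),
    class = "gmm_fit"
  )
  if (degenerate) {
    warn("degenerate fit: a class is nearly empty or the classes are indistinguishable")
  }
  out
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "<gmm_fit> 2 classes, n = %d, loglik = %.2f, sigma = %.2f, tau = %.2f\n",
    x$n, x$loglik, x$sigma, x$tau
  ))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.gmm_fit <- function(x, ...) x$coefficients

#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(
    loglik = x$loglik, sigma = x$sigma, tau = x$tau,
    mixing_high = x$mixing[["high"]], n = x$n,
    n_starts_converged = x$n_starts_converged, degenerate = x$degenerate
  )
}

#' Posterior class probabilities for new trajectories
#'
#' E-step of a fitted (possibly locked) growth mixture model applied to a
#' new trajectory matrix: returns each participant's posterior probability
#' of the high-pain-sensitive class under the frozen parameters.
#'
#' @param fit A [fit_gmm()] result.
#' @param tm A complete [trajectory_matrix()] on the same timepoint grid.
#' @return A tibble `participant`, `p_high`.
#' @export
gmm_posterior <- function(fit, tm) {
  stopifnot(inherits(fit, "gmm_fit"), inherits(tm, "trajectory_matrix"))
  if (length(tm$t) != length(fit$t) || any(tm$t != fit$t)) {
    abort("trajectory matrix timepoints do not match the fitted model")
  }
  Y <- tm$scores
  keep <- complete.cases(Y)
  if (!all(keep)) {
    warn(sprintf("dropping %d participant(s) with missing timepoints", sum(!keep)))
    Y <- Y[keep, , drop = FALSE]
  }
  X <- .design_matrix(tm$t)
  beta <- rbind(
    t(as.matrix(fit$coefficients[, c("intercept", "slope", "quadratic")]))
  )
  sigma2 <- fit$sigma^2
  tau2 <- fit$tau^2
  logd <- sapply(1:2, function(k) {
    R <- Y - matrix(X %*% beta[, k], nrow(Y), ncol(Y), byrow = TRUE)
    .cs_loglik(R, sigma2, tau2)$ll + log(fit$mixing[[k]])
  })
  logd <- matrix(logd, nrow = nrow(Y))
  m <- apply(logd, 1, max)
  w <- exp(logd - m)
  w <- w / rowSums(w)
  tibble(participant = tm$participant[keep], p_high = w[, 1])
}

#' Label training participants by posterior rank and lock the rule
#'
#' Orders training participants by posterior probability of the high class;
#' the top `n_extreme` are labeled high, the bottom `n_extreme` low, and the
#' middle left unlabeled. The locked rule records the posterior of the
#' rank-`n_extreme` participant from each end as inclusive thresholds. Ties
#' straddling a rank cut are broken by enrollment order (stable sort).
#'
#' @param posterior A tibble (`participant`, `p_high`) from [fit_gmm()]'s
#'   `$posterior` or [gmm_posterior()].
#' @param n_extreme Number labeled at each end (default 40).
#' @return A list: `labels` (tibble `participant`, `p_high`, `label` with
#'   `NA` for unlabeled) and `rule` (class `label_rule`: `tau_high`,
#'   `tau_low`, `locked = TRUE`).
#' @export
assign_training_labels <- function(posterior, n_extreme = 40) {
  posterior <- as_tibble(posterior)
  n <- nrow(posterior)
  if (n < 2 * n_extreme) {
    abort(sprintf("need at least 2 * n_extreme = %d participants, got %d",
                  2 * n_extreme, n))
  }
  ord <- order(-posterior$p_high, seq_len(n)) # stable: enrollment order
  lab <- rep(NA_character_, n)
  lab[ord[seq_len(n_extreme)]] <- "high"
  lab[ord[(n - n_extreme + 1):n]] <- "low"
  tau_high <- posterior$p_high[ord[n_extreme]]
  tau_low <- posterior$p_high[ord[n - n_extreme + 1]]
  rule <- structure(
    list(tau_high = tau_high, tau_low = tau_low, class_anchor = "high",
         n_extreme = n_extreme, locked = TRUE),
    class = "label_rule"
  )
  list(
    labels = mutate(posterior, label = lab),
    rule = rule
  )
}

#' Apply a locked label rule to test-set posteriors
#'
#' Labels high when the posterior is at or above `tau_high`, low when at or
#' below `tau_low`, and leaves participants between the thresholds
#' unlabeled. Refuses to run on an unlocked rule.
#'
#' @param posterior A tibble (`participant`, `p_high`).
#' @param rule A locked `label_rule` from [assign_training_labels()].
#' @return The posterior tibble with a `label` column (`NA` = unlabeled).
#' @export
apply_locked_labels <- function(posterior, rule) {
  if (!inherits(rule, "label_rule") || !isTRUE(rule$locked)) {
    abort("label rule must be locked before labeling a test set (audit)")
  }
  p <- posterior$p_high
  lab <- dplyr::case_when(
    p >= rule$tau_high ~ "high",
    p <= rule$tau_low ~ "low",
    TRUE ~ NA_character_
  )
  mutate(as_tibble(posterior), label = lab)
}
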