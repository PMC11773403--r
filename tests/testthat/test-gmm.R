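# Pain scores, trajectory matrices, imputation and the growth mixture model.

test_that("combined pain score is the chewing + yawning sum with NA propagation", {
  d <- tibble::tibble(
    day = c(1, 1, 1, 1, 2, 2),
    time = c("10:00", "10:00", "19:00", "19:00", "10:00", "10:00"),
    activity = c("chewing", "yawning", "chewing", "yawning", "chewing", "yawning"),
    score = c(3, 2, 0, 0, 10, 10),
    missing = FALSE
  )
  ps <- compute_pain_scores(d)
  expect_equal(ps$score, c(5, 0, 20))
  expect_equal(ps$t, c(1, 1.375, 2))
  # missing one activity -> missing timepoint
  d$score[1] <- NA
  expect_true(is.na(compute_pain_scores(d)$score[1]))
  expect_error(compute_pain_scores(d, activities = c("chewing", "running")),
               "running")
})

test_that("imputation fills interior gaps linearly and edges by carry-over", {
  diaries <- list(a = simulate_diary(default_trajectory_classes()$low,
                                     missing_rate = 0, seed = 1))
  tm <- trajectory_matrix(diaries, days = 1:3)
  # plant: interior gap at t2 between 2 and 4; leading gap
  tm$scores <- matrix(c(2, NA, 4, 6, 8, 10,
                        NA, NA, 3, 3, 3, 3), 2, 6, byrow = TRUE)
  tm$t <- c(1, 2, 3, 4, 5, 6)
  tm$participant <- c("a", "b")
  imp <- impute_trajectories(tm)
  expect_equal(imp$scores[1, 2], 3) # linear midpoint
  expect_equal(imp$scores[2, 1:2], c(3, 3)) # carried back
  # complete rows unchanged under both modes
  full <- matrix(1:6, 1)
  tm2 <- structure(list(scores = full, t = tm$t, participant = "c"),
                   class = "trajectory_matrix")
  expect_equal(impute_trajectories(tm2)$scores, full)
  expect_equal(impute_trajectories(tm2, mode = "none")$scores, full)
  # under-observed participants are dropped with a warning
  tm3 <- tm
  tm3$scores[2, ] <- c(5, NA, NA, NA, NA, NA)
  expect_warning(out <- impute_trajectories(tm3), "fewer than 2")
  expect_equal(out$participant, "a")
})

test_that("noise-free distinct constant trajectories separate perfectly", {
  t_ <- .diary_times_vec <- c(1, 1.375, 2, 2.375, 3, 3.375)
  y <- rbind(
    matrix(10, 6, 6), matrix(2, 6, 6)
  ) + matrix(rnorm(72, 0, 1e-3), 12, 6)
  tm <- structure(list(scores = y, t = t_, participant = 1:12),
                  class = "trajectory_matrix")
  fit <- fit_gmm(tm, n_starts = 5, seed = 1)
  expect_true(all(fit$posterior$p_high[1:6] > 0.999))
  expect_true(all(fit$posterior$p_high[7:12] < 0.001))
  co <- fit$coefficients
  mu_high <- co$intercept[1] + co$slope[1] * t_ + co$quadratic[1] * t_^2
  mu_low <- co$intercept[2] + co$slope[2] * t_ + co$quadratic[2] * t_^2
  expect_equal(mean(mu_high), 10, tolerance = 0.01)
  expect_equal(mean(mu_low), 2, tolerance = 0.01)
})

test_that("EM log-likelihood is nondecreasing and posteriors sum to one", {
  sim <- two_class_diaries(n = 40, seed = 3)
  tm <- impute_trajectories(trajectory_matrix(sim$diaries))
  fit <- fit_gmm(tm, n_starts = 5, seed = 2)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(all(fit$posterior$p_high >= 0 & fit$posterior$p_high <= 1))
  expect_true(is.finite(fit$loglik))
  expect_equal(sum(fit$mixing), 1)
})

test_that("well-separated planted classes are recovered across seeds (ARI >= 0.9)", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:5, function(s) {
    sim <- two_class_diaries(n = 60, seed = s, sep_sd = 4)
    tm <- impute_trajectories(trajectory_matrix(sim$diaries))
    fit <- fit_gmm(tm, n_starts = 8, seed = s)
    ari(ifelse(fit$posterior$p_high > 0.5, "high", "low"), sim$truth)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("identical trajectories trigger the degenerate-class warning", {
  y <- matrix(5, 12, 6) + matrix(rnorm(72, 0, 1e-6), 12, 6)
  tm <- structure(list(scores = y, t = c(1, 1.375, 2, 2.375, 3, 3.375),
                       participant = 1:12),
                  class = "trajectory_matrix")
  expect_warning(fit_gmm(tm, n_starts = 3, seed = 1), "degenerate")
})

test_that("posterior-rank labeling yields 80 labeled of 100 with locked thresholds", {
  set.seed(4)
  post <- tibble::tibble(participant = 1:100, p_high = runif(100))
  al <- assign_training_labels(post, n_extreme = 40)
  expect_equal(sum(al$labels$label == "high", na.rm = TRUE), 40)
  expect_equal(sum(al$labels$label == "low", na.rm = TRUE), 40)
  expect_equal(sum(is.na(al$labels$label)), 20)
  sorted <- sort(post$p_high, decreasing = TRUE)
  expect_equal(al$rule$tau_high, sorted[40])
  expect_equal(al$rule$tau_low, sorted[61])
  expect_true(al$rule$locked)
  # all-or-nothing posteriors, 50/50: thresholds {1, 0}
  post2 <- tibble::tibble(participant = 1:80, p_high = rep(c(1, 0), 40))
  al2 <- assign_training_labels(post2, n_extreme = 40)
  expect_equal(unname(c(al2$rule$tau_high, al2$rule$tau_low)), c(1, 0))
  expect_equal(sum(is.na(al2$labels$label)), 0)
  # n_extreme = n/2 labels everyone
  al3 <- assign_training_labels(post, n_extreme = 50)
  expect_equal(sum(is.na(al3$labels$label)), 0)
  expect_error(assign_training_labels(post[1:70, ], 40), "at least")
})

test_that("labels are invariant to participant ordering up to the tie rule", {
  set.seed(5)
  post <- tibble::tibble(participant = 1:100, p_high = round(runif(100), 2))
  al <- assign_training_labels(post, 40)
  perm <- sample(100)
  al_p <- assign_training_labels(post[perm, ], 40)
  merged <- dplyr::left_join(al$labels, al_p$labels, by = "participant")
  # identical posteriors may swap at the cut; thresholds must agree exactly
  expect_equal(al$rule$tau_high, al_p$rule$tau_high)
  expect_equal(al$rule$tau_low, al_p$rule$tau_low)
  ties_high <- sum(post$p_high == al$rule$tau_high) > 1
  ties_low <- sum(post$p_high == al$rule$tau_low) > 1
  if (!ties_high && !ties_low) {
    expect_identical(merged$label.x, merged$label.y)
  }
})

test_that("locked label rule labels by threshold and refuses unlocked rules", {
  rule <- structure(list(tau_high = 0.8, tau_low = 0.2, locked = TRUE),
                    class = "label_rule")
  post <- tibble::tibble(participant = 1:5,
                         p_high = c(0.9, 0.8, 0.5, 0.2, 0.1))
  lab <- apply_locked_labels(post, rule)
  expect_equal(lab$label, c("high", "high", NA, "low", "low"))
  unlocked <- rule
  unlocked$locked <- FALSE
  expect_error(apply_locked_labels(post, unlocked), "locked")
})

test_that("7-day and 30-day labelings agree on persistent planted classes", {
  sim <- two_class_diaries(n = 60, seed = 11, sep_sd = 4)
  lab_for <- function(days) {
    tm <- impute_trajectories(trajectory_matrix(sim$diaries, days = days))
    fit <- fit_gmm(tm, n_starts = 8, seed = 1)
    al <- assign_training_labels(fit$posterior, n_extreme = 24)
    al$labels$label
  }
  l7 <- lab_for(1:7)
  l30 <- lab_for(1:30)
  both <- !is.na(l7) & !is.na(l30)
  expect_gte(mean(l7[both] == l30[both]), 0.8)
})
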