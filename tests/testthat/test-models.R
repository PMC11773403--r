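# ROC/AUC, threshold derivation, nested CV, locking and blinded prediction.

make_features <- function(n = 80, seed = 1, signal = TRUE, covariates = FALSE) {
  set.seed(seed)
  label <- rep(c("high", "low"), length.out = n)
  paf <- ifelse(label == "high", 9.5, 10.5) + rnorm(n, 0, 0.5)
  cme <- rbinom(n, 1, ifelse(label == "high", 0.25, 0.75))
  if (!signal) {
    paf <- rnorm(n, 10, 0.7)
    cme <- rbinom(n, 1, 0.5)
  }
  out <- tibble::tibble(
    participant = seq_len(n), set = "train", paf_hz = paf, cme_class = cme,
    label = label
  )
  if (covariates) {
    out$sex <- sample(c("female", "male"), n, TRUE)
    out$pcs_total <- round(runif(n, 0, 40))
    out$pcs_helplessness <- round(out$pcs_total * 0.4 + runif(n, 0, 5))
  }
  out
}

test_that("AUC matches the O(n^2) pairwise concordance oracle, with ties", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
    labels <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("high", "low")
    pos <- which(labels == "high")
    neg <- which(labels == "low")
    pairs <- expand.grid(p = pos, q = neg)
    oracle <- mean(ifelse(scores[pairs$p] > scores[pairs$q], 1,
                          ifelse(scores[pairs$p] == scores[pairs$q], 0.5, 0)))
    expect_equal(roc_auc(scores, labels, n_boot = 0)$auc, oracle,
                 tolerance = 1e-12)
  }
})

test_that("AUC boundary cases: perfect separation, constant scores, single class", {
  r <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c("high", "high", "low", "low"),
               n_boot = 0)
  expect_equal(r$auc, 1)
  expect_equal(r$band, "outstanding")
  expect_equal(roc_auc(rep(0.5, 10), rep(c("high", "low"), 5), n_boot = 0)$auc,
               0.5)
  expect_error(roc_auc(runif(5), rep("high", 5)), "both classes")
})

test_that("AUC agrees with pROC and the bootstrap CI brackets the estimate", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- runif(60)
  labels <- ifelse(runif(60) < plogis(4 * scores - 2), "high", "low")
  if (length(unique(labels)) < 2) labels[1:2] <- c("high", "low")
  ours <- roc_auc(scores, labels, n_boot = 500, seed = 1)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              levels = c("low", "high"))))
  expect_equal(ours$auc, as.numeric(ref), tolerance = 1e-12)
  expect_lte(ours$ci_low, ours$auc)
  expect_gte(ours$ci_high, ours$auc)
  # ROC points are monotone nondecreasing
  expect_true(all(diff(ours$points$fpr) >= 0))
  expect_true(all(diff(ours$points$tpr) >= 0))
})

test_that("Youden threshold matches exhaustive search and its boundary cases", {
  # hand-built 4-point instance
  scores <- c(0.1, 0.4, 0.6, 0.9)
  labels <- c("low", "low", "high", "high")
  th <- optimal_threshold(scores, labels)
  expect_equal(th$threshold, 0.6)
  expect_equal(th$sensitivity, 1)
  expect_equal(th$specificity, 1)
  expect_equal(th$youden_j, 1)
  # exhaustive-search oracle on random instances
  set.seed(22)
  for (i in 1:30) {
    sc <- round(runif(20), 2)
    lb <- sample(c("high", "low"), 20, TRUE)
    if (length(unique(lb)) < 2) lb[1:2] <- c("high", "low")
    th <- optimal_threshold(sc, lb)
    cand <- sort(unique(sc))
    js <- vapply(cand, function(t) {
      pred <- sc >= t
      mean(pred[lb == "high"]) + mean(!pred[lb == "low"]) - 1
    }, numeric(1))
    expect_equal(th$youden_j, max(js), tolerance = 1e-12)
    expect_equal(th$threshold, cand[which.max(js)]) # smallest maximiser
  }
  # random scores: J near zero on average
  set.seed(23)
  js <- replicate(40, {
    sc <- runif(40)
    lb <- rep(c("high", "low"), 20)
    optimal_threshold(sc, lb)$youden_j
  })
  expect_lt(mean(js), 0.35)
})

test_that("internal CV partitions 80 labeled rows into 64/16 with four folds of 16", {
  feats <- make_features(80, seed = 2)
  cv <- internal_cv(feats, families = "logistic_regression", seed = 3)
  expect_equal(sum(cv$partition$role == "validation"), 16)
  expect_equal(sum(cv$partition$role == "internal"), 64)
  internal_folds <- table(cv$partition$fold[cv$partition$role == "internal"])
  expect_equal(unname(as.vector(internal_folds)), rep(16, 4))
  # non-multiple sizes fall back to near-equal folds (difference <= 1)
  cv72 <- internal_cv(make_features(72), families = "logistic_regression",
                      seed = 1)
  sizes <- table(cv72$partition$fold)
  expect_lte(diff(range(sizes)), 1)
  expect_error(internal_cv(make_features(8), seed = 1), "at least")
})

test_that("perfectly separable features give validation AUC 1 for every family", {
  feats <- make_features(80, seed = 4)
  feats$paf_hz <- ifelse(feats$label == "high", 8.5, 11.5) # huge margin
  feats$cme_class <- as.integer(feats$label == "low")
  cv <- internal_cv(feats, seed = 5)
  expect_true(all(cv$summary$validation_auc == 1))
})

test_that("label-permuted features yield chance-level validation AUC", {
  aucs <- vapply(1:20, function(s) {
    feats <- make_features(80, seed = 100 + s, signal = FALSE)
    cv <- internal_cv(feats, families = "logistic_regression", seed = s)
    cv$summary$validation_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("model selection locks the best family, preferring parsimony on ties", {
  feats <- make_features(80, seed = 6)
  cv <- internal_cv(feats, seed = 7)
  model <- select_and_lock(cv)
  expect_s3_class(model, "locked_model")
  expect_true(model$locked)
  expect_equal(model$validation_auc, max(cv$summary$validation_auc))
  # forced tie: every family at AUC 1 -> logistic regression (fewest params)
  sep <- make_features(80, seed = 8)
  sep$paf_hz <- ifelse(sep$label == "high", 8.5, 11.5)
  cv2 <- internal_cv(sep, seed = 9)
  expect_equal(select_and_lock(cv2)$family, "logistic_regression")
  # single family: that family locked
  cv3 <- internal_cv(feats, families = "svm", seed = 10)
  expect_equal(select_and_lock(cv3)$family, "svm")
})

test_that("planted effects recover the published sign convention", {
  # high = positive class, facilitator = 1: slower PAF and depression in the
  # high class force both coefficients negative
  feats <- make_features(80, seed = 11)
  cv <- internal_cv(feats, families = "logistic_regression", seed = 12)
  model <- select_and_lock(cv)
  expect_lt(model$parameters[["paf_hz"]], 0)
  expect_lt(model$parameters[["cme_class"]], 0)
})

test_that("locked models are immutable: tampering is detected, standardization is frozen", {
  feats <- make_features(80, seed = 13)
  cv <- internal_cv(feats, families = "logistic_regression", seed = 14)
  model <- select_and_lock(cv)
  tampered <- model
  tampered$probability_threshold <- 0.99
  expect_error(predict_locked(tampered, feats), "integrity")
  # standardization constants come from training data only: re-deriving them
  # from test data must change nothing (they are frozen inside the model)
  test_feats <- make_features(40, seed = 15)
  s1 <- predict_locked(model, test_feats)
  shifted <- dplyr::mutate(test_feats, paf_hz = paf_hz + 5)
  s2 <- predict_locked(model, shifted)
  expect_false(isTRUE(all.equal(s1, s2))) # shifts propagate: no re-centring
  expect_equal(predict_locked(model, test_feats), s1)
})

test_that("blinded prediction un-shuffles truth correctly and is row-exchangeable", {
  feats <- make_features(80, seed = 16)
  cv <- internal_cv(feats, families = "logistic_regression", seed = 17)
  model <- select_and_lock(cv)
  test_feats <- make_features(38, seed = 18)
  truth <- test_feats$label
  set.seed(19)
  perm <- sample(38)
  shuffled <- truth[perm]
  pred <- predict_blinded(model, test_feats, shuffled, perm, n_boot = 100,
                          seed = 1)
  # scoring must compare each participant's prediction to their own label:
  # an aligned (identity-permutation) scoring gives the same AUC
  aligned <- predict_blinded(model, test_feats, truth, seq_len(38),
                             n_boot = 0)
  expect_equal(pred$roc$auc, aligned$roc$auc)
  # per-participant scores do not depend on row order
  rperm <- sample(38)
  pred2 <- predict_blinded(model, test_feats[rperm, ], truth[rperm],
                           seq_len(38), n_boot = 0)
  reord <- pred2$scores[match(pred$scores$participant,
                              pred2$scores$participant), ]
  expect_equal(reord$score, pred$scores$score)
  # a perfect predictor scores AUC 1 and the outstanding band
  sep <- make_features(38, seed = 20)
  sep$paf_hz <- ifelse(sep$label == "high", 8.2, 11.8)
  cvs <- internal_cv(make_features(80, seed = 21) |>
                       dplyr::mutate(paf_hz = ifelse(label == "high", 8.2, 11.8)),
                     families = "logistic_regression", seed = 22)
  ms <- select_and_lock(cvs)
  ps <- predict_blinded(ms, sep, sep$label, seq_len(38), n_boot = 0)
  expect_equal(ps$roc$auc, 1)
  expect_equal(ps$roc$band, "outstanding")
})

test_that("coin-flip scores stay inside the binomial null band", {
  set.seed(23)
  aucs <- replicate(50, {
    labels <- c(rep("high", 24), rep("low", 14))
    roc_auc(runif(38), labels, n_boot = 0)$auc
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
  expect_lt(max(abs(aucs - 0.5)), 0.35)
})

test_that("raw-Hz cutoffs invert the logistic boundary exactly", {
  feats <- make_features(80, seed = 24)
  cv <- internal_cv(feats, families = "logistic_regression", seed = 25)
  model <- select_and_lock(cv)
  cuts <- paf_cutoffs(model)
  expect_equal(cuts$cme_class, c("facilitator", "depressor"))
  # algebraic oracle: depressor - facilitator cutoff = (b_cme/b_paf) * sd(paf)
  b <- model$parameters
  s <- model$standardization
  sd_paf <- s$sd[s$feature == "paf_hz"]
  expect_equal(cuts$cutoff_hz[2] - cuts$cutoff_hz[1],
               (b[["cme_class"]] / b[["paf_hz"]]) * sd_paf,
               tolerance = 1e-10)
  # fixpoint: a participant exactly at the cutoff sits on the boundary
  tau <- model$probability_threshold
  for (i in 1:2) {
    at_cut <- tibble::tibble(paf_hz = cuts$cutoff_hz[i],
                             cme_class = 2 - i) # facilitator=1 then 0
    expect_equal(predict_locked(model, at_cut), tau, tolerance = 1e-10)
  }
  # with both coefficients negative the facilitator cutoff is lower
  expect_lt(cuts$cutoff_hz[1], cuts$cutoff_hz[2])
  expect_equal(cuts$direction[1], "less_than")
})

test_that("covariate selection keeps biomarkers and drops independent covariates", {
  feats <- make_features(80, seed = 26, covariates = TRUE)
  cm <- covariate_model(feats, p_threshold = 0.01, seed = 27)
  expect_true(all(c("paf_hz", "cme_class") %in% cm$selected))
  expect_false(any(c("pcs_total", "pcs_helplessness") %in% cm$selected))
  expect_equal(cm$selected, unique(cm$selected))
  # duplicated candidate columns are deduplicated
  cm2 <- covariate_model(feats,
                         candidate_cols = c("paf_hz", "paf_hz", "cme_class"),
                         p_threshold = 0.01, seed = 28)
  expect_equal(sum(cm2$selected == "paf_hz"), 1)
  # nothing survives an impossible threshold -> biomarker fallback + warning
  expect_warning(
    cm3 <- covariate_model(feats, p_threshold = 1e-300, seed = 29),
    "falling back"
  )
  expect_setequal(cm3$selected, c("paf_hz", "cme_class"))
})

test_that("locked logistic models round-trip through JSON", {
  feats <- make_features(80, seed = 30)
  cv <- internal_cv(feats, families = "logistic_regression", seed = 31)
  model <- select_and_lock(cv)
  path <- withr::local_tempfile(fileext = ".json")
  write_locked_model(model, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$family, "logistic_regression")
  expect_equal(js$probability_threshold, model$probability_threshold)
  expect_equal(unlist(js$coefficients[["paf_hz"]]),
               unname(model$parameters[["paf_hz"]]), tolerance = 1e-12)
})
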