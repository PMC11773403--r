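# Candidate classifier families, nested internal cross-validation, locked
# model selection, blinded test prediction and raw-unit cutoffs.

.family_order <- c(
  "logistic_regression", "svm", "neural_network", "gradient_boosting",
  "random_forest"
) # parsimony order for validation-AUC ties

.default_hyper_grids <- function() {
  list(
    logistic_regression = tibble(.dummy = 1),
    random_forest = expand_grid(mtry = c(1, 2), num_trees = 300),
    gradient_boosting = expand_grid(max_depth = c(1, 2), nrounds = c(50, 100),
                                    eta = 0.3),
    svm = tibble(cost = c(0.1, 1, 10)),
    neural_network = expand_grid(size = c(2, 4), decay = c(0.5, 0.1))
  )
}

# Standardisation constants for continuous columns, from training data only.
.standardizer <- function(df, continuous) {
  stats <- purrr::map(continuous, function(cl) {
    tibble(feature = cl, mean = mean(df[[cl]]), sd = sd(df[[cl]]))
  }) |> list_rbind()
  stats$sd[stats$sd == 0] <- 1
  stats
}

.apply_standardizer <- function(df, std) {
  for (i in seq_len(nrow(std))) {
    cl <- std$feature[i]
    df[[cl]] <- (df[[cl]] - std$mean[i]) / std$sd[i]
  }
  df
}

# Encode features numerically: sex -> female = 1.
.encode_features <- function(df, feature_cols) {
  if ("sex" %in% feature_cols && !is.numeric(df$sex)) {
    df$sex <- as.integer(df$sex == "female")
  }
  df[, feature_cols, drop = FALSE]
}

.fit_family <- function(family, x, y, hyper, seed) {
  # y: integer 0/1 (1 = high pain sensitive, the positive class)
  set.seed(seed)
  df <- bind_cols(x, .y = y)
  switch(family,
    logistic_regression = glm(.y ~ ., data = df, family = binomial()),
    random_forest = ranger::ranger(
      x = x, y = factor(y, levels = 0:1), probability = TRUE,
      num.trees = hyper$num_trees, mtry = min(hyper$mtry, ncol(x)),
      seed = seed
    ),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = hyper$max_depth, eta = hyper$eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
      nrounds = hyper$nrounds, verbose = 0
    ),
    svm = e1071::svm(
      x = as.matrix(x), y = factor(y, levels = 0:1), probability = TRUE,
      kernel = "radial", cost = hyper$cost
    ),
    neural_network = nnet::nnet(
      x = as.matrix(x), y = y, size = hyper$size, decay = hyper$decay,
      maxit = 500, trace = FALSE, entropy = TRUE
    ),
    abort(paste0("unknown model family: ", family))
  )
}

.predict_prob <- function(family, fit, x) {
  switch(family,
    logistic_regression = unname(predict(fit, newdata = x, type = "response")),
    random_forest = unname(predict(fit, data = x)$predictions[, "1"]),
    gradient_boosting = unname(predict(fit, xgboost::xgb.DMatrix(as.matrix(x)))),
    svm = {
      p <- predict(fit, as.matrix(x), probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    },
    neural_network = unname(predict(fit, as.matrix(x))[, 1])
  )
}

# Stratified assignment of rows into `k` near-equal groups (sizes differ by
# at most one; exactly equal when k divides n): shuffled within class, then
# dealt round-robin across folds so classes spread evenly.
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  counter <- 0L
  for (cls in unique(y)) {
    for (j in sample(which(y == cls))) {
      fold[j] <- counter %% k + 1L
      counter <- counter + 1L
    }
  }
  fold
}

#' Internal cross-validation over candidate model families
#'
#' Implements the nested model-selection scheme on the labeled training
#' rows: the 80 labeled participants are split (stratified) into an internal
#' training set of 64 — four equal folds of 16 — and a validation set of 16.
#' Each family's hyperparameters are tuned by cross-validation across the
#' four internal folds; the tuned family is refit on all 64 and judged by
#' its AUC on the held-out validation 16.
#'
#' @param features Feature tibble with a `label` column (`"high"`/`"low"`);
#'   only labeled rows are used and must number a multiple of the fold size.
#' @param feature_cols Feature columns (default PAF + CME class).
#' @param families Character vector of families to evaluate (default all
#'   five: logistic regression, random forest, gradient boosting, SVM,
#'   neural network).
#' @param n_folds Internal folds (default 4); fold size is
#'   `n_labeled / (n_folds + 1)`.
#' @param hyper_grids Named list of hyperparameter tibbles (defaults kept
#'   small and published in [.default_hyper_grids()]... see source).
#' @param seed Seed governing the partition and fits.
#' @return A list of class `cv_result`: `summary` (tibble: family, tuned
#'   hyperparameters, mean internal CV AUC, validation AUC), `partition`
#'   (row assignment), `features`, `feature_cols`, `seed`.
#' @export
internal_cv <- function(features, feature_cols = c("paf_hz", "cme_class"),
                        families = .family_order, n_folds = 4,
                        hyper_grids = .default_hyper_grids(), seed = 1) {
  labeled <- features[!is.na(features$label), ]
  complete <- stats::complete.cases(labeled[, feature_cols, drop = FALSE])
  if (!all(complete)) {
    warn(sprintf("dropping %d labeled row(s) with missing features",
                 sum(!complete)))
    labeled <- labeled[complete, ]
  }
  n <- nrow(labeled)
  k <- n_folds + 1
  if (n < 2 * k) {
    abort(sprintf("need at least %d labeled rows for %d folds, got %d",
                  2 * k, k, n))
  }
  y <- as.integer(labeled$label == "high")
  if (length(unique(y)) < 2) abort("both labels must be present")
  fold <- .stratified_folds(y, k, seed)
  val_idx <- fold == k
  continuous <- feature_cols[
    vapply(feature_cols, function(cl) {
      is.numeric(labeled[[cl]]) && length(unique(labeled[[cl]])) > 2
    }, logical(1))
  ]
  xall <- .encode_features(labeled, feature_cols)

  res <- purrr::map(families, function(fam) {
    grid <- hyper_grids[[fam]]
    cv_aucs <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
      hy <- grid[g, ]
      aucs <- purrr::map_dbl(seq_len(n_folds), function(f) {
        tr <- !val_idx & fold != f
        te <- fold == f
        std <- .standardizer(xall[tr, ], continuous)
        xtr <- .apply_standardizer(xall[tr, ], std)
        xte <- .apply_standardizer(xall[te, ], std)
        fit <- .fit_family(fam, xtr, y[tr], hy, seed + 100 * g + f)
        sc <- .predict_prob(fam, fit, xte)
        tryCatch(
          roc_auc(sc, y[te], positive = 1, n_boot = 0)$auc,
          error = function(e) NA_real_
        )
      })
      mean(aucs, na.rm = TRUE)
    })
    best <- which.max(cv_aucs)
    hy <- grid[best, ]
    std <- .standardizer(xall[!val_idx, ], continuous)
    xtr <- .apply_standardizer(xall[!val_idx, ], std)
    xva <- .apply_standardizer(xall[val_idx, ], std)
    fit <- .fit_family(fam, xtr, y[!val_idx], hy, seed + 7)
    va <- roc_auc(.predict_prob(fam, fit, xva), y[val_idx],
                  positive = 1, n_boot = 0)$auc
    tibble(
      family = fam, cv_auc = cv_aucs[best], validation_auc = va,
      hyper = list(hy)
    )
  }) |> list_rbind()

  structure(
    list(
      summary = res,
      partition = tibble(participant = labeled$participant, fold = fold,
                         role = ifelse(val_idx, "validation", "internal")),
      features = labeled, feature_cols = feature_cols,
      continuous = continuous, seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> internal cross-validation\n")
  print(x$summary[, c("family", "cv_auc", "validation_auc")])
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$summary[, c("family", "cv_auc", "validation_auc")]

#' Select the winning family and lock the model
#'
#' Picks the family with the highest validation AUC (ties resolved in favor
#' of the fewest-parameter family, logistic regression first), refits it on
#' all labeled training rows, freezes the feature standardisation constants
#' from those rows, derives the Youden-optimal probability threshold from
#' the training predictions, and seals everything with an integrity hash.
#' A locked model is immutable: prediction verifies the hash.
#'
#' @param cv A [internal_cv()] result.
#' @return An object of class `locked_model`.
#' @export
select_and_lock <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  s <- cv$summary
  s <- s[order(-s$validation_auc, match(s$family, .family_order)), ]
  fam <- s$family[1]
  hy <- s$hyper[[1]]
  labeled <- cv$features
  y <- as.integer(labeled$label == "high")
  xall <- .encode_features(labeled, cv$feature_cols)
  std <- .standardizer(xall, cv$continuous)
  xs <- .apply_standardizer(xall, std)
  fit <- .fit_family(fam, xs, y, hy, cv$seed + 99)
  train_scores <- .predict_prob(fam, fit, xs)
  thr <- optimal_threshold(train_scores, y, positive = 1)
  params <- if (fam == "logistic_regression") coef(fit) else NULL
  core <- list(
    family = fam, hyper = hy, fit = fit, standardization = std,
    feature_cols = cv$feature_cols, parameters = params,
    probability_threshold = thr$threshold,
    validation_auc = s$validation_auc[1]
  )
  structure(
    c(core, list(
      locked = TRUE, lock_time = format(Sys.time(), tz = "UTC"),
      hash = hash(core[c("family", "standardization", "feature_cols",
                         "parameters", "probability_threshold")])
    )),
    class = "locked_model"
  )
}

#' @export
print.locked_model <- function(x, ...) {
  cat(sprintf(
    "<locked_model> %s (validation AUC %.3f), threshold %.3f, locked %s\n",
    x$family, x$validation_auc, x$probability_threshold, x$lock_time
  ))
  invisible(x)
}

#' @export
tidy.locked_model <- function(x, ...) {
  if (is.null(x$parameters)) {
    return(tibble(term = character(), estimate = numeric()))
  }
  tibble(term = names(x$parameters), estimate = unname(x$parameters))
}

#' @export
glance.locked_model <- function(x, ...) {
  tibble(family = x$family, validation_auc = x$validation_auc,
         probability_threshold = x$probability_threshold, locked = x$locked)
}

# Verify a locked model has not been tampered with since locking.
.check_lock <- function(model) {
  if (!inherits(model, "locked_model") || !isTRUE(model$locked)) {
    abort("model is not locked; lock it with select_and_lock() first")
  }
  h <- hash(model[c("family", "standardization", "feature_cols",
                    "parameters", "probability_threshold")])
  if (!identical(h, model$hash)) {
    abort("locked-model integrity check failed: parameters changed after locking")
  }
  invisible(TRUE)
}

#' Predict per-participant probabilities from a locked model
#'
#' @param model A `locked_model`.
#' @param features Feature tibble (rows in any order; scores are a pure
#'   per-row function of the features).
#' @return Numeric vector of P(high) scores, one per row.
#' @export
predict_locked <- function(model, features) {
  .check_lock(model)
  x <- .encode_features(as_tibble(features), model$feature_cols)
  xs <- .apply_standardizer(x, model$standardization)
  .predict_prob(model$family, model$fit, xs)
}

#' Blinded test-set prediction and scoring
#'
#' Applies a locked model to the test features, then — and only then —
#' un-shuffles the blinded ground-truth labels using the recorded
#' permutation and scores the predictions: ROC AUC with bootstrap CI and
#' sensitivity/specificity at the locked probability threshold. The truth
#' enters shuffled (`shuffled_labels[j] = labels[permutation[j]]`), so
#' prediction never sees aligned labels; scoring verifies the model lock
#' first.
#'
#' @param model A `locked_model`.
#' @param test_features Test-set feature tibble (unlabeled rows allowed and
#'   dropped from scoring with their shuffled labels).
#' @param shuffled_labels Ground-truth labels in shuffled order.
#' @param permutation The shuffling permutation (recorded before
#'   prediction).
#' @param n_boot,seed Bootstrap controls for the AUC CI.
#' @return A list of class `blinded_prediction`: `roc` (a `roc_result`),
#'   `threshold`, `sensitivity`, `specificity`, `confusion` (2x2 tibble),
#'   `scores` tibble (participant, score, predicted label).
#' @export
predict_blinded <- function(model, test_features, shuffled_labels,
                            permutation, n_boot = 2000, seed = 1) {
  .check_lock(model)
  if (length(shuffled_labels) != nrow(test_features) ||
      length(permutation) != nrow(test_features)) {
    abort("shuffled labels and permutation must match the test rows")
  }
  scores <- predict_locked(model, test_features)
  truth <- shuffled_labels[order(permutation)] # un-shuffle at scoring time
  keep <- !is.na(truth) & !is.na(scores)
  tau <- model$probability_threshold
  pred <- ifelse(scores >= tau, "high", "low")
  roc <- roc_auc(scores[keep], truth[keep], positive = "high",
                 n_boot = n_boot, seed = seed)
  pos <- truth[keep] == "high"
  sens <- mean(pred[keep][pos] == "high")
  spec <- mean(pred[keep][!pos] == "low")
  confusion <- as_tibble(expand_grid(truth = c("high", "low"),
                                     predicted = c("high", "low"))) |>
    mutate(n = purrr::map2_int(.data$truth, .data$predicted, function(tr, pr) {
      sum(truth[keep] == tr & pred[keep] == pr)
    }))
  structure(
    list(
      roc = roc, threshold = tau, sensitivity = sens, specificity = spec,
      confusion = confusion,
      scores = tibble(
        participant = test_features$participant %||% seq_along(scores),
        score = scores, predicted = pred
      ),
      n_scored = sum(keep)
    ),
    class = "blinded_prediction"
  )
}

#' @export
print.blinded_prediction <- function(x, ...) {
  cat(sprintf(
    "<blinded_prediction> AUC %.3f (95%% CI %.3f-%.3f, %s); sens %.3f / spec %.3f at tau = %.2f (n = %d)\n",
    x$roc$auc, x$roc$ci_low, x$roc$ci_high, x$roc$band,
    x$sensitivity, x$specificity, x$threshold, x$n_scored
  ))
  invisible(x)
}

#' @export
glance.blinded_prediction <- function(x, ...) {
  bind_cols(glance(x$roc),
            tibble(sensitivity = x$sensitivity, specificity = x$specificity,
                   threshold = x$threshold, n_scored = x$n_scored))
}

#' Raw-Hz PAF cutoffs implied by a locked logistic model
#'
#' For a logistic model on standardised PAF and binary CME class
#' (facilitator = 1), inverts the decision boundary at probability `tau`
#' into a raw-Hz PAF cutoff per CME class: a participant of that class is
#' called high pain sensitive when their PAF falls below the cutoff
#' (assuming a negative PAF coefficient, i.e. slower alpha = higher risk).
#'
#' @param model A locked `locked_model` with family logistic regression and
#'   features `paf_hz` + `cme_class`.
#' @param tau Probability threshold (default the model's locked threshold).
#' @return A tibble: `cme_class` (`"facilitator"`, `"depressor"`),
#'   `cutoff_hz` (`NA` with a message when the PAF coefficient is zero),
#'   `direction` (`"less_than"` for negative PAF coefficients).
#' @export
paf_cutoffs <- function(model, tau = NULL) {
  .check_lock(model)
  if (model$family != "logistic_regression") {
    abort("raw-Hz cutoffs require the logistic regression family")
  }
  tau <- tau %||% model$probability_threshold
  b <- model$parameters
  if (!all(c("(Intercept)", "paf_hz", "cme_class") %in% names(b))) {
    abort("model must use features paf_hz and cme_class")
  }
  std <- model$standardization
  mu <- std$mean[std$feature == "paf_hz"]
  s <- std$sd[std$feature == "paf_hz"]
  if (b[["paf_hz"]] == 0) {
    return(tibble(cme_class = c("facilitator", "depressor"),
                  cutoff_hz = NA_real_, direction = "undefined"))
  }
  cut_for <- function(c_val) {
    z <- (qlogis(tau) - b[["(Intercept)"]] - b[["cme_class"]] * c_val) /
      b[["paf_hz"]]
    mu + s * z
  }
  tibble(
    cme_class = c("facilitator", "depressor"),
    cutoff_hz = c(cut_for(1), cut_for(0)),
    direction = if (b[["paf_hz"]] < 0) "less_than" else "greater_than"
  )
}

#' Covariate-augmented model with p-value feature selection
#'
#' Computes univariate label-association p-values for every candidate
#' feature (Welch two-sample t-test for continuous features, Fisher's exact
#' test for binary), retains those below `p_threshold` (deduplicated),
#' refits the same nested CV + lock scheme on the augmented feature set and
#' reports it alongside the biomarker-only model. Falls back to the
#' biomarker-only feature set, with a warning, when nothing survives.
#'
#' @param features Labeled feature tibble (training rows).
#' @param candidate_cols Candidate feature columns (default PAF, CME class,
#'   sex, PCS total, PCS helplessness).
#' @param p_threshold Selection threshold on the univariate p-value.
#' @param families Families for the augmented CV (default logistic only).
#' @param seed Seed for the CV partition.
#' @return A list of class `covariate_model`: `p_values` tibble,
#'   `selected`, `cv` (a `cv_result`), `model` (a `locked_model`).
#' @export
covariate_model <- function(features,
                            candidate_cols = c("paf_hz", "cme_class", "sex",
                                               "pcs_total", "pcs_helplessness"),
                            p_threshold = 0.05,
                            families = "logistic_regression", seed = 1) {
  candidate_cols <- unique(candidate_cols)
  labeled <- features[!is.na(features$label), ]
  y <- labeled$label == "high"
  pv <- purrr::map(candidate_cols, function(cl) {
    v <- labeled[[cl]]
    if (!is.numeric(v)) v <- as.integer(v == v[which(!is.na(v))][1])
    p <- if (length(unique(v)) <= 2) {
      fisher.test(table(factor(v), factor(y)))$p.value
    } else {
      t.test(v ~ y)$p.value
    }
    tibble(feature = cl, p_value = p)
  }) |> list_rbind()
  selected <- pv$feature[pv$p_value < p_threshold]
  if (length(selected) == 0) {
    warn("no feature passed selection; falling back to biomarker-only features")
    selected <- intersect(c("paf_hz", "cme_class"), candidate_cols)
  }
  cv <- internal_cv(labeled, feature_cols = selected, families = families,
                    seed = seed)
  model <- select_and_lock(cv)
  structure(
    list(p_values = pv, selected = selected, cv = cv, model = model),
    class = "covariate_model"
  )
}

#' Serialise a locked logistic model to JSON
#'
#' Writes family, coefficients, standardisation constants, threshold and
#' the integrity hash. Only the logistic family has a portable text
#' parameterisation; other families raise an error.
#'
#' @param model A `locked_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_locked_model <- function(model, path) {
  .check_lock(model)
  if (model$family != "logistic_regression") {
    abort("only logistic-regression locked models have a JSON serialisation")
  }
  jsonlite::write_json(
    list(
      family = model$family,
      coefficients = as.list(model$parameters),
      standardization = model$standardization,
      feature_cols = model$feature_cols,
      probability_threshold = model$probability_threshold,
      validation_auc = model$validation_auc,
      lock_time = model$lock_time, hash = model$hash
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
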