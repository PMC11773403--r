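# End-to-end nested control-test pipeline with locking/blinding discipline.

#' Pipeline configuration
#'
#' Bundles every stage option of the nested control-test workflow. All
#' randomness flows from `seed` through named per-stage substreams; the
#' config hash is recorded in the run report for audit.
#'
#' @param cohort A [cohort_config()] (synthetic cohort source).
#' @param paf_source,paf_window,paf_method,roi_labels PAF stage options.
#' @param cme_metric,active_threshold CME stage options.
#' @param label_days Diary span used for labeling (default days 1-7;
#'   `1:30` for the robustness variant).
#' @param imputation `"linear_interpolate"` or `"none"`.
#' @param n_extreme Participants labeled at each posterior extreme.
#' @param families Candidate model families.
#' @param gmm_starts EM starts for the growth mixture model.
#' @param n_boot Bootstrap resamples for the test AUC CI.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            paf_source = "component",
                            paf_window = c(8, 12), paf_method = "cog",
                            roi_labels = sensorimotor_channels(),
                            cme_metric = "volume", active_threshold = 0.1,
                            label_days = 1:7,
                            imputation = "linear_interpolate",
                            n_extreme = 40,
                            families = .family_order,
                            gmm_starts = 20, n_boot = 2000, seed = 1) {
  stopifnot(inherits(cohort, "cohort_config"))
  paf_source <- match.arg(paf_source, c("component", "roi"))
  paf_method <- match.arg(paf_method, c("cog", "peak"))
  cme_metric <- match.arg(cme_metric, c("volume", "area"))
  imputation <- match.arg(imputation, c("linear_interpolate", "none"))
  cfg <- list(
    cohort = cohort, paf_source = paf_source, paf_window = paf_window,
    paf_method = paf_method, roi_labels = roi_labels,
    cme_metric = cme_metric, active_threshold = active_threshold,
    label_days = label_days, imputation = imputation, n_extreme = n_extreme,
    families = families, gmm_starts = gmm_starts, n_boot = n_boot,
    seed = as.integer(seed)
  )
  structure(cfg, class = "pipeline_config")
}

.stage_seeds <- function(master) {
  set.seed(master)
  setNames(sample.int(2^31 - 2, 5), c("gmm", "cv", "shuffle", "boot", "spare"))
}

#' Run the nested control-test pipeline end to end
#'
#' Stages, strictly in order: synthesise (or accept) the cohort; extract
#' biomarker features; fit the growth mixture model on the training diaries
#' and lock the label rule; label the test set with the locked rule (truth
#' then shuffled for blinding); tune and select candidate classifiers by
#' internal cross-validation; lock the winner; predict the blinded test set
#' and un-shuffle only at scoring. Every stage appends an audit record with
#' a content hash; reruns with an identical config reproduce identical
#' results.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optionally, a pre-generated [generate_cohort()] cohort
#'   matching `config$cohort` (to share one cohort across variants).
#' @return An object of class `pipeline_run`: `features`, `gmm`,
#'   `label_rule`, `training_labels`, `test_labels`, `cv`, `model`,
#'   `prediction` (a `blinded_prediction`), `cutoffs`, `audit` (stage log),
#'   `config_hash`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- .stage_seeds(config$seed)
  audit <- list()
  log_stage <- function(stage, obj) {
    audit[[length(audit) + 1]] <<- tibble(
      stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
      hash = hash(obj)
    )
  }

  eeg_channels <- if (config$paf_source == "roi") config$roi_labels else NULL
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$cohort, eeg_days = 0,
                              eeg_channels = eeg_channels)
  }
  log_stage("cohort", cohort$participants)

  features <- build_feature_table(
    cohort, paf_source = config$paf_source, paf_window = config$paf_window,
    paf_method = config$paf_method, roi_labels = config$roi_labels,
    cme_metric = config$cme_metric,
    active_threshold = config$active_threshold
  )
  log_stage("features", features)

  train_idx <- features$set == "train"
  diaries_train <- cohort$diaries[train_idx]
  diaries_test <- cohort$diaries[!train_idx]
  names(diaries_train) <- features$participant[train_idx]
  names(diaries_test) <- features$participant[!train_idx]
  tm_train <- impute_trajectories(
    trajectory_matrix(diaries_train, days = config$label_days),
    mode = config$imputation
  )
  gmm <- fit_gmm(tm_train, n_starts = config$gmm_starts,
                 seed = seeds[["gmm"]])
  assigned <- assign_training_labels(gmm$posterior, config$n_extreme)
  log_stage("gmm_labels", list(tidy(gmm), assigned$rule))

  tm_test <- impute_trajectories(
    trajectory_matrix(diaries_test, days = config$label_days),
    mode = config$imputation
  )
  test_post <- gmm_posterior(gmm, tm_test)
  test_labels <- apply_locked_labels(test_post, assigned$rule)
  # blinding: shuffle the test truth; the permutation is recorded now,
  # before any prediction happens
  set.seed(seeds[["shuffle"]])
  perm <- sample.int(nrow(test_labels))
  shuffled <- test_labels$label[perm]
  log_stage("test_labels_shuffled", list(perm, shuffled))

  train_features <- features[train_idx, ] |>
    left_join(
      assigned$labels |>
        mutate(participant = as.integer(.data$participant)) |>
        select("participant", "label"),
      by = "participant"
    )
  cv <- internal_cv(train_features, families = config$families,
                    seed = seeds[["cv"]])
  model <- select_and_lock(cv)
  log_stage("locked_model", model$hash)

  test_features <- features[!train_idx, ]
  prediction <- predict_blinded(model, test_features, shuffled, perm,
                                n_boot = config$n_boot,
                                seed = seeds[["boot"]])
  log_stage("blinded_prediction", glance(prediction))

  cutoffs <- if (model$family == "logistic_regression") {
    paf_cutoffs(model)
  } else NULL

  structure(
    list(
      features = features, gmm = gmm, label_rule = assigned$rule,
      training_labels = assigned$labels, test_labels = test_labels,
      cv = cv, model = model, prediction = prediction, cutoffs = cutoffs,
      audit = list_rbind(audit),
      config_hash = hash(unclass(config)), seed = config$seed
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  cat(sprintf("  labeled training: %d / %d; labeled test: %d / %d\n",
              sum(!is.na(x$training_labels$label)), nrow(x$training_labels),
              sum(!is.na(x$test_labels$label)), nrow(x$test_labels)))
  cat(sprintf("  locked model: %s (validation AUC %.3f)\n",
              x$model$family, x$model$validation_auc))
  print(x$prediction)
  invisible(x)
}

#' @export
glance.pipeline_run <- function(x, ...) {
  bind_cols(
    tibble(
      family = x$model$family, validation_auc = x$model$validation_auc,
      n_train_labeled = sum(!is.na(x$training_labels$label)),
      n_test_labeled = sum(!is.na(x$test_labels$label))
    ),
    glance(x$prediction)
  )
}

#' Robustness grid over methodological choices
#'
#' Re-runs the pipeline across a grid of PAF pathway / frequency window /
#' peak estimator / CME metric / label span / imputation variants on a
#' single cohort, reusing one set of recordings per PAF source, and
#' tabulates validation and test AUCs per cell. Cell failures are recorded
#' and the grid continues.
#'
#' @param config Base [pipeline_config()] (its cohort and seed are shared
#'   by every cell).
#' @param grid A tibble of variant columns among `paf_source`, `window_high`
#'   `window_low`, `paf_method`, `cme_metric`, `label_span`, `imputation`;
#'   defaults to the full factorial used in the robustness analysis.
#' @param families Model families per cell (default logistic regression).
#' @return A tibble: one row per grid cell with `validation_auc`,
#'   `test_auc`, `n_test_labeled`, `error` (NA on success).
#' @details The cohort is generated once; per-participant component
#'   decompositions / ROI spectra, map metrics and growth-mixture labelings
#'   are each computed once per unique sub-option and shared across cells.
#' @export
robustness_grid <- function(config = pipeline_config(),
                            grid = NULL, families = "logistic_regression") {
  grid <- grid %||% expand_grid(
    paf_source = c("component", "roi"),
    window = list(c(8, 12), c(9, 11)),
    paf_method = c("cog", "peak"),
    cme_metric = c("volume", "area"),
    label_span = list(1:7, 1:30),
    imputation = c("linear_interpolate", "none")
  )
  if (!"paf_source" %in% names(grid)) grid$paf_source <- config$paf_source
  if (!"window" %in% names(grid)) grid$window <- list(config$paf_window)
  if (!"paf_method" %in% names(grid)) grid$paf_method <- config$paf_method
  if (!"cme_metric" %in% names(grid)) grid$cme_metric <- config$cme_metric
  if (!"label_span" %in% names(grid)) grid$label_span <- list(config$label_days)
  if (!"imputation" %in% names(grid)) grid$imputation <- config$imputation

  needs_component <- any(grid$paf_source == "component")
  cohort <- generate_cohort(
    config$cohort, eeg_days = 0,
    eeg_channels = if (needs_component) NULL else config$roi_labels
  )
  n <- nrow(cohort$participants)
  seeds <- .stage_seeds(config$seed)

  # cache spectra once per PAF source
  comp_cache <- NULL
  if (needs_component) {
    comp_cache <- purrr::map(seq_len(n), function(i) {
      rec <- preprocess_eeg(cohort$recordings[[i]]$day0)
      decomp <- decompose_components(rec)
      list(decomp = decomp, spectra = component_spectra(decomp))
    })
  }
  roi_cache <- NULL
  if (any(grid$paf_source == "roi")) {
    roi_cache <- purrr::map(seq_len(n), function(i) {
      rec <- cohort$recordings[[i]]$day0
      keep <- match(config$roi_labels, rec$channel_labels)
      rec <- eeg_recording(rec$data[keep, , drop = FALSE], rec$sfreq,
                           rec$channel_labels[keep])
      compute_spectrum(preprocess_eeg(rec))
    })
  }
  paf_for <- function(source, window, method) {
    vapply(seq_len(n), function(i) {
      if (source == "component") {
        sel <- select_sensorimotor_component(comp_cache[[i]]$decomp,
                                             comp_cache[[i]]$spectra,
                                             window = c(8, 12))
        if (is.na(sel$component)) return(NA_real_)
        estimate_paf(comp_cache[[i]]$spectra, window, method,
                     channel = sel$component)$paf
      } else {
        sensor_roi_paf(roi_cache[[i]], config$roi_labels, window, method)$paf
      }
    }, numeric(1))
  }

  cme_for <- function(metric) {
    purrr::map(seq_len(n), function(i) {
      classify_cme(cohort$maps[[i]]$day0, cohort$maps[[i]]$day5,
                   metric = metric, threshold = config$active_threshold)
    }) |> list_rbind()
  }

  train_idx <- cohort$participants$set == "train"
  labels_for <- function(span, imputation) {
    dtr <- setNames(cohort$diaries[train_idx], which(train_idx))
    dte <- setNames(cohort$diaries[!train_idx], which(!train_idx))
    tm_tr <- impute_trajectories(trajectory_matrix(dtr, days = span),
                                 mode = imputation)
    gmm <- fit_gmm(tm_tr, n_starts = config$gmm_starts, seed = seeds[["gmm"]])
    assigned <- assign_training_labels(gmm$posterior, config$n_extreme)
    tm_te <- impute_trajectories(trajectory_matrix(dte, days = span),
                                 mode = imputation)
    test_labels <- apply_locked_labels(gmm_posterior(gmm, tm_te),
                                       assigned$rule)
    list(train = assigned$labels, test = test_labels)
  }

  paf_key <- function(cell) paste(cell$paf_source,
                                  paste(cell$window[[1]], collapse = "-"),
                                  cell$paf_method)
  lab_key <- function(cell) paste(paste(range(cell$label_span[[1]]),
                                        collapse = "-"), cell$imputation)
  paf_cache <- list()
  cme_cache <- list()
  lab_cache <- list()

  purrr::map(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    desc <- tibble(
      cell_id = i, paf_source = cell$paf_source,
      window = paste(cell$window[[1]], collapse = "-"),
      paf_method = cell$paf_method, cme_metric = cell$cme_metric,
      label_span = paste0("days_", min(cell$label_span[[1]]), "_",
                          max(cell$label_span[[1]])),
      imputation = cell$imputation
    )
    res <- tryCatch({
      pk <- paf_key(cell)
      if (is.null(paf_cache[[pk]])) {
        paf_cache[[pk]] <<- paf_for(cell$paf_source, cell$window[[1]],
                                    cell$paf_method)
      }
      ck <- cell$cme_metric
      if (is.null(cme_cache[[ck]])) cme_cache[[ck]] <<- cme_for(ck)
      lk <- lab_key(cell)
      if (is.null(lab_cache[[lk]])) {
        lab_cache[[lk]] <<- labels_for(cell$label_span[[1]], cell$imputation)
      }
      labs <- lab_cache[[lk]]
      feats <- tibble(
        participant = cohort$participants$participant,
        set = cohort$participants$set,
        paf_hz = paf_cache[[pk]],
        cme_class = as.integer(cme_cache[[ck]]$cme_class == "facilitator")
      )
      train_features <- feats[train_idx, ] |>
        left_join(labs$train |>
                    mutate(participant = as.integer(.data$participant)) |>
                    select("participant", "label"),
                  by = "participant")
      cv <- internal_cv(train_features, families = families,
                        seed = seeds[["cv"]])
      model <- select_and_lock(cv)
      set.seed(seeds[["shuffle"]])
      perm <- sample.int(sum(!train_idx))
      shuffled <- labs$test$label[perm]
      pred <- predict_blinded(model, feats[!train_idx, ], shuffled, perm,
                              n_boot = 0)
      bind_cols(desc, tibble(
        validation_auc = model$validation_auc,
        test_auc = pred$roc$auc,
        n_test_labeled = sum(!is.na(labs$test$label)),
        error = NA_character_
      ))
    }, error = function(e) {
      bind_cols(desc, tibble(validation_auc = NA_real_, test_auc = NA_real_,
                             n_test_labeled = NA_integer_,
                             error = conditionMessage(e)))
    })
    res
  }) |> list_rbind()
}
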