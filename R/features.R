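# Per-participant biomarker feature extraction from a cohort.

#' Build the biomarker feature table
#'
#' Extracts each participant's day-0 sensorimotor PAF (component or sensor
#' ROI pathway) and facilitator/depressor CME class (day 5 vs day 0 map
#' volume or area), plus covariates, from a synthetic or loaded cohort.
#'
#' @param cohort A [generate_cohort()] result.
#' @param paf_source,paf_window,paf_method PAF pathway options (see
#'   [paf_from_recording()]).
#' @param roi_labels Sensor ROI for the `"roi"` pathway.
#' @param cme_metric `"volume"` or `"area"`.
#' @param active_threshold Active-site rule, fraction of maximum.
#' @return A tibble: `participant`, `set`, `paf_hz`, `cme_class`
#'   (facilitator = 1, depressor = 0), `sex`, `pcs_total`,
#'   `pcs_helplessness`, `paf_qc` plus a `qc_plausible` flag (PAF within
#'   6-14 Hz).
#' @export
build_feature_table <- function(cohort,
                                paf_source = c("component", "roi"),
                                paf_window = c(8, 12),
                                paf_method = c("cog", "peak"),
                                roi_labels = sensorimotor_channels(),
                                cme_metric = c("volume", "area"),
                                active_threshold = 0.1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  paf_source <- match.arg(paf_source)
  paf_method <- match.arg(paf_method)
  cme_metric <- match.arg(cme_metric)
  if (is.null(cohort$recordings)) {
    abort("cohort has no EEG recordings; regenerate with keep_recordings = TRUE")
  }
  n <- nrow(cohort$participants)
  paf <- purrr::map(seq_len(n), function(i) {
    rec <- cohort$recordings[[i]]$day0
    if (is.null(rec)) abort("day-0 EEG recording missing")
    paf_from_recording(rec, source = paf_source, window = paf_window,
                       method = paf_method, roi_labels = roi_labels)
  }) |> list_rbind()
  cme <- purrr::map(seq_len(n), function(i) {
    classify_cme(cohort$maps[[i]]$day0, cohort$maps[[i]]$day5,
                 metric = cme_metric, threshold = active_threshold)
  }) |> list_rbind()
  cohort$participants |>
    select("participant", "set", "sex", "pcs_total", "pcs_helplessness") |>
    mutate(
      paf_hz = paf$paf,
      paf_qc = paf$qc_flag,
      qc_plausible = !is.na(paf$paf) & paf$paf >= 6 & paf$paf <= 14,
      cme_class = as.integer(cme$cme_class == "facilitator"),
      delta_cme = cme$delta
    ) |>
    select("participant", "set", "paf_hz", "cme_class", "delta_cme",
           "sex", "pcs_total", "pcs_helplessness", "paf_qc", "qc_plausible")
}
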