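#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis: input
#' location (or a synthetic-cohort configuration), preprocessing limits,
#' split proportions and seed, model choice and evaluation settings. All
#' limits default to the study's operating constants.
#'
#' @param cohort_config a [cohort_config()] for synthetic input, or `NULL`
#'   when reading CSV extracts from `input_dir`.
#' @param input_dir directory with `patients.csv`, `urine_output.csv`,
#'   `creatinine.csv` (ignored when `cohort_config` is given).
#' @param model one of "cnn", "logistic_multi", "logistic_single".
#' @param model_config a [model_config()] (cnn only).
#' @param rule a [single_feature_rule()] (logistic_single only).
#' @param max_uo_gap_hours,max_scr_gap_hours,min_los_hours,min_baseline,min_center_volume,ca_horizon_hours
#'   exclusion limits (see [apply_exclusions()]).
#' @param split_seed seed of the patient-level 60/10/20/10 partition.
#' @param target_sensitivity fixed-sensitivity operating target.
#' @param lead_hours early-detection lead requirement.
#' @param alarm_threshold default alarm cut-off on the 0-100 score scale;
#'   the evaluation additionally re-derives a knee-point threshold per run.
#' @param n_resamples test-set resamples for the mean +/- SD summary.
#' @param seed master seed for feature sampling and resampling.
#' @param out_dir optional directory; when set, every stage writes its
#'   CSV/JSON artifact there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_config = NULL, input_dir = NULL,
                            model = c("cnn", "logistic_multi",
                                      "logistic_single"),
                            model_config = NULL, rule = single_feature_rule(),
                            max_uo_gap_hours = 9, max_scr_gap_hours = 96,
                            min_los_hours = 24, min_baseline = 0.5,
                            min_center_volume = 50, ca_horizon_hours = 12,
                            split_seed = 1L, target_sensitivity = 0.80,
                            lead_hours = 12, alarm_threshold = 70,
                            n_resamples = 100L, seed = 1L, out_dir = NULL) {
  model <- match.arg(model)
  if (is.null(cohort_config) && is.null(input_dir))
    stop("either `cohort_config` or `input_dir` must be given", call. = FALSE)
  structure(list(cohort_config = cohort_config, input_dir = input_dir,
                 model = model,
                 model_config = model_config %||% model_config_default(seed),
                 rule = rule,
                 max_uo_gap_hours = max_uo_gap_hours,
                 max_scr_gap_hours = max_scr_gap_hours,
                 min_los_hours = min_los_hours, min_baseline = min_baseline,
                 min_center_volume = min_center_volume,
                 ca_horizon_hours = ca_horizon_hours,
                 split_seed = as.integer(split_seed),
                 target_sensitivity = target_sensitivity,
                 lead_hours = lead_hours, alarm_threshold = alarm_threshold,
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

model_config_default <- function(seed) model_config(seed = seed)

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the end-to-end pipeline
#'
#' simulate/read -> preprocess -> exclude -> label -> truncate -> split ->
#' fit -> calibrate -> evaluate. Each stage logs its patient accounting;
#' with `config$out_dir` set, each stage also writes its artifact (cohort
#' tables, hourly series, exclusion report, episode table, scores, and the
#' evaluation report as JSON).
#'
#' @param config a [pipeline_config()].
#' @return object of class `uo_report`: exclusion waterfall, episode table,
#'   split assignment, patient-level test scores, and the evaluation list
#'   (AUC with resampled mean +/- SD, knee and fixed-sensitivity operating
#'   points with likelihood ratios, early-detection fraction, per-stage
#'   breakdown).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  ## ---- input -------------------------------------------------------------
  cohort <- if (!is.null(config$cohort_config)) {
    .log_stage("simulate", "generating synthetic cohort (n=%d, seed=%d)",
               config$cohort_config$n_patients, config$cohort_config$seed)
    generate_cohort(config$cohort_config)
  } else {
    .log_stage("input", "reading cohort from %s", config$input_dir)
    read_cohort_csv(config$input_dir)
  }
  if (!is.null(out) && !is.null(config$cohort_config))
    write_cohort_csv(cohort, file.path(out, "cohort"))

  ## ---- preprocess + exclusions -------------------------------------------
  pre <- preprocess_cohort(cohort, config$max_uo_gap_hours,
                           config$max_scr_gap_hours)
  exc <- apply_exclusions(pre$series, pre$baselines,
                          min_los_hours = config$min_los_hours,
                          min_baseline = config$min_baseline,
                          min_center_volume = config$min_center_volume,
                          ca_horizon_hours = config$ca_horizon_hours)
  waterfall <- table(exc$report$first_reason[exc$report$excluded])
  .log_stage("preprocess", "%d stays in, %d kept, %d excluded (%s)",
             length(pre$series), length(exc$kept),
             sum(exc$report$excluded),
             paste(sprintf("%s=%d", names(waterfall), waterfall),
                   collapse = ", "))
  stopifnot(length(pre$series) ==
              length(exc$kept) + sum(exc$report$excluded))
  if (!is.null(out)) {
    utils::write.csv(exc$report, file.path(out, "exclusions.csv"),
                     row.names = FALSE)
    write_hourly_csv(exc$kept, file.path(out, "hourly.csv"))
  }

  ## ---- label + truncate ----------------------------------------------------
  labels <- label_cohort(exc$kept, exc$baselines)
  short_onset <- labels$label == "case" & labels$onset_hour < 19
  if (any(short_onset)) {
    .log_stage("label", "dropping %d case(s) with onset before hour 19 (no 12-h window with 6-h lead)",
               sum(short_onset))
    drop_ids <- labels$patient_id[short_onset]
    exc$kept <- exc$kept[!vapply(exc$kept, function(s)
      s$patient_id %in% drop_ids, logical(1))]
    labels <- labels[!short_onset, , drop = FALSE]
  }
  .log_stage("label", "%d cases (stage 2: %d, stage 3: %d), %d controls",
             sum(labels$label == "case"),
             sum(labels$stage == 2, na.rm = TRUE),
             sum(labels$stage == 3, na.rm = TRUE),
             sum(labels$label == "control"))
  if (!is.null(out))
    utils::write.csv(labels, file.path(out, "episodes.csv"),
                     row.names = FALSE)
  onset_by_id <- stats::setNames(labels$onset_hour, labels$patient_id)
  series <- lapply(exc$kept, function(s) {
    o <- onset_by_id[[s$patient_id]]
    if (!is.na(o)) truncate_case_series(s, o) else s
  })

  ## ---- split ---------------------------------------------------------------
  ids <- vapply(series, function(s) s$patient_id, character(1))
  splits <- assign_splits(ids, config$split_seed)
  assert_patient_disjoint(splits)
  .log_stage("split", paste(sprintf("%s=%d", names(table(splits)),
                                    table(splits)), collapse = ", "))
  series_of <- function(which) series[splits[ids] == which]
  lab_of <- function(which)
    labels[labels$patient_id %in% names(splits)[splits == which], ,
           drop = FALSE]
  if (sum(lab_of("train")$label == "case") == 0L)
    stop("single-class training data: no cases survive in the training split",
         call. = FALSE)

  ## ---- model ---------------------------------------------------------------
  test_series <- series_of("test")
  test_labels <- lab_of("test")
  if (config$model == "cnn") {
    tr <- make_window_samples(series_of("train"), labels)
    va <- make_window_samples(series_of("validation"), labels)
    ca <- make_window_samples(series_of("calibration"), labels)
    .log_stage("train", "cnn on %d windows (%d positive), %d validation windows",
               length(tr$y), sum(tr$y), length(va$y))
    model <- build_model(config$model_config)
    model <- train_model(model, tr, va)
    calibrator <- tryCatch(calibrate_model(model, ca),
                           error = function(e) NULL)
    pat <- score_patients(model, test_series, calibrator,
                          config$alarm_threshold)
    hourly <- do.call(rbind, lapply(test_series, function(s)
      if (s$n_hours >= 12) predict_risk(model, s, calibrator,
                                        config$alarm_threshold) else NULL))
  } else {
    feats_train <- feature_table(series_of("train"), labels)
    feats_test <- feature_table(test_series, labels)
    if (config$model == "logistic_multi") {
      fit <- fit_multifeature_logistic(
        sample_one_per_patient(feats_train, child_seed(config$seed, "sample")))
      .log_stage("train", "multi-feature logistic on %d patients",
                 length(unique(feats_train$patient_id)))
      p <- stats::predict(fit, feats_test)
      model <- fit
    } else {
      .log_stage("train", "single-feature rule: w=%d, threshold=%.3f",
                 config$rule$window_w, config$rule$threshold_mlkg_h)
      f <- feats_test[[paste0("f", config$rule$window_w)]]
      ## map flow to a 0-1 risk so that the published threshold sits where
      ## the alarm semantics expect it: lower flow = higher score
      p <- .sigmoid((config$rule$threshold_mlkg_h - f) * 10)
      model <- config$rule
    }
    hourly <- data.frame(patient_id = feats_test$patient_id,
                         hour = feats_test$prediction_hour,
                         score = 100 * p,
                         alarm = 100 * p > config$alarm_threshold)
    pat <- do.call(rbind, lapply(split(hourly, hourly$patient_id),
      function(d) data.frame(
        patient_id = d$patient_id[1], score = max(d$score),
        first_alarm_hour = if (any(d$alarm)) min(d$hour[d$alarm])
                           else NA_integer_)))
  }

  ## ---- evaluate -------------------------------------------------------------
  scores <- merge(pat, test_labels, by = "patient_id")
  scores <- scores[!is.na(scores$score), , drop = FALSE]
  evaluation <- evaluate_patient_scores(
    scores, hourly, target_sensitivity = config$target_sensitivity,
    lead_hours = config$lead_hours, n_resamples = config$n_resamples,
    seed = child_seed(config$seed, "resample"))
  .log_stage("evaluate",
             "test AUC %.3f (resampled %.3f +/- %.3f), knee sens %.2f spec %.2f, early detection %.0f%%",
             evaluation$auc, evaluation$auc_mean, evaluation$auc_sd,
             evaluation$knee$sensitivity, evaluation$knee$specificity,
             100 * evaluation$early_detection_fraction)

  report <- structure(list(
    config = config, exclusions = exc$report, labels = labels,
    splits = splits, model = model, test_scores = scores,
    evaluation = evaluation), class = "uo_report")
  if (!is.null(out)) {
    utils::write.csv(scores, file.path(out, "test_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Evaluate patient-level scores
#'
#' Shared evaluation back-end: ROC/AUC, knee and fixed-sensitivity
#' operating points with likelihood ratios, resampled mean +/- SD,
#' early-detection fraction at the knee threshold, and the per-stage
#' breakdown.
#'
#' @param scores data.frame with `patient_id`, `score`, `first_alarm_hour`,
#'   `label`, `stage`, `onset_hour`.
#' @param hourly hourly score table (`patient_id`, `hour`, `score`) used to
#'   re-derive first alarms at the knee threshold; `NULL` falls back to the
#'   `first_alarm_hour` column.
#' @param target_sensitivity,lead_hours,n_resamples,seed see
#'   [pipeline_config()].
#' @return list with `auc`, `auc_mean`, `auc_sd`, `knee`, `fixed`,
#'   `early_detection_fraction`, `per_stage`, `n_cases`, `n_controls`.
#' @export
evaluate_patient_scores <- function(scores, hourly = NULL,
                                    target_sensitivity = 0.80,
                                    lead_hours = 12, n_resamples = 100L,
                                    seed = 1L) {
  roc <- roc_curve_and_auc(scores$score, scores$label)
  kp <- knee_point(roc)
  fx <- operating_point_at_sensitivity(roc, target_sensitivity)
  rs <- resampled_performance(scores, n_resamples = n_resamples, seed = seed,
                              target_sensitivity = target_sensitivity)
  cases <- scores[scores$label == "case", , drop = FALSE]
  if (!is.null(hourly) && nrow(cases)) {
    fa <- vapply(cases$patient_id, function(pid) {
      d <- hourly[hourly$patient_id == pid & hourly$score > kp$threshold, ,
                  drop = FALSE]
      if (nrow(d)) min(d$hour) else NA_real_
    }, numeric(1))
  } else fa <- cases$first_alarm_hour
  edf <- early_detection_fraction(fa, cases$onset_hour, lead_hours)
  per_stage <- per_stage_breakdown(scores, cases, kp$threshold)
  list(auc = roc$auc, auc_mean = rs$auc_mean, auc_sd = rs$auc_sd,
       knee = kp, fixed = fx, early_detection_fraction = edf,
       per_stage = per_stage, n_cases = nrow(cases),
       n_controls = sum(scores$label == "control"))
}

#' Plain summary of a pipeline report
#'
#' @param report a `uo_report`.
#' @return a nested list suitable for JSON serialisation.
#' @export
report_summary <- function(report) {
  ev <- report$evaluation
  list(
    n_patients = length(report$splits),
    n_cases = sum(report$labels$label == "case"),
    excluded = sum(report$exclusions$excluded),
    model = report$config$model,
    auc = ev$auc, auc_mean = ev$auc_mean, auc_sd = ev$auc_sd,
    knee = list(threshold = ev$knee$threshold,
                sensitivity = ev$knee$sensitivity,
                specificity = ev$knee$specificity,
                lr_pos = ev$knee$lr_pos, lr_neg = ev$knee$lr_neg),
    fixed_sensitivity = list(threshold = ev$fixed$threshold,
                             sensitivity = ev$fixed$sensitivity,
                             specificity = ev$fixed$specificity,
                             lr_pos = ev$fixed$lr_pos,
                             lr_neg = ev$fixed$lr_neg),
    early_detection_fraction = ev$early_detection_fraction)
}

#' @export
print.uo_report <- function(x, ...) {
  ev <- x$evaluation
  cat(sprintf("<uo_report> model %s: %d test patients (%d cases)\n",
              x$config$model, nrow(x$test_scores), ev$n_cases))
  cat(sprintf("  AUC %.3f (resampled %.3f +/- %.3f)\n",
              ev$auc, ev$auc_mean, ev$auc_sd))
  cat(sprintf("  knee: sens %.2f spec %.2f LR+ %.2f LR- %.2f\n",
              ev$knee$sensitivity, ev$knee$specificity, ev$knee$lr_pos,
              ev$knee$lr_neg))
  cat(sprintf("  fixed %d%%: sens %.2f spec %.2f LR+ %.2f LR- %.2f\n",
              round(100 * x$config$target_sensitivity),
              ev$fixed$sensitivity, ev$fixed$specificity, ev$fixed$lr_pos,
              ev$fixed$lr_neg))
  cat(sprintf("  early detection (>= %d h lead): %.0f%%\n",
              x$config$lead_hours, 100 * ev$early_detection_fraction))
  invisible(x)
}
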