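#' Minimum moving average of an hourly urine-output series
#'
#' The minimum, over all contiguous windows of length `w`, of the window
#' mean. This is the basic sliding-window feature: low values mean the
#' patient sustained a `w`-hour stretch of low diuresis somewhere in the
#' series.
#'
#' @param uo numeric hourly series (ml/kg/h), length at least `w`.
#' @param w window length in hours.
#' @return the minimum window mean.
#' @export
min_moving_average <- function(uo, w) {
  n <- length(uo)
  if (w < 1) abort_field("w", "must be >= 1")
  if (n < w)
    stop(sprintf("series of length %d is shorter than window w = %d", n, w),
         call. = FALSE)
  cs <- cumsum(c(0, uo))
  min((cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w)
}

#' Extract the 11 sliding-window features at a prediction hour
#'
#' For window sizes 2 through 12, the minimum moving average of the hourly
#' urine output over hours `[0, t)`. Prediction starts at the 12th hour of
#' the stay, so `t >= 12`.
#'
#' @param series an `hourly_series` or numeric hourly ml/kg/h vector.
#' @param t prediction hour (the features use hours `0..t-1`).
#' @return named numeric vector `f2..f12`.
#' @export
extract_features <- function(series, t) {
  uo <- if (inherits(series, "hourly_series")) series$uo_mlkg_h else series
  if (t < 12) abort_field("t", "prediction starts at the 12th hour (t >= 12)")
  if (length(uo) < t)
    stop(sprintf("series has %d hours, prediction hour %d requested",
                 length(uo), t), call. = FALSE)
  x <- uo[seq_len(t)]
  f <- vapply(2:12, function(w) min_moving_average(x, w), numeric(1))
  names(f) <- paste0("f", 2:12)
  f
}

## all feature vectors of one series for t = 12..n_hours, computed in O(n)
## per window size via running minima of the moving averages
.feature_matrix <- function(uo) {
  n <- length(uo)
  if (n < 12) return(NULL)
  ts <- 12:n
  out <- matrix(NA_real_, nrow = length(ts), ncol = 11,
                dimnames = list(NULL, paste0("f", 2:12)))
  cs <- cumsum(c(0, uo))
  for (w in 2:12) {
    ma <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w  # window starting at s covers s..s+w-1
    cm <- cummin(ma)
    ## features at hour t use windows fully inside [0, t): starts s <= t - w
    out[, w - 1] <- cm[ts - w + 1]
  }
  out
}

#' Feature table for a cohort
#'
#' One row per (stay, prediction hour): control stays contribute a row at
#' every hour from 12 to discharge, case stays (already truncated 6 h before
#' onset) at every hour of the truncated series.
#'
#' @param series list of `hourly_series` (cases truncated).
#' @param labels data.frame with `patient_id` and `label` ("case"/"control").
#' @return data.frame `patient_id`, `prediction_hour`, `f2..f12`, `label`.
#' @export
feature_table <- function(series, labels) {
  lab <- stats::setNames(labels$label, labels$patient_id)
  rows <- lapply(series, function(s) {
    m <- .feature_matrix(s$uo_mlkg_h)
    if (is.null(m)) return(NULL)
    data.frame(patient_id = s$patient_id,
               prediction_hour = 12:s$n_hours, m,
               label = lab[[s$patient_id]], row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Select one feature vector per patient
#'
#' To analyse independent samples, a single prediction hour is drawn
#' uniformly at random for each patient.
#'
#' @param features a [feature_table()] data.frame.
#' @param seed integer seed; identical seeds give identical selections.
#' @return subset of `features`, one row per patient.
#' @export
sample_one_per_patient <- function(features, seed) {
  with_seed(seed, {
    ## iterate patients in a fixed order so the draw stream is reproducible
    idx_by_patient <- split(seq_len(nrow(features)), features$patient_id)
    picks <- vapply(idx_by_patient, function(ix)
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)],
      integer(1))
    features[sort(picks), , drop = FALSE]
  })
}

#' Fit the multi-feature logistic model
#'
#' A plain maximum-likelihood logistic regression of case status on the 11
#' sliding-window features. For separable toy data an optional ridge penalty
#' (via glmnet) keeps coefficients finite.
#'
#' @param features data.frame with `f2..f12` and `label`.
#' @param regularize if `TRUE`, fit an L2-penalised model instead of plain
#'   MLE (requires glmnet).
#' @param lambda ridge penalty when `regularize = TRUE`.
#' @return object of class `uo_logistic` with a `predict` method returning
#'   the probability of case.
#' @export
fit_multifeature_logistic <- function(features, regularize = FALSE,
                                      lambda = 1e-3) {
  y <- features$label == "case"
  if (length(unique(y)) < 2L)
    stop("both classes are required to fit the logistic model", call. = FALSE)
  fcols <- paste0("f", 2:12)
  if (regularize) {
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("glmnet is required for regularize = TRUE", call. = FALSE)
    x <- as.matrix(features[, fcols])
    fit <- glmnet::glmnet(x, as.numeric(y), family = "binomial",
                          alpha = 0, lambda = lambda)
    obj <- list(kind = "ridge", fit = fit, fcols = fcols)
  } else {
    d <- features[, c(fcols)]
    d$y <- y
    fit <- stats::glm(y ~ ., data = d, family = stats::binomial())
    obj <- list(kind = "mle", fit = fit, fcols = fcols)
  }
  class(obj) <- "uo_logistic"
  obj
}

#' @export
predict.uo_logistic <- function(object, newdata, ...) {
  if (object$kind == "ridge") {
    x <- as.matrix(newdata[, object$fcols])
    as.numeric(stats::predict(object$fit, newx = x, type = "response"))
  } else {
    as.numeric(stats::predict(object$fit, newdata = newdata,
                              type = "response"))
  }
}

#' @export
coef.uo_logistic <- function(object, ...) {
  if (object$kind == "ridge") {
    cf <- as.matrix(stats::coef(object$fit))
    stats::setNames(as.numeric(cf), rownames(cf))
  } else stats::coef(object$fit)
}

#' Single-feature alarm rule
#'
#' A fixed-threshold rule on one sliding-window feature: alarm when the
#' minimum `window_w`-hour average urine output falls strictly below
#' `threshold_mlkg_h`. The published operating rule uses a 7-h window at
#' 0.372 ml/kg/h.
#'
#' @param window_w window size, 2..12.
#' @param threshold_mlkg_h positive flow threshold.
#' @return object of class `single_feature_rule`.
#' @export
single_feature_rule <- function(window_w = 7L, threshold_mlkg_h = 0.372) {
  check_scalar_number(window_w, "window_w", lower = 2, upper = 12,
                      integer = TRUE)
  check_scalar_number(threshold_mlkg_h, "threshold_mlkg_h", lower = 1e-12)
  structure(list(window_w = as.integer(window_w),
                 threshold_mlkg_h = threshold_mlkg_h),
            class = "single_feature_rule")
}

#' Apply a single-feature rule
#'
#' @param features a named feature vector from [extract_features()] or a
#'   [feature_table()] data.frame.
#' @param rule a [single_feature_rule()].
#' @return "alarm"/"no_alarm" (vector for a data.frame input). The
#'   inequality is strict: a feature exactly at the threshold does not alarm.
#' @export
apply_single_feature_rule <- function(features, rule) {
  col <- paste0("f", rule$window_w)
  f <- if (is.data.frame(features)) features[[col]] else features[[col]]
  ifelse(f < rule$threshold_mlkg_h, "alarm", "no_alarm")
}
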