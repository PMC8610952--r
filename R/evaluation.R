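#' Patient-disjoint 60/10/20/10 splits
#'
#' Randomly partitions patient ids into training (60%), validation (10%),
#' test (20%) and calibration (10%) sets. Information from a given patient
#' appears in exactly one split; counts are within one patient of the target
#' proportions.
#'
#' @param patient_ids character vector of unique patient ids (>= 10).
#' @param seed integer seed.
#' @param proportions named numeric vector summing to 1.
#' @return named character vector mapping patient id to split name.
#' @export
assign_splits <- function(patient_ids, seed,
                          proportions = c(train = 0.6, validation = 0.1,
                                          test = 0.2, calibration = 0.1)) {
  patient_ids <- unique(patient_ids)
  n <- length(patient_ids)
  if (n < 10) stop("need at least 10 patients to split", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-8)
    abort_field("proportions", "must sum to 1")
  with_seed(seed, {
    shuffled <- sample(patient_ids)
    bounds <- round(cumsum(c(0, proportions)) * n)
    sizes <- diff(bounds)
    split <- rep(names(proportions), sizes)
    stats::setNames(split, shuffled)[patient_ids]
  })
}

#' Assert that splits are patient-disjoint
#'
#' @param splits output of [assign_splits()].
#' @return invisibly `TRUE`; errors if any patient appears in two splits.
#' @export
assert_patient_disjoint <- function(splits) {
  tab <- table(names(splits))
  if (any(tab > 1))
    stop("patients present in more than one split: ",
         paste(names(tab)[tab > 1], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' ROC curve and AUC
#'
#' Threshold scan over the unique score values (a prediction is positive
#' when its score is strictly greater than the threshold), plus the two
#' trivial endpoints. The AUC is the tie-corrected normalised Mann-Whitney
#' U statistic, i.e. the probability that a random case outranks a random
#' control, counting ties as one half.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels logical or "case"/"control" vector.
#' @return list of class `uo_roc`: `points` (data.frame `threshold`, `fpr`,
#'   `tpr`) ordered from the all-negative to the all-positive corner, and
#'   `auc`.
#' @export
roc_curve_and_auc <- function(scores, labels) {
  y <- .as_case_logical(labels)
  if (length(unique(y)) < 2L)
    stop("both classes are required for ROC analysis", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) mean(scores[y] > th), numeric(1))
  fpr <- vapply(thr, function(th) mean(scores[!y] > th), numeric(1))
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "uo_roc")
}

.as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  labels == "case"
}

#' @export
print.uo_roc <- function(x, ...) {
  cat(sprintf("<uo_roc> %d vertices, AUC %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Positive and negative likelihood ratios
#'
#' `LR+ = sensitivity / (1 - specificity)` and
#' `LR- = (1 - sensitivity) / specificity`. At specificity 1 the positive
#' ratio is reported as `Inf` with `lr_pos_infinite = TRUE`.
#'
#' @param sensitivity,specificity fractions in `[0, 1]`.
#' @return list with `lr_pos`, `lr_neg`, `lr_pos_infinite`.
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  check_scalar_number(sensitivity, "sensitivity", 0, 1)
  check_scalar_number(specificity, "specificity", 0, 1)
  lr_pos <- if (specificity < 1) sensitivity / (1 - specificity) else Inf
  lr_neg <- if (specificity > 0) (1 - sensitivity) / specificity else NaN
  list(lr_pos = lr_pos, lr_neg = lr_neg,
       lr_pos_infinite = !is.finite(lr_pos))
}

.operating_point <- function(threshold, tpr, fpr, kind) {
  lr <- likelihood_ratios(tpr, 1 - fpr)
  structure(list(threshold = threshold, sensitivity = tpr,
                 specificity = 1 - fpr, lr_pos = lr$lr_pos,
                 lr_neg = lr$lr_neg, kind = kind),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point %s> thr %.3f sens %.3f spec %.3f LR+ %.2f LR- %.2f\n",
              x$kind, x$threshold, x$sensitivity, x$specificity,
              x$lr_pos, x$lr_neg))
  invisible(x)
}

#' Operating point at a fixed sensitivity
#'
#' The ROC vertex with the best specificity among those reaching at least
#' the target sensitivity (ties broken toward higher sensitivity); achieved
#' sensitivity/specificity and likelihood ratios are reported.
#'
#' @param roc a `uo_roc`.
#' @param target target sensitivity (default 0.80).
#' @return an `operating_point` with `kind = "fixed_sensitivity_80"`.
#' @export
operating_point_at_sensitivity <- function(roc, target = 0.80) {
  p <- roc$points
  ok <- p$tpr >= target
  if (!any(ok)) ok <- p$tpr == max(p$tpr)
  cand <- p[ok, , drop = FALSE]
  best <- cand[order(cand$fpr, -cand$tpr), , drop = FALSE][1, ]
  .operating_point(best$threshold, best$tpr, best$fpr,
                   "fixed_sensitivity_80")
}

#' Knee-point of a ROC curve
#'
#' The ROC vertex closest (Euclidean distance) to the ideal corner of
#' perfect sensitivity and specificity; ties are broken toward higher
#' sensitivity. Youden's J (sensitivity + specificity - 1) is available as
#' an alternative criterion.
#'
#' @param roc a `uo_roc`.
#' @param method "distance" (default) or "youden".
#' @return an `operating_point` with `kind = "knee"`.
#' @export
knee_point <- function(roc, method = c("distance", "youden")) {
  method <- match.arg(method)
  p <- roc$points
  score <- if (method == "distance") -(p$fpr^2 + (1 - p$tpr)^2)
           else p$tpr - p$fpr
  best <- which(score == max(score))
  best <- best[which.max(p$tpr[best])]
  .operating_point(p$threshold[best], p$tpr[best], p$fpr[best], "knee")
}

#' Early-detection fraction
#'
#' The fraction of cases whose first alarm precedes onset by at least
#' `lead_hours`; cases that never alarm count as misses.
#'
#' @param first_alarm_hours per-case hour of first alarm (`NA` = no alarm).
#' @param onset_hours per-case onset hour.
#' @param lead_hours required lead time (default 12).
#' @return fraction in `[0, 1]`.
#' @export
early_detection_fraction <- function(first_alarm_hours, onset_hours,
                                     lead_hours = 12) {
  stopifnot(length(first_alarm_hours) == length(onset_hours))
  if (length(onset_hours) == 0L) return(NA_real_)
  hit <- !is.na(first_alarm_hours) &
    first_alarm_hours <= onset_hours - lead_hours
  mean(hit)
}

#' Resampled performance summary
#'
#' Repeatedly subsamples the test pool by patient (without replacement) and
#' summarises AUC and the two operating points as mean and standard
#' deviation, in the "0.89 +/- 0.01" reporting style. Degenerate resamples
#' containing a single class are redrawn (with a logged count).
#'
#' @param scores data.frame with `patient_id`, `score`, `label`.
#' @param n_resamples number of resamples (default 100).
#' @param fraction fraction of patients per resample (default 0.8).
#' @param seed integer seed.
#' @param target_sensitivity fixed-sensitivity operating target.
#' @return list with `auc_mean`, `auc_sd`, data.frame `metrics`
#'   (per-resample AUC, knee and fixed-sensitivity sens/spec), and
#'   `n_redrawn`.
#' @export
resampled_performance <- function(scores, n_resamples = 100, fraction = 0.8,
                                  seed = 1, target_sensitivity = 0.80) {
  ids <- unique(scores$patient_id)
  m <- max(2L, round(fraction * length(ids)))
  with_seed(seed, {
    redrawn <- 0L
    rows <- vector("list", n_resamples)
    for (k in seq_len(n_resamples)) {
      repeat {
        take <- sample(ids, m)
        sub <- scores[scores$patient_id %in% take, , drop = FALSE]
        if (length(unique(.as_case_logical(sub$label))) == 2L) break
        redrawn <- redrawn + 1L
      }
      roc <- roc_curve_and_auc(sub$score, sub$label)
      kp <- knee_point(roc)
      fx <- operating_point_at_sensitivity(roc, target_sensitivity)
      rows[[k]] <- data.frame(auc = roc$auc,
                              knee_sens = kp$sensitivity,
                              knee_spec = kp$specificity,
                              fixed_sens = fx$sensitivity,
                              fixed_spec = fx$specificity)
    }
    metrics <- do.call(rbind, rows)
    if (redrawn > 0L)
      message(sprintf("resampled_performance: %d single-class resamples redrawn",
                      redrawn))
    list(auc_mean = mean(metrics$auc), auc_sd = stats::sd(metrics$auc),
         metrics = metrics, n_redrawn = redrawn)
  })
}

#' Per-stage predictive value
#'
#' Sensitivity is computed per AKI stage against the shared control pool;
#' specificity is common to both stages. Likelihood ratios follow from
#' [likelihood_ratios()].
#'
#' @param scores data.frame with `patient_id`, `score`, `label`.
#' @param stages data.frame with `patient_id` and `stage` for cases.
#' @param threshold alarm threshold on the score.
#' @return data.frame with one row per stage present: `stage`, `n_cases`,
#'   `sensitivity`, `specificity`, `lr_pos`, `lr_neg`.
#' @export
per_stage_breakdown <- function(scores, stages, threshold) {
  y <- .as_case_logical(scores$label)
  spec <- mean(scores$score[!y] <= threshold)
  st <- stages$stage[match(scores$patient_id, stages$patient_id)]
  rows <- lapply(c(2L, 3L), function(s) {
    sel <- y & !is.na(st) & st == s
    if (!any(sel)) {
      warning(sprintf("no stage-%d cases; row omitted", s), call. = FALSE)
      return(NULL)
    }
    sens <- mean(scores$score[sel] > threshold)
    lr <- likelihood_ratios(sens, spec)
    data.frame(stage = s, n_cases = sum(sel), sensitivity = sens,
               specificity = spec, lr_pos = lr$lr_pos, lr_neg = lr$lr_neg)
  })
  do.call(rbind, rows)
}
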