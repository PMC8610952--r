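#' Maximal oliguria windows
#'
#' Finds the maximal runs of consecutive hours with urine output strictly
#' below `threshold_mlkg_h` (at or below 1e-9 for the anuria threshold 0)
#' lasting strictly longer than `min_duration_hours`. `NA` hours break runs.
#'
#' @param series an `hourly_series`, or a numeric vector of hourly
#'   ml/kg/h values.
#' @param threshold_mlkg_h flow threshold (0.5, 0.3 or 0 for anuria).
#' @param min_duration_hours required duration, strict ("> 12 h" keeps only
#'   runs of 13 h or more).
#' @return data.frame with 0-based `start_hour`, exclusive `end_hour`, and
#'   `threshold_mlkg_h`; empty if no window qualifies.
#' @export
find_oliguria_windows <- function(series, threshold_mlkg_h,
                                  min_duration_hours) {
  uo <- if (inherits(series, "hourly_series")) series$uo_mlkg_h else series
  below <- if (threshold_mlkg_h <= 1e-9) uo <= 1e-9 else uo < threshold_mlkg_h
  below[is.na(below)] <- FALSE
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths > min_duration_hours
  data.frame(start_hour = starts[keep], end_hour = ends[keep],
             threshold_mlkg_h = rep(threshold_mlkg_h, sum(keep)))
}

## rolling minimum of scr over the previous `win` hours (inclusive)
.rolling_min <- function(x, win) {
  n <- length(x)
  vapply(seq_len(n), function(h) min(x[max(1, h - win):h], na.rm = TRUE),
         numeric(1))
}

#' Detect and stage an AKIN 2/3 episode
#'
#' Evaluates the joint creatinine/urine-output criteria on an hourly series:
#'
#' * stage 2: creatinine at 200-300% of baseline (inclusive at both ends;
#'   a tie at exactly 300% counts as stage 2) together with urine output
#'   below 0.5 ml/kg/h for more than 12 h;
#' * stage 3: creatinine above 300% of baseline, or at least 4.0 mg/dl with
#'   an acute rise of at least 0.5 mg/dl within a rolling 48-h window,
#'   together with urine output below 0.3 ml/kg/h for more than 24 h or
#'   anuria for more than 12 h.
#'
#' The onset hour is the first hour at which the completed urine-output
#' duration and the creatinine clause hold jointly; the creatinine clause
#' may be met at any hour inside the oliguria window or within
#' `scr_coupling_hours` after it ends (tolerating lab-draw latency). When
#' stage-2 and stage-3 criteria complete at the same hour, stage 3 wins;
#' otherwise the earlier onset wins.
#'
#' @param series an `hourly_series`.
#' @param baseline baseline creatinine (mg/dl), positive.
#' @param scr_coupling_hours how far past the end of an oliguria window the
#'   creatinine clause may fall (default 24 h).
#' @return a list of class `aki_episode` with `patient_id`, `stage`,
#'   `onset_hour`, `scr_criterion`, `uo_criterion`; or `NULL` if the joint
#'   criteria are never met.
#' @export
stage_episode <- function(series, baseline, scr_coupling_hours = 24) {
  stopifnot(inherits(series, "hourly_series"))
  if (!is.finite(baseline) || baseline <= 0)
    abort_field("baseline", "must be positive")
  n <- series$n_hours
  scr <- series$scr_mg_dl
  if (all(is.na(scr))) return(NULL)
  ratio <- scr / baseline
  scr2_ok <- !is.na(ratio) & ratio >= 2 & ratio <= 3
  rise <- scr - .rolling_min(scr, 48)
  scr3_ok <- (!is.na(ratio) & ratio > 3) |
    (!is.na(scr) & scr >= 4.0 & rise >= 0.5)
  scr3_why <- ifelse(!is.na(ratio) & ratio > 3,
                     "ratio_gt_300", "abs_ge_4_with_rise_ge_0.5")

  candidate <- function(threshold, min_dur, scr_ok) {
    win <- find_oliguria_windows(series, threshold, min_dur)
    best <- NULL
    for (k in seq_len(nrow(win))) {
      st <- win$start_hour[k]; en <- win$end_hour[k]
      completion <- st + min_dur
      limit <- min(en - 1 + scr_coupling_hours, n - 1)
      hrs <- st:limit
      hit <- hrs[scr_ok[hrs + 1L]]
      if (length(hit) == 0L) next
      onset <- max(completion, hit[1])
      if (onset > limit) next
      if (is.null(best) || onset < best) best <- onset
    }
    best
  }

  o3a <- candidate(0.3, 24, scr3_ok)
  o3b <- candidate(0, 12, scr3_ok)
  o2  <- candidate(0.5, 12, scr2_ok)
  onset3 <- suppressWarnings(min(c(o3a, o3b), na.rm = TRUE))
  if (!length(c(o3a, o3b))) onset3 <- Inf
  onset2 <- if (is.null(o2)) Inf else o2
  if (!is.finite(onset3) && !is.finite(onset2)) return(NULL)
  if (onset3 <= onset2) {
    uo_crit <- if (!is.null(o3b) && o3b == onset3 &&
                   (is.null(o3a) || o3a > onset3)) "anuria_gt_12h"
               else if (!is.null(o3a) && o3a == onset3) "uo_lt_0.3_gt_24h"
               else "anuria_gt_12h"
    ep <- list(patient_id = series$patient_id, stage = 3L,
               onset_hour = as.integer(onset3),
               scr_criterion = scr3_why[onset3 + 1L],
               uo_criterion = uo_crit)
  } else {
    ep <- list(patient_id = series$patient_id, stage = 2L,
               onset_hour = as.integer(onset2),
               scr_criterion = "ratio_200_300",
               uo_criterion = "uo_lt_0.5_gt_12h")
  }
  class(ep) <- "aki_episode"
  ep
}

#' @export
print.aki_episode <- function(x, ...) {
  cat(sprintf("<aki_episode %s> stage %d at hour %d (%s + %s)\n",
              x$patient_id, x$stage, x$onset_hour, x$scr_criterion,
              x$uo_criterion))
  invisible(x)
}

#' Label a whole cohort
#'
#' Runs [stage_episode()] on every series and returns a tidy episode table.
#'
#' @param series list of `hourly_series`.
#' @param baselines named per-patient baseline creatinine vector.
#' @inheritParams stage_episode
#' @return data.frame with one row per stay: `patient_id`, `label`
#'   ("case"/"control"), `stage`, `onset_hour`, `scr_criterion`,
#'   `uo_criterion`.
#' @export
label_cohort <- function(series, baselines, scr_coupling_hours = 24) {
  rows <- lapply(series, function(s) {
    b <- baselines[[s$patient_id]]
    ep <- if (is.na(b)) NULL else stage_episode(s, b, scr_coupling_hours)
    if (is.null(ep))
      data.frame(patient_id = s$patient_id, label = "control",
                 stage = NA_integer_, onset_hour = NA_integer_,
                 scr_criterion = NA_character_, uo_criterion = NA_character_)
    else
      data.frame(patient_id = s$patient_id, label = "case",
                 stage = ep$stage, onset_hour = ep$onset_hour,
                 scr_criterion = ep$scr_criterion,
                 uo_criterion = ep$uo_criterion)
  })
  do.call(rbind, rows)
}

#' Truncate a case series 6 hours before onset
#'
#' Case series are cut to hours `[0, onset_hour - 6)` so that every
#' prediction made from them leads the event by at least 6 h. Onsets before
#' hour 19 leave no room for a single 12-h lookback window plus the 6-h lead
#' and are rejected (such cases are dropped upstream with a logged reason).
#' Control series are used whole and must not be passed here.
#'
#' @param series an `hourly_series` belonging to a case.
#' @param onset_hour detected onset hour (integer, >= 19).
#' @return the truncated `hourly_series` (`n_hours == onset_hour - 6`).
#' @export
truncate_case_series <- function(series, onset_hour) {
  stopifnot(inherits(series, "hourly_series"))
  if (onset_hour < 19)
    stop(sprintf("onset at hour %d leaves no 12-h window with a 6-h lead (needs onset >= 19)",
                 onset_hour), call. = FALSE)
  keep <- seq_len(min(onset_hour - 6, series$n_hours))
  for (f in c("uo_ml", "uo_mlkg_h", "scr_mg_dl", "uo_imputed", "scr_imputed"))
    series[[f]] <- series[[f]][keep]
  series$n_hours <- length(keep)
  series$truncated_at <- onset_hour - 6L
  series
}
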