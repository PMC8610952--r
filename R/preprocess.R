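#' Ideal body weight (Devine)
#'
#' Devine's formula: 50 kg (male) or 45.5 kg (female) plus 2.3 kg per inch of
#' height over 60 inches (2.54 cm/in exactly). Heights below 60 in return the
#' base weight: the formula is undefined there and a decreasing value would
#' blow up per-kg flows.
#'
#' @param sex "male" or "female" (vectorised, recycled against `height_cm`).
#' @param height_cm height in centimetres, positive.
#' @return ideal body weight in kg.
#' @export
#' @examples
#' compute_ibw("male", 152.4)    # 50
#' compute_ibw("female", 152.4)  # 45.5
compute_ibw <- function(sex, height_cm) {
  if (!all(sex %in% c("male", "female")))
    abort_field("sex", "must be \"male\" or \"female\"")
  if (any(!is.finite(height_cm)) || any(height_cm <= 0))
    abort_field("height_cm", "must be positive")
  base <- ifelse(sex == "male", 50, 45.5)
  inches <- height_cm / 2.54
  base + 2.3 * pmax(inches - 60, 0)
}

#' Resample irregular urine-output records to an hourly grid
#'
#' Each charted volume covers the interval since the previous record (or
#' admission). The volume is spread uniformly over that interval and
#' attributed to the 0-based hour bins `[h, h+1)` it overlaps, pro-rated by
#' overlap fraction, so hourly totals conserve the recorded volume exactly.
#' Intervals longer than `max_gap_hours` are not filled: their hours stay
#' `NA` and the series is flagged `uo_gap_gt_9h` for exclusion. Hours after
#' the last record (or never covered by any record) are also `NA`.
#'
#' @param uo_records data.frame with `time_hr` (hours since admission,
#'   sorted, within the stay) and `volume_ml` (non-negative).
#' @param los_hours length of stay in hours.
#' @param max_gap_hours charting gap above which the stay is flagged
#'   (strictly greater than; default 9).
#' @return list with `uo_ml` (length `ceiling(los_hours)`), logical
#'   `imputed` (hour filled by redistribution rather than a 1-h record), and
#'   character `flags`.
#' @export
resample_uo_hourly <- function(uo_records, los_hours, max_gap_hours = 9) {
  n <- as.integer(ceiling(los_hours))
  uo <- rep(0, n)
  covered <- rep(FALSE, n)
  imputed <- rep(FALSE, n)
  flags <- character(0)
  if (is.null(uo_records) || nrow(uo_records) == 0L) {
    return(list(uo_ml = rep(NA_real_, n), imputed = rep(TRUE, n),
                flags = "uo_gap_gt_9h"))
  }
  stopifnot(!is.unsorted(uo_records$time_hr))
  if (any(uo_records$volume_ml < 0))
    abort_field("volume_ml", "must be non-negative")
  prev <- 0
  for (k in seq_len(nrow(uo_records))) {
    t <- uo_records$time_hr[k]
    v <- uo_records$volume_ml[k]
    gap <- t - prev
    if (gap <= 0) next
    if (gap > max_gap_hours) {
      flags <- c(flags, "uo_gap_gt_9h")
      prev <- t
      next
    }
    h0 <- floor(prev)
    h1 <- min(ceiling(t) - 1, n - 1)
    hrs <- h0:h1
    overlap <- pmin(t, hrs + 1) - pmax(prev, hrs)
    keep <- overlap > 1e-12
    uo[hrs[keep] + 1L] <- uo[hrs[keep] + 1L] + v * overlap[keep] / gap
    covered[hrs[keep] + 1L] <- TRUE
    if (gap > 1 + 1e-9 || prev %% 1 > 1e-9 || t %% 1 > 1e-9)
      imputed[hrs[keep] + 1L] <- TRUE
    prev <- t
  }
  if (los_hours - prev > max_gap_hours) flags <- c(flags, "uo_gap_gt_9h")
  uo[!covered] <- NA_real_
  imputed[!covered] <- TRUE
  list(uo_ml = uo, imputed = imputed, flags = unique(flags))
}

#' Forward-drag creatinine measurements to an hourly grid
#'
#' Each hour carries the most recent measurement at or before it; hours
#' before the first measurement carry the first value (back-filled, flagged
#' imputed). Gaps between consecutive measurements of more than
#' `max_gap_hours` (4 days) flag the stay `scr_gap_gt_4d`; a stay with no
#' measurement at all gets the same flag and an all-`NA` series.
#'
#' @param scr_records data.frame with `time_hr` (sorted) and `scr_mg_dl`
#'   (positive).
#' @param los_hours length of stay in hours.
#' @param max_gap_hours maximum tolerated gap between measurements
#'   (strictly greater than; default 96).
#' @return list with `scr_mg_dl`, logical `imputed`, character `flags`.
#' @export
forward_fill_scr <- function(scr_records, los_hours, max_gap_hours = 96) {
  n <- as.integer(ceiling(los_hours))
  if (is.null(scr_records) || nrow(scr_records) == 0L) {
    return(list(scr_mg_dl = rep(NA_real_, n), imputed = rep(TRUE, n),
                flags = "scr_gap_gt_4d"))
  }
  stopifnot(!is.unsorted(scr_records$time_hr))
  if (any(scr_records$scr_mg_dl <= 0))
    abort_field("scr_mg_dl", "must be positive")
  flags <- character(0)
  if (any(diff(scr_records$time_hr) > max_gap_hours))
    flags <- c(flags, "scr_gap_gt_4d")
  hours <- 0:(n - 1)
  idx <- findInterval(hours, scr_records$time_hr)
  scr <- scr_records$scr_mg_dl[pmax(idx, 1L)]
  measured <- hours %in% floor(scr_records$time_hr)
  list(scr_mg_dl = scr, imputed = !measured, flags = flags)
}

#' Baseline serum creatinine
#'
#' The lowest reported ICU creatinine for the patient; for patients with
#' several ICU stays, the minimum across all stays.
#'
#' @param scr_values numeric vector of measurements, or a list of per-stay
#'   vectors / data.frames with an `scr_mg_dl` column.
#' @return the minimum value (mg/dl).
#' @export
baseline_scr <- function(scr_values) {
  if (is.list(scr_values) && !is.data.frame(scr_values))
    scr_values <- unlist(lapply(scr_values, function(x)
      if (is.data.frame(x)) x$scr_mg_dl else x))
  if (is.data.frame(scr_values)) scr_values <- scr_values$scr_mg_dl
  scr_values <- scr_values[is.finite(scr_values)]
  if (length(scr_values) == 0L)
    stop("no creatinine values: baseline undefined", call. = FALSE)
  min(scr_values)
}

#' Build the hourly series for one stay
#'
#' Combines [resample_uo_hourly()], ideal-body-weight normalisation and
#' [forward_fill_scr()] into a single per-stay hourly object.
#'
#' @param stay a `raw_stay`.
#' @param max_uo_gap_hours,max_scr_gap_hours missingness limits forwarded to
#'   the resamplers.
#' @return an object of class `hourly_series`.
#' @export
preprocess_stay <- function(stay, max_uo_gap_hours = 9,
                            max_scr_gap_hours = 96) {
  ibw <- compute_ibw(stay$sex, stay$height_cm)
  uo <- resample_uo_hourly(stay$uo_records, stay$los_hours, max_uo_gap_hours)
  scr <- forward_fill_scr(stay$scr_records, stay$los_hours, max_scr_gap_hours)
  structure(list(
    patient_id = stay$patient_id,
    center_id = stay$center_id,
    los_hours = stay$los_hours,
    n_hours = length(uo$uo_ml),
    ibw_kg = ibw,
    dialysis = isTRUE(stay$dialysis),
    uo_ml = uo$uo_ml,
    uo_mlkg_h = uo$uo_ml / ibw,
    scr_mg_dl = scr$scr_mg_dl,
    uo_imputed = uo$imputed,
    scr_imputed = scr$imputed,
    flags = unique(c(uo$flags, scr$flags))
  ), class = "hourly_series")
}

#' @export
print.hourly_series <- function(x, ...) {
  cat(sprintf("<hourly_series %s> %d h, IBW %.1f kg, median UO %.2f ml/kg/h%s\n",
              x$patient_id, x$n_hours, x$ibw_kg,
              stats::median(x$uo_mlkg_h, na.rm = TRUE),
              if (length(x$flags)) paste0(", flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Preprocess a whole cohort
#'
#' @param cohort a `uo_cohort` (or list of `raw_stay`).
#' @inheritParams preprocess_stay
#' @return list with `series` (list of `hourly_series`) and `baselines`
#'   (named vector of per-patient baseline creatinine, minimum across all of
#'   the patient's stays).
#' @export
preprocess_cohort <- function(cohort, max_uo_gap_hours = 9,
                              max_scr_gap_hours = 96) {
  series <- lapply(cohort, preprocess_stay,
                   max_uo_gap_hours = max_uo_gap_hours,
                   max_scr_gap_hours = max_scr_gap_hours)
  ids <- vapply(cohort, function(s) s$patient_id, character(1))
  by_patient <- split(lapply(cohort, function(s) s$scr_records), ids)
  baselines <- vapply(by_patient, function(recs) {
    vals <- unlist(lapply(recs, function(r) r$scr_mg_dl))
    if (length(vals)) min(vals) else NA_real_
  }, numeric(1))
  list(series = series, baselines = baselines)
}

.exclusion_order <- c("los_lt_24h", "baseline_scr_lt_0.5",
                      "community_acquired_aki", "dialysis",
                      "uo_gap_gt_9h", "scr_gap_gt_4d", "low_volume_center")

#' Apply the cohort exclusion criteria
#'
#' Removes stays with length of stay below 24 h, baseline creatinine below
#' 0.5 mg/dl, community-acquired AKI (stage-2/3 criteria already complete
#' within the first `ca_horizon_hours` of the stay), dialysis, urine-output
#' charting gaps over 9 h, creatinine gaps over 4 days, or admission to a
#' center contributing fewer than `min_center_volume` stays to the input
#' cohort. Every reason that applies is reported; a stay is excluded iff its
#' reason list is non-empty.
#'
#' @param series list of `hourly_series` (from [preprocess_cohort()]).
#' @param baselines named per-patient baseline creatinine vector.
#' @param min_los_hours,min_baseline,min_center_volume,ca_horizon_hours
#'   exclusion limits.
#' @return list with `kept` (the surviving series), `baselines` (subset),
#'   and `report` (one row per stay: `patient_id`, `excluded`, `reasons`
#'   (semicolon-joined), `first_reason` for waterfall accounting).
#' @export
apply_exclusions <- function(series, baselines,
                             min_los_hours = 24, min_baseline = 0.5,
                             min_center_volume = 50, ca_horizon_hours = 12) {
  centers <- vapply(series, function(s) s$center_id, character(1))
  center_n <- table(centers)
  rows <- lapply(series, function(s) {
    reasons <- character(0)
    if (s$los_hours < min_los_hours) reasons <- c(reasons, "los_lt_24h")
    b <- baselines[[s$patient_id]]
    if (is.na(b) || b < min_baseline)
      reasons <- c(reasons, "baseline_scr_lt_0.5")
    if (!is.na(b)) {
      ep <- stage_episode(s, b)
      if (!is.null(ep) && ep$onset_hour <= ca_horizon_hours)
        reasons <- c(reasons, "community_acquired_aki")
    }
    if (s$dialysis) reasons <- c(reasons, "dialysis")
    if ("uo_gap_gt_9h" %in% s$flags) reasons <- c(reasons, "uo_gap_gt_9h")
    if ("scr_gap_gt_4d" %in% s$flags) reasons <- c(reasons, "scr_gap_gt_4d")
    if (center_n[[s$center_id]] < min_center_volume)
      reasons <- c(reasons, "low_volume_center")
    reasons <- .exclusion_order[.exclusion_order %in% reasons]
    data.frame(patient_id = s$patient_id,
               excluded = length(reasons) > 0L,
               reasons = paste(reasons, collapse = ";"),
               first_reason = if (length(reasons)) reasons[1] else NA_character_)
  })
  report <- do.call(rbind, rows)
  kept <- series[!report$excluded]
  list(kept = kept,
       baselines = baselines[vapply(kept, function(s) s$patient_id, character(1))],
       report = report)
}
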