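#' Configuration for the synthetic ICU cohort generator
#'
#' Bundles and validates the parameters of [generate_cohort()]. Defaults
#' describe a cohort in which roughly 3% of patients develop an ICU-acquired
#' AKIN stage-2/3 episode, urine output is charted at irregular intervals
#' (geometric-like gaps truncated so that default cohorts survive the 9-hour
#' missingness exclusion), and creatinine is drawn about once a day with extra
#' draws while a patient deteriorates.
#'
#' @param n_patients number of ICU stays to simulate (one stay per patient).
#' @param prevalence target fraction of stage-2/3 cases, in `[0, 1]`.
#' @param n_centers number of ICU centers patients are assigned to.
#' @param uo_charting_gap_hours mean gap between urine-output chart entries
#'   (hours). A value of 1 produces gap-free hourly charting.
#' @param uo_gap_max_hours truncation point for charting gaps (hours).
#' @param allow_long_gaps if `TRUE`, a small fraction of gaps of 10-14 h are
#'   drawn so that the 9-hour missingness exclusion is exercised.
#' @param scr_interval_hours typical spacing of creatinine laboratory draws.
#' @param los_hours_range length-2 numeric, min/max length of stay in hours.
#' @param noise_sd multiplicative lognormal noise scale (sdlog) for hourly
#'   urine output; creatinine noise is `0.2 * noise_sd`. Zero gives fully
#'   deterministic trajectories.
#' @param control_uo_median median of the between-patient baseline diuresis
#'   distribution (ml/kg/h); lognormal with sdlog `control_uo_sdlog`.
#' @param control_uo_sdlog between-patient sdlog of baseline diuresis.
#' @param control_dip_rate fraction of control stays containing a transient
#'   (3-10 h, shorter than any AKIN duration) oliguric dip.
#' @param case_stage3_fraction fraction of injected cases at stage 3.
#' @param anuria_fraction fraction of stage-3 cases injected via the anuria
#'   clause rather than the `< 0.3 ml/kg/h` clause.
#' @param dialysis_rate fraction of stays flagged as receiving dialysis
#'   (metadata only; such stays are removed by [apply_exclusions()]).
#' @param seed integer seed; identical configs produce identical cohorts.
#'
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          prevalence = 0.03,
                          n_centers = 4L,
                          uo_charting_gap_hours = 2,
                          uo_gap_max_hours = 8,
                          allow_long_gaps = FALSE,
                          scr_interval_hours = 24,
                          los_hours_range = c(36, 168),
                          noise_sd = 0.35,
                          control_uo_median = 1.1,
                          control_uo_sdlog = 0.35,
                          control_dip_rate = 0.3,
                          case_stage3_fraction = 0.4,
                          anuria_fraction = 0.3,
                          dialysis_rate = 0,
                          seed = 1L) {
  check_scalar_number(n_patients, "n_patients", lower = 1, integer = TRUE)
  check_scalar_number(prevalence, "prevalence", lower = 0, upper = 1)
  check_scalar_number(n_centers, "n_centers", lower = 1, integer = TRUE)
  check_scalar_number(uo_charting_gap_hours, "uo_charting_gap_hours", lower = 1)
  check_scalar_number(uo_gap_max_hours, "uo_gap_max_hours", lower = 1)
  check_scalar_number(scr_interval_hours, "scr_interval_hours", lower = 1)
  if (!is.numeric(los_hours_range) || length(los_hours_range) != 2L ||
      any(los_hours_range <= 0) || diff(los_hours_range) < 0)
    abort_field("los_hours_range", "must be a positive increasing (min, max) pair")
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(control_uo_median, "control_uo_median", lower = 1e-6)
  check_scalar_number(control_uo_sdlog, "control_uo_sdlog", lower = 0)
  check_scalar_number(control_dip_rate, "control_dip_rate", lower = 0, upper = 1)
  check_scalar_number(case_stage3_fraction, "case_stage3_fraction", lower = 0, upper = 1)
  check_scalar_number(anuria_fraction, "anuria_fraction", lower = 0, upper = 1)
  check_scalar_number(dialysis_rate, "dialysis_rate", lower = 0, upper = 1)
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(
    list(n_patients = as.integer(n_patients), prevalence = prevalence,
         n_centers = as.integer(n_centers),
         uo_charting_gap_hours = uo_charting_gap_hours,
         uo_gap_max_hours = uo_gap_max_hours,
         allow_long_gaps = isTRUE(allow_long_gaps),
         scr_interval_hours = scr_interval_hours,
         los_hours_range = los_hours_range,
         noise_sd = noise_sd,
         control_uo_median = control_uo_median,
         control_uo_sdlog = control_uo_sdlog,
         control_dip_rate = control_dip_rate,
         case_stage3_fraction = case_stage3_fraction,
         anuria_fraction = anuria_fraction,
         dialysis_rate = dialysis_rate,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Strongly separable benchmark configuration
#'
#' A preset cohort configuration used for constructed-signal benchmarks:
#' low-noise controls around 1 ml/kg/h with no transient dips, and stage-3
#' cases with a long (> 24 h) sustained oliguric phase at 0.15 ml/kg/h, so
#' that pre-onset windows of cases and controls are cleanly distinguishable.
#'
#' @inheritParams cohort_config
#' @return a `cohort_config`.
#' @export
separable_cohort_config <- function(n_patients = 2000L, prevalence = 0.03,
                                    seed = 1L) {
  cohort_config(n_patients = n_patients, prevalence = prevalence,
                uo_charting_gap_hours = 2, noise_sd = 0.10,
                control_uo_median = 1.0, control_uo_sdlog = 0.25,
                control_dip_rate = 0, case_stage3_fraction = 1,
                anuria_fraction = 0, los_hours_range = c(48, 120),
                seed = seed)
}

## hours covered by the record interval (prev, t]: 0-based hour h covers
## [h, h+1); with integer charting times this is prev..t-1
.interval_hours <- function(prev, t) seq.int(prev, t - 1L)

## chart an hourly per-kg flow into irregular volume records
.chart_uo <- function(flow_mlkg, ibw, cfg) {
  los <- length(flow_mlkg)
  flow_ml <- flow_mlkg * ibw
  times <- integer(0)
  t <- 0L
  while (t < los) {
    if (cfg$uo_charting_gap_hours <= 1) {
      gap <- 1L
    } else {
      gap <- 1L + stats::rgeom(1L, 1 / cfg$uo_charting_gap_hours)
      gap <- min(gap, as.integer(cfg$uo_gap_max_hours))
      if (cfg$allow_long_gaps && stats::runif(1) < 0.05)
        gap <- sample(10:14, 1L)
    }
    t <- min(t + gap, los)
    times <- c(times, t)
  }
  prev <- c(0L, times[-length(times)])
  vols <- vapply(seq_along(times), function(k)
    sum(flow_ml[.interval_hours(prev[k], times[k]) + 1L]), numeric(1))
  data.frame(time_hr = as.numeric(times), volume_ml = vols)
}

## baseline (non-AKI) hourly diuresis trajectory in ml/kg/h
.control_flow <- function(los, cfg) {
  base <- stats::rlnorm(1, log(cfg$control_uo_median), cfg$control_uo_sdlog)
  flow <- base * stats::rlnorm(los, 0, cfg$noise_sd)
  if (stats::runif(1) < cfg$control_dip_rate && los > 16) {
    dip_len <- sample(3:10, 1L)
    dip_start <- sample.int(los - dip_len, 1L)
    level <- stats::runif(1, 0.15, 0.45)
    idx <- dip_start + seq_len(dip_len)
    flow[idx] <- level * stats::rlnorm(dip_len, 0, cfg$noise_sd / 2)
  }
  pmax(flow, 0)
}

## routine creatinine lab schedule over a stay
.control_scr <- function(los, cfg) {
  times <- 0
  t <- 0
  while (t < los - 1) {
    t <- t + cfg$scr_interval_hours * stats::runif(1, 0.8, 1.2)
    if (t < los) times <- c(times, round(t))
  }
  base <- stats::runif(1, 0.6, 1.3)
  vals <- base * stats::rlnorm(length(times), 0, 0.2 * cfg$noise_sd)
  data.frame(time_hr = as.numeric(times), scr_mg_dl = pmax(vals, 0.5))
}

.new_stay <- function(patient_id, center_id, cfg, los) {
  sex <- if (stats::runif(1) < 0.63) "male" else "female"
  height <- if (sex == "male") stats::runif(1, 160, 195) else stats::runif(1, 150, 183)
  admit <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
    round(stats::runif(1, 0, 364 * 24)) * 3600
  ibw <- compute_ibw(sex, height)
  flow <- .control_flow(los, cfg)
  stay <- list(
    patient_id = patient_id,
    center_id = center_id,
    sex = sex,
    height_cm = height,
    admit_time = admit,
    discharge_time = admit + los * 3600,
    los_hours = los,
    died_in_hospital = stats::runif(1) < 0.055,
    dialysis = stats::runif(1) < cfg$dialysis_rate,
    ckd = stats::runif(1) < 0.086,
    heart_disease = stats::runif(1) < 0.077,
    dm2 = stats::runif(1) < 0.021,
    uo_records = .chart_uo(flow, ibw, cfg),
    scr_records = .control_scr(los, cfg),
    truth = list(label = "control", stage = NA_integer_,
                 onset_hour = NA_real_, anuria = FALSE)
  )
  class(stay) <- "raw_stay"
  stay
}

#' @export
print.raw_stay <- function(x, ...) {
  cat(sprintf("<raw_stay %s> center %s, %s, %.0f cm, LOS %.0f h, %d UO / %d sCr records, truth: %s\n",
              x$patient_id, x$center_id, x$sex, x$height_cm, x$los_hours,
              nrow(x$uo_records), nrow(x$scr_records), x$truth$label))
  invisible(x)
}

#' Inject an AKIN stage-2/3 episode into a stay
#'
#' Rewrites the urine-output and creatinine trajectories of a stay so that,
#' after hourly preprocessing and joint labeling, the stay is assigned the
#' requested stage with a detected onset within one hour of `onset_hour`.
#' The oliguric phase starts `d` hours before onset (`d` = 12 for stage 2 and
#' the anuria variant, 24 for the stage-3 low-flow clause) so that the
#' required duration is exactly complete at the onset hour, and the
#' creatinine trajectory crosses the stage's multiplier relative to the
#' stay's minimum creatinine shortly after oliguria begins. Charting times of
#' the original record stream are preserved; volumes are re-aggregated.
#'
#' Randomness (noise, when `noise_sd > 0`) is drawn from the caller's RNG
#' stream, so results are reproducible under an enclosing seed.
#'
#' @param stay a `raw_stay`.
#' @param stage 2 or 3.
#' @param onset_hour hour (integer, 0-based) at which the diagnostic criteria
#'   become complete.
#' @param anuria for stage 3, use the "anuria > 12 h" clause instead of the
#'   "< 0.3 ml/kg/h > 24 h" clause.
#' @param noise_sd multiplicative lognormal noise applied to the rewritten
#'   hours (oliguric hours are kept below the stage's threshold so the
#'   injected episode always satisfies its UO criterion).
#' @return the modified `raw_stay`, with `truth` updated.
#' @export
inject_aki_episode <- function(stay, stage, onset_hour, anuria = FALSE,
                               noise_sd = 0) {
  if (!stage %in% c(2L, 3L)) abort_field("stage", "must be 2 or 3")
  onset_hour <- as.integer(onset_hour)
  dur <- if (stage == 2L || anuria) 12L else 24L
  s <- onset_hour - dur
  los <- as.integer(stay$los_hours)
  if (s < 1L || onset_hour + 1L > los)
    stop(sprintf("stay %s (LOS %d h) too short for a stage-%d episode at onset %d (oliguria would span hours %d..%d)",
                 stay$patient_id, los, stage, onset_hour, s, onset_hour),
         call. = FALSE)

  ibw <- compute_ibw(stay$sex, stay$height_cm)
  flow <- resample_uo_hourly(stay$uo_records, los)$uo_ml / ibw
  flow[is.na(flow)] <- stats::median(flow, na.rm = TRUE)
  ## the injected window must be the stay's only qualifying oliguria run, so
  ## hours outside it are kept above the 0.5 ml/kg/h threshold
  flow <- pmax(flow, 0.55)

  level <- if (stage == 2L) 0.4 else if (anuria) 0 else 0.15
  hold_end <- min(onset_hour + 3L, los - 1L)  # a few oliguric hours past onset
  idx <- (s:hold_end) + 1L
  noisy <- level * stats::rlnorm(length(idx), 0, noise_sd)
  flow[idx] <- if (stage == 2L) pmin(pmax(noisy, 0.31), 0.49)
               else if (anuria) 0 else pmin(noisy, 0.29)
  ## short ramps into and out of the oliguric phase
  pre <- intersect(c(s - 2L, s - 1L), 1:(los - 1L))
  if (length(pre)) flow[pre + 1L] <- pmax(level, 0.55) + 0.2 * rev(seq_along(pre))
  post <- intersect(hold_end + 1:2, 0:(los - 1L))
  if (length(post)) flow[post + 1L] <- pmax(level, 0.6) + 0.25 * seq_along(post)

  ## re-chart at the stay's original record times
  times <- stay$uo_records$time_hr
  prev <- c(0, times[-length(times)])
  flow_ml <- flow * ibw
  stay$uo_records$volume_ml <- vapply(seq_along(times), function(k)
    sum(flow_ml[.interval_hours(prev[k], times[k]) + 1L]), numeric(1))

  ## creatinine: keep pre-episode draws, then a stage-dependent rise relative
  ## to the realized pre-episode minimum (the labeling baseline)
  pre_scr <- stay$scr_records[stay$scr_records$time_hr < s, , drop = FALSE]
  if (nrow(pre_scr) == 0L)
    pre_scr <- data.frame(time_hr = 0, scr_mg_dl = stats::runif(1, 0.6, 1.3))
  b <- min(pre_scr$scr_mg_dl)
  ep_times <- s + c(2, 4, 6, 8)
  later <- seq(onset_hour + 12, los - 1, by = 24)
  ep_times <- sort(unique(c(ep_times, later)))
  ep_times <- ep_times[ep_times < los]
  scr_noise <- 0.2 * noise_sd
  val_at <- function(t) {
    if (stage == 2L) {
      if (t <= s + 6) {            # linear rise crossing 2x at ~ s+6
        v <- b + (2.4 * b - b) * (t - s) / 6
      } else if (t <= onset_hour + 12) {
        v <- 2.4 * b
      } else {                      # slow recovery, never below baseline
        v <- max(1.1 * b, 2.4 * b - (t - onset_hour - 12) * 0.02 * b)
      }
      v <- v * stats::rlnorm(1, 0, scr_noise)
      if (t >= s + 6 && t <= onset_hour + 12) v <- min(max(v, 2.1 * b), 2.85 * b)
      v
    } else {
      ## step rise that skips the 200-300% band between consecutive draws
      if (t <= s + 2) {
        v <- b * stats::rlnorm(1, 0, scr_noise)
      } else if (t <= onset_hour + 12) {
        v <- 3.6 * b * stats::rlnorm(1, 0, scr_noise)
        v <- max(v, 3.1 * b)
      } else {
        v <- max(1.1 * b, 3.6 * b - (t - onset_hour - 12) * 0.02 * b)
      }
      v
    }
  }
  ep_vals <- vapply(ep_times, val_at, numeric(1))
  stay$scr_records <- rbind(pre_scr,
                            data.frame(time_hr = ep_times, scr_mg_dl = ep_vals))
  stay$scr_records <- stay$scr_records[order(stay$scr_records$time_hr), ]
  rownames(stay$scr_records) <- NULL

  stay$died_in_hospital <- stats::runif(1) < 0.30
  stay$truth <- list(label = "case", stage = as.integer(stage),
                     onset_hour = onset_hour, anuria = isTRUE(anuria))
  stay
}

#' Generate a synthetic ICU cohort
#'
#' Simulates `config$n_patients` ICU stays with irregularly charted urine
#' output, periodic creatinine labs, and an expected fraction
#' `config$prevalence` of stays carrying an injected ICU-acquired AKIN
#' stage-2/3 episode (onset at hour 30 or later, leaving room for a 12-h
#' lookback plus a 6-h lead). Control stays may contain transient oliguric
#' dips shorter than any AKIN duration, so downstream labeling is genuinely
#' exercised. Output is byte-identical for identical configurations.
#'
#' @param config a [cohort_config()].
#' @return a list of `raw_stay` objects (class `uo_cohort`), with the
#'   configuration attached as attribute `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, as.list(config))
  with_seed(config$seed, {
    stays <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%05d", i)
      center <- sprintf("C%02d", sample.int(config$n_centers, 1L))
      is_case <- stats::runif(1) < config$prevalence
      if (is_case) {
        stage <- if (stats::runif(1) < config$case_stage3_fraction) 3L else 2L
        anuria <- stage == 3L && stats::runif(1) < config$anuria_fraction
        los_draw <- round(stats::runif(1, config$los_hours_range[1],
                                       config$los_hours_range[2]))
        onset <- round(stats::runif(1, 30, max(30, los_draw - 14)))
        los <- max(los_draw, onset + 14)
        stay <- .new_stay(pid, center, config, los)
        stay <- inject_aki_episode(stay, stage, onset, anuria = anuria,
                                   noise_sd = config$noise_sd)
      } else {
        los <- round(stats::runif(1, config$los_hours_range[1],
                                  config$los_hours_range[2]))
        stay <- .new_stay(pid, center, config, los)
      }
      stays[[i]] <- stay
    }
    structure(stays, class = "uo_cohort", config = config)
  })
}

#' @export
print.uo_cohort <- function(x, ...) {
  n_case <- sum(vapply(x, function(s) s$truth$label == "case", logical(1)))
  cat(sprintf("<uo_cohort> %d stays (%d injected cases, %.1f%%)\n",
              length(x), n_case, 100 * n_case / max(1, length(x))))
  invisible(x)
}

#' Ground-truth labels of a synthetic cohort
#'
#' @param cohort a `uo_cohort`.
#' @return data.frame with `patient_id`, `label`, `stage`, `onset_hour`.
#' @export
cohort_truth <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s)
    data.frame(patient_id = s$patient_id, label = s$truth$label,
               stage = s$truth$stage, onset_hour = s$truth$onset_hour)))
}
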