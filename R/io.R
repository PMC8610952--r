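#' Write a cohort as long-format CSV tables
#'
#' Emits the pipeline's file contract: `patients.csv` (demographics and
#' admission metadata), `urine_output.csv` (patient id, ISO-8601 timestamp,
#' volume in ml), `creatinine.csv` (patient id, timestamp, mg/dl), and --
#' for synthetic cohorts -- `truth.csv` with the generator's ground-truth
#' labels, which the analysis pipeline itself never reads.
#'
#' @param cohort a `uo_cohort` or list of `raw_stay`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  patients <- do.call(rbind, lapply(cohort, function(s)
    data.frame(patient_id = s$patient_id, center_id = s$center_id,
               sex = s$sex, height_cm = s$height_cm,
               admit_time = iso(s$admit_time),
               discharge_time = iso(s$discharge_time),
               died_in_hospital = s$died_in_hospital,
               dialysis = isTRUE(s$dialysis),
               ckd = isTRUE(s$ckd), heart_disease = isTRUE(s$heart_disease),
               dm2 = isTRUE(s$dm2))))
  uo <- do.call(rbind, lapply(cohort, function(s)
    data.frame(patient_id = s$patient_id,
               time = iso(s$admit_time + s$uo_records$time_hr * 3600),
               volume_ml = s$uo_records$volume_ml)))
  scr <- do.call(rbind, lapply(cohort, function(s)
    data.frame(patient_id = s$patient_id,
               time = iso(s$admit_time + s$scr_records$time_hr * 3600),
               scr_mg_dl = s$scr_records$scr_mg_dl)))
  paths <- file.path(dir, c("patients.csv", "urine_output.csv",
                            "creatinine.csv", "truth.csv"))
  utils::write.csv(patients, paths[1], row.names = FALSE)
  utils::write.csv(uo, paths[2], row.names = FALSE)
  utils::write.csv(scr, paths[3], row.names = FALSE)
  utils::write.csv(cohort_truth(cohort), paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from the long-format CSV tables
#'
#' Inverse of [write_cohort_csv()]; accepts user-supplied extracts with the
#' same headers. `truth.csv` is ignored even if present.
#'
#' @param dir directory holding `patients.csv`, `urine_output.csv`,
#'   `creatinine.csv`.
#' @return a `uo_cohort`.
#' @export
read_cohort_csv <- function(dir) {
  need <- file.path(dir, c("patients.csv", "urine_output.csv",
                           "creatinine.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing input tables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  patients <- utils::read.csv(need[1])
  uo <- utils::read.csv(need[2])
  scr <- utils::read.csv(need[3])
  parse_t <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ",
                                    tz = "UTC")
  uo$time <- parse_t(uo$time); scr$time <- parse_t(scr$time)
  stays <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    admit <- parse_t(p$admit_time); disch <- parse_t(p$discharge_time)
    u <- uo[uo$patient_id == p$patient_id, ]
    u <- u[order(u$time), ]
    sc <- scr[scr$patient_id == p$patient_id, ]
    sc <- sc[order(sc$time), ]
    stay <- list(
      patient_id = p$patient_id, center_id = p$center_id, sex = p$sex,
      height_cm = p$height_cm, admit_time = admit, discharge_time = disch,
      los_hours = as.numeric(difftime(disch, admit, units = "hours")),
      died_in_hospital = isTRUE(p$died_in_hospital),
      dialysis = isTRUE(p$dialysis), ckd = isTRUE(p$ckd),
      heart_disease = isTRUE(p$heart_disease), dm2 = isTRUE(p$dm2),
      uo_records = data.frame(
        time_hr = as.numeric(difftime(u$time, admit, units = "hours")),
        volume_ml = u$volume_ml),
      scr_records = data.frame(
        time_hr = as.numeric(difftime(sc$time, admit, units = "hours")),
        scr_mg_dl = sc$scr_mg_dl),
      truth = list(label = NA_character_, stage = NA_integer_,
                   onset_hour = NA_real_, anuria = NA))
    class(stay) <- "raw_stay"
    stay
  })
  structure(stays, class = "uo_cohort")
}

#' Write the hourly series of a cohort as one tidy CSV
#'
#' @param series list of `hourly_series`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_hourly_csv <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(patient_id = s$patient_id, hour = seq_len(s$n_hours) - 1L,
               uo_mlkg_h = s$uo_mlkg_h, scr_mg_dl = s$scr_mg_dl,
               uo_imputed = s$uo_imputed, scr_imputed = s$scr_imputed)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
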