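# shared fixtures, built in code at test time

# wrap a bare hourly urine-output (and optional creatinine) vector as a series
make_series <- function(uo, scr = rep(1, length(uo)), id = "PX",
                        center = "C01", dialysis = FALSE,
                        los = length(uo)) {
  structure(list(
    patient_id = id, center_id = center, los_hours = los,
    n_hours = length(uo), ibw_kg = 70, dialysis = dialysis,
    uo_ml = uo * 70, uo_mlkg_h = uo, scr_mg_dl = scr,
    uo_imputed = rep(FALSE, length(uo)),
    scr_imputed = rep(FALSE, length(uo)),
    flags = character(0)), class = "hourly_series")
}

# brute-force oracle for the minimum moving average
mma_oracle <- function(uo, w) {
  n <- length(uo)
  min(vapply(1:(n - w + 1), function(s) mean(uo[s:(s + w - 1)]), numeric(1)))
}

# pair-counting AUC oracle: P(case score > control score), ties = 1/2
auc_oracle <- function(scores, labels) {
  y <- if (is.logical(labels)) labels else labels == "case"
  cs <- scores[y]; ct <- scores[!y]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}

# brute-force oliguria windows: maximal runs via explicit scan
oliguria_oracle <- function(uo, threshold, min_dur) {
  below <- if (threshold <= 1e-9) uo <= 1e-9 else uo < threshold
  below[is.na(below)] <- FALSE
  out <- NULL
  s <- NA
  for (h in seq_along(below)) {
    if (below[h] && is.na(s)) s <- h
    if ((!below[h] || h == length(below)) && !is.na(s)) {
      e <- if (below[h]) h else h - 1
      if (e - s + 1 > min_dur)
        out <- rbind(out, c(start_hour = s - 1, end_hour = e))
      s <- NA
    }
  }
  out
}

# a noise-free, gap-free configuration so injected episodes are exactly
# recoverable
noisefree_config <- function(n, prevalence, seed,
                             los = c(48, 120)) {
  cohort_config(n_patients = n, prevalence = prevalence,
                uo_charting_gap_hours = 1, noise_sd = 0,
                los_hours_range = los, seed = seed)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
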