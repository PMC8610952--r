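test_that("Devine ideal body weight matches direct evaluation", {
  expect_equal(compute_ibw("male", 152.4), 50)
  expect_equal(compute_ibw("female", 152.4), 45.5)
  expect_equal(compute_ibw("male", 180), 50 + 2.3 * (180 / 2.54 - 60))
  # floor below 60 inches: base weight, not a decreasing value
  expect_equal(compute_ibw("male", 140), 50)
  expect_equal(compute_ibw("female", 100), 45.5)
  expect_error(compute_ibw("male", -170), "height_cm")
  expect_error(compute_ibw("other", 170), "sex")
})

test_that("charted volumes are redistributed uniformly over their gap", {
  r <- resample_uo_hourly(data.frame(time_hr = 3, volume_ml = 300), 3)
  expect_equal(r$uo_ml, c(100, 100, 100))
  expect_true(all(r$imputed))
  expect_length(r$flags, 0)
})

test_that("hourly records pass through unchanged", {
  rec <- data.frame(time_hr = 1:6, volume_ml = c(50, 60, 40, 80, 70, 90))
  r <- resample_uo_hourly(rec, 6)
  expect_equal(r$uo_ml, rec$volume_ml)
  expect_false(any(r$imputed))
})

test_that("sub-hour record times are prorated by bin overlap", {
  # 150 ml over (0, 1.5]: rate 100 ml/h -> 100 in hour 0, 50 in hour 1
  r <- resample_uo_hourly(data.frame(time_hr = c(1.5, 2),
                                     volume_ml = c(150, 60)), 2)
  expect_equal(r$uo_ml, c(100, 50 + 60))
  expect_equal(sum(r$uo_ml), 210)
})

test_that("gaps over 9 hours flag the stay instead of being filled", {
  r <- resample_uo_hourly(data.frame(time_hr = c(10, 12),
                                     volume_ml = c(500, 100)), 12)
  expect_true("uo_gap_gt_9h" %in% r$flags)
  expect_true(all(is.na(r$uo_ml[1:10])))     # not silently filled
  expect_equal(r$uo_ml[11:12], c(50, 50))
  # a 9-hour gap is redistributed ("more than 9 h" is strict)
  r9 <- resample_uo_hourly(data.frame(time_hr = 9, volume_ml = 90), 9)
  expect_length(r9$flags, 0)
  expect_equal(r9$uo_ml, rep(10, 9))
})

test_that("urine volume is conserved across random gappy stays", {
  co <- generate_cohort(cohort_config(n_patients = 60, prevalence = 0.1,
                                      seed = 6))
  for (s in co) {
    r <- resample_uo_hourly(s$uo_records, s$los_hours)
    expect_equal(sum(r$uo_ml, na.rm = TRUE), sum(s$uo_records$volume_ml),
                 tolerance = 1e-9)
  }
})

test_that("resampling an already-hourly series is idempotent", {
  rec <- data.frame(time_hr = 1:8, volume_ml = runif(8, 20, 120))
  once <- resample_uo_hourly(rec, 8)
  again <- resample_uo_hourly(data.frame(time_hr = 1:8,
                                         volume_ml = once$uo_ml), 8)
  expect_equal(again$uo_ml, once$uo_ml)
})

test_that("creatinine is dragged forward to the next measurement", {
  r <- forward_fill_scr(data.frame(time_hr = c(0, 24),
                                   scr_mg_dl = c(1, 2)), 30)
  expect_equal(r$scr_mg_dl, c(rep(1, 24), rep(2, 6)))
  # single measurement: constant series
  r1 <- forward_fill_scr(data.frame(time_hr = 5, scr_mg_dl = 1.3), 48)
  expect_equal(unique(r1$scr_mg_dl), 1.3)
  # gap over 4 days flags the stay
  r2 <- forward_fill_scr(data.frame(time_hr = c(0, 100),
                                    scr_mg_dl = c(1, 1.1)), 120)
  expect_true("scr_gap_gt_4d" %in% r2$flags)
  # no record at all: flagged, undefined series
  r3 <- forward_fill_scr(data.frame(time_hr = numeric(0),
                                    scr_mg_dl = numeric(0)), 24)
  expect_true("scr_gap_gt_4d" %in% r3$flags)
  expect_true(all(is.na(r3$scr_mg_dl)))
})

test_that("baseline creatinine is the minimum across all stays", {
  expect_equal(baseline_scr(c(1.2, 0.9, 1.5)), 0.9)
  expect_equal(baseline_scr(list(c(1.3, 1.1), c(0.8, 1.0))), 0.8)
  expect_error(baseline_scr(numeric(0)), "baseline")
})

test_that("exclusion criteria are applied with full reason lists", {
  short <- make_series(rep(1, 20), id = "SHORT", los = 20)
  low_b <- make_series(rep(1, 48), scr = rep(0.4, 48), id = "LOWB")
  dial <- make_series(rep(1, 48), id = "DIAL", dialysis = TRUE)
  clean <- make_series(rep(1, 48), id = "OK")
  series <- list(short, low_b, dial, clean)
  baselines <- c(SHORT = 1, LOWB = 0.4, DIAL = 1, OK = 1)
  res <- apply_exclusions(series, baselines, min_center_volume = 1)
  rep <- res$report
  expect_equal(rep$first_reason[rep$patient_id == "SHORT"], "los_lt_24h")
  expect_equal(rep$first_reason[rep$patient_id == "LOWB"],
               "baseline_scr_lt_0.5")
  expect_equal(rep$first_reason[rep$patient_id == "DIAL"], "dialysis")
  expect_false(rep$excluded[rep$patient_id == "OK"])
  expect_equal(rep$reasons[rep$patient_id == "OK"], "")
  # excluded <-> reasons non-empty
  expect_equal(rep$excluded, nzchar(rep$reasons))
  expect_equal(vapply(res$kept, function(s) s$patient_id, character(1)), "OK")
})

test_that("low-volume centers lose all their stays", {
  big <- lapply(1:60, function(i) make_series(rep(1, 48),
                                              id = sprintf("A%02d", i),
                                              center = "BIG"))
  small <- lapply(1:3, function(i) make_series(rep(1, 48),
                                               id = sprintf("B%02d", i),
                                               center = "SMALL"))
  series <- c(big, small)
  baselines <- setNames(rep(1, 63),
                        vapply(series, function(s) s$patient_id,
                               character(1)))
  res <- apply_exclusions(series, baselines)
  rep <- res$report
  expect_true(all(rep$reasons[grepl("^B", rep$patient_id)] ==
                    "low_volume_center"))
  expect_false(any(rep$excluded[grepl("^A", rep$patient_id)]))
})

test_that("adding an exclusion-triggering record never un-excludes a stay", {
  s <- make_series(rep(1, 20), id = "S", los = 20)   # excluded: short stay
  baselines <- c(S = 1)
  r1 <- apply_exclusions(list(s), baselines, min_center_volume = 1)
  s$dialysis <- TRUE
  r2 <- apply_exclusions(list(s), baselines, min_center_volume = 1)
  expect_true(r1$report$excluded && r2$report$excluded)
  expect_gte(nchar(r2$report$reasons), nchar(r1$report$reasons))
})

test_that("community-acquired episodes (criteria complete in first 12 h) are excluded", {
  uo <- c(rep(0, 14), rep(1.5, 34))            # anuria from admission
  scr <- c(rep(1, 4), rep(3.6, 44))
  s <- make_series(uo, scr, id = "CA")
  res <- apply_exclusions(list(s), c(CA = 1), min_center_volume = 1)
  expect_true(res$report$excluded)
  expect_match(res$report$reasons, "community_acquired_aki")
})
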