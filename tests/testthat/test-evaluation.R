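test_that("splits follow the 60/10/20/10 patient-disjoint contract", {
  ids <- sprintf("P%03d", 1:100)
  sp <- assign_splits(ids, seed = 4)
  expect_equal(as.vector(table(sp)[c("train", "validation", "test",
                                     "calibration")]),
               c(60, 10, 20, 10))
  expect_identical(sp, assign_splits(ids, seed = 4))
  expect_false(identical(sp, assign_splits(ids, seed = 5)))
  expect_setequal(names(sp), ids)
  expect_silent(assert_patient_disjoint(sp))
  expect_error(assign_splits(sprintf("P%d", 1:5), 1), "at least 10")
  # uneven n: within one patient of target
  sp2 <- assign_splits(sprintf("Q%03d", 1:97), seed = 1)
  tab <- table(sp2)
  targets <- c(train = 0.6, validation = 0.1, test = 0.2,
               calibration = 0.1) * 97
  expect_true(all(abs(tab[names(targets)] - targets) <= 1))
})

test_that("AUC equals the pair-counting oracle", {
  # perfect ranking
  expect_equal(roc_curve_and_auc(c(3, 4, 1, 2),
                                 c("case", "case", "control",
                                   "control"))$auc, 1.0)
  # complete ties
  expect_equal(roc_curve_and_auc(rep(2, 6),
                                 rep(c("case", "control"), 3))$auc, 0.5)
  # six-point toy set, against exhaustive pair counting
  s <- c(0.9, 0.4, 0.7, 0.2, 0.7, 0.5)
  l <- c("case", "case", "case", "control", "control", "control")
  expect_equal(roc_curve_and_auc(s, l)$auc, auc_oracle(s, l),
               tolerance = 1e-12)
  # random sets, exact agreement with the oracle
  set.seed(2)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    s <- sample(round(runif(n), 1))          # forces ties
    l <- sample(c("case", "control"), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(roc_curve_and_auc(s, l)$auc, auc_oracle(s, l),
                 tolerance = 1e-12)
  }
  expect_error(roc_curve_and_auc(1:3, rep("case", 3)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- runif(200)
  l <- rbinom(200, 1, plogis(3 * (s - 0.5)))
  ours <- roc_curve_and_auc(s, l == 1)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("likelihood ratios follow their defining identities", {
  lr <- likelihood_ratios(0.774, 0.780)
  expect_equal(round(lr$lr_pos, 2), 3.52)
  expect_equal(round(lr$lr_neg, 2), 0.29)
  expect_equal(likelihood_ratios(0.5, 0.5)[c("lr_pos", "lr_neg")],
               list(lr_pos = 1, lr_neg = 1))
  expect_equal(round(likelihood_ratios(0.80, 0.84)$lr_pos, 2), 5.00)
  perfect <- likelihood_ratios(0.9, 1)
  expect_true(is.infinite(perfect$lr_pos) && perfect$lr_pos_infinite)
})

test_that("fixed-sensitivity operating point matches an exhaustive scan", {
  set.seed(6)
  s <- round(runif(60), 2)
  l <- rbinom(60, 1, plogis(4 * (s - 0.5))) == 1
  if (length(unique(l)) < 2) l[1:2] <- c(TRUE, FALSE)
  roc <- roc_curve_and_auc(s, l)
  op <- operating_point_at_sensitivity(roc, 0.80)
  # oracle: scan all thresholds, keep best specificity among sens >= 0.8
  cand <- lapply(c(Inf, sort(unique(s), decreasing = TRUE)), function(th) {
    c(sens = mean(s[l] > th), spec = mean(s[!l] <= th))
  })
  cand <- do.call(rbind, cand)
  ok <- cand[, "sens"] >= 0.80
  best_spec <- max(cand[ok, "spec"])
  expect_gte(op$sensitivity, 0.80)
  expect_equal(op$specificity, best_spec)
  # boundary targets
  expect_equal(operating_point_at_sensitivity(roc, 0)$specificity, 1)
  op1 <- operating_point_at_sensitivity(roc, 1)
  expect_equal(op1$sensitivity, 1)
  expect_equal(op1$specificity, mean(s[!l] <= op1$threshold))
})

test_that("knee-point minimises distance to the perfect corner", {
  # a ROC containing the perfect corner returns it
  s <- c(5, 6, 1, 2)
  l <- c(TRUE, TRUE, FALSE, FALSE)
  kp <- knee_point(roc_curve_and_auc(s, l))
  expect_equal(kp$sensitivity, 1)
  expect_equal(kp$specificity, 1)
  # toy ROC, against exhaustive vertex minimisation
  set.seed(12)
  s <- round(runif(40), 2)
  l <- rbinom(40, 1, plogis(3 * (s - 0.4))) == 1
  roc <- roc_curve_and_auc(s, l)
  kp <- knee_point(roc)
  d <- roc$points$fpr^2 + (1 - roc$points$tpr)^2
  expect_equal(kp$specificity * 0 + min(d),
               kp$threshold * 0 + (1 - kp$specificity)^2 +
                 (1 - kp$sensitivity)^2,
               tolerance = 1e-12)
  # Youden variant is available and locally optimal
  ky <- knee_point(roc, method = "youden")
  j <- roc$points$tpr - roc$points$fpr
  expect_equal(ky$sensitivity + ky$specificity - 1, max(j),
               tolerance = 1e-12)
})

test_that("symmetric knee ties break toward higher sensitivity", {
  # two vertices equidistant from (0,1): (fpr 0, tpr 0.6) and (fpr .4, tpr 1)
  s <- c(10, 10, 10, 5, 5, 3, 3, 1, 1, 1)
  l <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  roc <- roc_curve_and_auc(s, l)
  d <- round(roc$points$fpr^2 + (1 - roc$points$tpr)^2, 12)
  expect_gte(sum(d == min(d)), 2)            # genuine tie
  kp <- knee_point(roc)
  tied <- roc$points[d == min(d), ]
  expect_equal(kp$sensitivity, max(tied$tpr))
})

test_that("knee-point is never Youden-dominated by both neighbours", {
  set.seed(14)
  for (i in 1:10) {
    s <- runif(80)
    l <- rbinom(80, 1, plogis(2 * (s - 0.5))) == 1
    if (length(unique(l)) < 2) next
    roc <- roc_curve_and_auc(s, l)
    kp <- knee_point(roc)
    p <- roc$points
    k <- which(p$threshold == kp$threshold)
    j <- p$tpr - p$fpr
    neigh <- j[c(max(1, k - 1), min(nrow(p), k + 1))]
    expect_true(j[k] >= min(neigh))
  }
})

test_that("early-detection fraction counts leads meeting the requirement", {
  onset <- rep(40, 5)
  first <- onset - c(14, 13, 11, 20, 6)
  expect_equal(early_detection_fraction(first, onset, 12), 3 / 5)
  expect_equal(early_detection_fraction(rep(0, 4), rep(20, 4), 12), 1)
  expect_equal(early_detection_fraction(rep(NA_real_, 3), rep(30, 3)), 0)
  # monotone non-increasing in the required lead
  leads <- c(6, 12, 18, 24)
  vals <- vapply(leads, function(ld)
    early_detection_fraction(first, onset, ld), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("resampled performance is seeded and degenerates gracefully", {
  set.seed(100)
  scores <- data.frame(patient_id = sprintf("P%02d", 1:40),
                       score = c(runif(10, 30, 100), runif(30, 0, 70)),
                       label = rep(c("case", "control"), c(10, 30)))
  # full pool, repeated resamples: a deterministic scorer has zero SD
  r1 <- resampled_performance(scores, n_resamples = 2, fraction = 1,
                              seed = 3)
  expect_equal(r1$auc_sd, 0)
  r2 <- quiet(resampled_performance(scores, n_resamples = 20, seed = 5))
  r3 <- quiet(resampled_performance(scores, n_resamples = 20, seed = 5))
  expect_identical(r2$metrics, r3$metrics)
  # sampling error shrinks as the resample size grows
  sds <- vapply(c(0.25, 0.5, 0.9), function(fr)
    quiet(resampled_performance(scores, n_resamples = 100, fraction = fr,
                                seed = 11)$auc_sd), numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("per-stage breakdown shares controls and reuses the LR identities", {
  scores <- data.frame(
    patient_id = sprintf("P%02d", 1:30),
    score = c(rep(80, 4), rep(20, 1), rep(90, 3), rep(10, 2),
              rep(30, 20)),
    label = rep(c("case", "control"), c(10, 20)))
  stages <- data.frame(patient_id = sprintf("P%02d", 1:10),
                       stage = rep(c(2L, 3L), each = 5))
  b <- per_stage_breakdown(scores, stages, threshold = 50)
  expect_equal(b$stage, c(2L, 3L))
  expect_equal(b$specificity, rep(1, 2))
  expect_equal(b$sensitivity, c(4 / 5, 3 / 5))
  expect_equal(b$lr_neg,
               c(likelihood_ratios(4 / 5, 1)$lr_neg,
                 likelihood_ratios(3 / 5, 1)$lr_neg))
  # identical scores for both stages give identical metrics
  scores2 <- scores
  scores2$score[1:10] <- 80
  b2 <- per_stage_breakdown(scores2, stages, threshold = 50)
  expect_equal(b2[b2$stage == 2, -(1:2)], b2[b2$stage == 3, -(1:2)],
               ignore_attr = TRUE)
  expect_warning(per_stage_breakdown(scores, stages[stages$stage == 2, ],
                                     50), "stage-3")
})
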