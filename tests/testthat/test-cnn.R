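test_that("window samples are counted and labelled per stay", {
  ctrl <- make_series(runif(30, 0.5, 2), id = "C1")
  case <- make_series(runif(24, 0.5, 2), id = "K1")
  labs <- data.frame(patient_id = c("C1", "K1"),
                     label = c("control", "case"),
                     onset_hour = c(NA, 30))
  ws <- make_window_samples(list(ctrl, case), labs)
  expect_equal(sum(ws$patient_id == "C1"), 19)   # ends 12..30
  expect_equal(sum(ws$patient_id == "K1"), 13)   # truncated at hour 24
  expect_equal(ncol(ws$X), 12)
  expect_true(all(!ws$y[ws$patient_id == "C1"]))
  expect_true(all(ws$y[ws$patient_id == "K1"]))
  # an 11-hour stay yields no samples
  short <- make_series(runif(11, 0.5, 2), id = "S1")
  ws0 <- make_window_samples(list(short),
                             data.frame(patient_id = "S1",
                                        label = "control"))
  expect_null(ws0$X)
  # window content: row holding hours [t-12, t)
  expect_equal(ws$X[1, ], ctrl$uo_mlkg_h[1:12])
})

test_that("horizon labelling keeps only near-onset case windows positive", {
  case <- make_series(runif(30, 0.5, 2), id = "K1")   # truncated at 30
  labs <- data.frame(patient_id = "K1", label = "case", onset_hour = 36)
  ws <- make_window_samples(list(case), labs, horizon_hours = 12)
  expect_true(all(ws$window_end_hour >= 36 - 12))
  expect_true(all(ws$y))
})

test_that("the network builds deterministically and stays small", {
  m1 <- build_model(model_config(seed = 5))
  m2 <- build_model(model_config(seed = 5))
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, build_model(model_config(seed = 6))$params))
  expect_lt(n_parameters(m1), 100000)
  p <- predict(m1, matrix(0, 4, 12))
  expect_true(all(p > 0 & p < 1))
  expect_error(model_config(kernel_sizes = c(3, 14)), "kernel_sizes")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- model_config(filters_per_block = 2, seed = 2)
  model <- build_model(cfg)
  set.seed(4)
  X <- matrix(runif(6 * 12), 6, 12)
  y <- c(1, 0, 1, 1, 0, 0)
  w <- c(1, 2, 1, 1, 2, 1)
  lg <- oliguard:::.cnn_loss_grads(model$params, X, y, w, cfg)
  for (nm in names(model$params)) {
    k <- sample(length(model$params[[nm]]), 1)
    eps <- 1e-5
    up <- model$params; up[[nm]][k] <- up[[nm]][k] + eps
    dn <- model$params; dn[[nm]][k] <- dn[[nm]][k] - eps
    num <- (oliguard:::.cnn_loss_grads(up, X, y, w, cfg)$loss -
              oliguard:::.cnn_loss_grads(dn, X, y, w, cfg)$loss) / (2 * eps)
    expect_equal(unname(lg$grads[[nm]][k]), num, tolerance = 1e-5)
  }
})

test_that("a gradient step on a separable batch reduces the loss", {
  cfg <- model_config(seed = 7, learning_rate = 0.05)
  model <- build_model(cfg)
  X <- rbind(matrix(0.05, 8, 12), matrix(1.2, 8, 12))
  y <- rep(c(1, 0), each = 8)
  w <- rep(1, 16)
  l0 <- oliguard:::.cnn_loss_grads(model$params, X, y, w, cfg)
  params <- model$params
  for (nm in names(l0$grads))
    params[[nm]] <- params[[nm]] - cfg$learning_rate * l0$grads[[nm]]
  l1 <- oliguard:::.cnn_loss_grads(params, X, y, w, cfg)
  expect_lt(l1$loss, l0$loss)
})

train_toy_windows <- function(n_pat, seed, case_level = 0.1,
                              control_level = 1.0) {
  set.seed(seed)
  xs <- list(); ys <- list(); ids <- list()
  for (i in seq_len(n_pat)) {
    is_case <- i <= ceiling(n_pat * 0.3)
    lvl <- if (is_case) case_level else control_level
    n_win <- 8
    X <- matrix(pmax(rnorm(n_win * 12, lvl, 0.1), 0), n_win, 12)
    xs[[i]] <- X; ys[[i]] <- rep(is_case, n_win)
    ids[[i]] <- rep(sprintf("S%d_%03d", seed, i), n_win)
  }
  list(X = do.call(rbind, xs), y = unlist(ys), patient_id = unlist(ids))
}

test_that("training separates a constructed signal and is seed-deterministic", {
  tr <- train_toy_windows(40, 1)
  va <- train_toy_windows(12, 2)
  te <- train_toy_windows(12, 3)
  cfg <- model_config(epochs = 4, batch_size = 64, seed = 9)
  m1 <- train_model(build_model(cfg), tr, va)
  auc <- roc_curve_and_auc(predict(m1, te$X), te$y)$auc
  expect_gte(auc, 0.95)
  m2 <- train_model(build_model(cfg), tr, va)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  # degenerate inputs are rejected
  tr1 <- tr; tr1$y <- rep(TRUE, length(tr1$y))
  expect_error(train_model(build_model(cfg), tr1, va), "single class")
  expect_error(train_model(build_model(cfg), tr, tr), "share patients")
})

test_that("risk scores cover every hour from 12 with a bounded 0-100 scale", {
  tr <- train_toy_windows(40, 1)
  va <- train_toy_windows(12, 2)
  cfg <- model_config(epochs = 8, batch_size = 64, seed = 9,
                      learning_rate = 0.01)
  model <- train_model(build_model(cfg), tr, va)
  s <- make_series(runif(40, 0.5, 2), id = "R1")
  r <- predict_risk(model, s)
  expect_equal(nrow(r), 40 - 11)
  expect_equal(r$hour, 12:40)
  expect_true(all(r$score >= 0 & r$score <= 100))
  # an anuric input to a model trained on the constructed signal
  anuric <- make_series(rep(0, 30), id = "R2")
  r0 <- predict_risk(model, anuric, alarm_threshold = 70)
  expect_true(all(r0$score > 70))
  expect_true(all(r0$alarm))
  expect_error(predict_risk(model, make_series(rep(1, 10), id = "R3")),
               "shorter")
})

test_that("Platt calibration preserves ranking and recovers known parameters", {
  set.seed(15)
  n <- 2000
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.8 * z - 0.4)) == 1
  p_raw <- plogis(z)                 # miscalibrated raw probabilities
  cal <- platt_calibrator(p_raw, y)
  p_cal <- predict(cal, p_raw)
  # rank preservation: identical AUC before and after
  expect_equal(roc_curve_and_auc(p_cal, y)$auc,
               roc_curve_and_auc(p_raw, y)$auc, tolerance = 1e-12)
  # slope/intercept recovery within 2 SE
  fit <- glm(y ~ z, family = binomial())
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(cal$slope - 1.8), 2 * se[2])
  expect_lt(abs(cal$intercept - (-0.4)), 2 * se[1])
  # reliability improves
  expect_lt(expected_calibration_error(p_cal, y),
            expected_calibration_error(p_raw, y))
  expect_error(platt_calibrator(runif(5), rep(TRUE, 5)), "single class")
})
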