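#' Configuration of the convolutional risk model
#'
#' A compact 1-D convolutional network for 12-hour urine-output windows:
#' stacked blocks of parallel convolution branches (one per kernel size,
#' concatenated), each block wrapped in a highway gate that blends the
#' block's output with a linear projection of its input, followed by global
#' average pooling and a sigmoid head. The default network has well under
#' 100k parameters and trains on a single CPU.
#'
#' @param conv_block_count number of stacked blocks.
#' @param filters_per_block filters per convolution branch.
#' @param kernel_sizes odd kernel widths of the parallel branches (<= 12).
#' @param highway_gate use the gated shortcut (`FALSE` = plain residual-free
#'   stack).
#' @param learning_rate Adam step size.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param class_weight "balanced" (inverse-prevalence loss weights) or
#'   "none".
#' @param patience early-stopping patience on validation AUC (epochs).
#' @param max_train_windows cap on training windows per epoch (subsampled
#'   per patient-preserving shuffle); keeps desk-scale training fast.
#' @param seed integer seed controlling initialisation and shuffling.
#' @return object of class `cnn_config`.
#' @export
model_config <- function(conv_block_count = 2L, filters_per_block = 8L,
                         kernel_sizes = c(3L, 5L, 7L), highway_gate = TRUE,
                         learning_rate = 3e-3, epochs = 12L,
                         batch_size = 256L, class_weight = "balanced",
                         patience = 3L, max_train_windows = 40000L,
                         seed = 1L) {
  check_scalar_number(conv_block_count, "conv_block_count", 1, 8, TRUE)
  check_scalar_number(filters_per_block, "filters_per_block", 1, 64, TRUE)
  if (any(kernel_sizes > 12) || any(kernel_sizes < 1) ||
      any(kernel_sizes %% 2 == 0))
    abort_field("kernel_sizes", "must be odd and <= 12")
  check_scalar_number(learning_rate, "learning_rate", 1e-8)
  check_scalar_number(epochs, "epochs", 1, integer = TRUE)
  check_scalar_number(batch_size, "batch_size", 1, integer = TRUE)
  if (!class_weight %in% c("balanced", "none"))
    abort_field("class_weight", 'must be "balanced" or "none"')
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(list(conv_block_count = as.integer(conv_block_count),
                 filters_per_block = as.integer(filters_per_block),
                 kernel_sizes = as.integer(kernel_sizes),
                 highway_gate = isTRUE(highway_gate),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 class_weight = class_weight, patience = as.integer(patience),
                 max_train_windows = as.integer(max_train_windows),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

.WIN <- 12L  # input window length in hours

## ---- low-level tensor helpers -------------------------------------------
## Activations are (n*T) x C matrices; row r encodes (i, t) with i fastest.

## row-index map that shifts time by s hours (out[t] reads in[t+s]); NA rows
## fall outside the window and read as zero
.shift_index <- function(n, s) {
  t_src <- rep(seq_len(.WIN) + s, each = n)
  i <- rep(seq_len(n), .WIN)
  ok <- t_src >= 1 & t_src <= .WIN
  ifelse(ok, i + (t_src - 1) * n, NA_integer_)
}

.shift <- function(X, idx) {
  out <- X[idx, , drop = FALSE]
  out[is.na(idx), ] <- 0
  out
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

## ---- parameter initialisation -------------------------------------------

.cnn_channels <- function(cfg) {
  cc <- length(cfg$kernel_sizes) * cfg$filters_per_block
  c(1L, rep(cc, cfg$conv_block_count))
}

.cnn_init <- function(cfg) {
  ch <- .cnn_channels(cfg)
  params <- list()
  for (b in seq_len(cfg$conv_block_count)) {
    cin <- ch[b]; cout <- ch[b + 1]
    for (k in cfg$kernel_sizes) {
      sd <- sqrt(2 / (k * cin))
      params[[sprintf("b%d.k%d.W", b, k)]] <-
        array(stats::rnorm(k * cin * cfg$filters_per_block, 0, sd),
              dim = c(k, cin, cfg$filters_per_block))
      params[[sprintf("b%d.k%d.b", b, k)]] <- rep(0, cfg$filters_per_block)
    }
    params[[sprintf("b%d.proj.W", b)]] <-
      matrix(stats::rnorm(cin * cout, 0, sqrt(1 / cin)), cin, cout)
    params[[sprintf("b%d.proj.b", b)]] <- rep(0, cout)
    if (cfg$highway_gate) {
      params[[sprintf("b%d.gate.W", b)]] <-
        matrix(stats::rnorm(cin * cout, 0, sqrt(1 / cin)), cin, cout)
      ## negative bias: start close to the carry path, ease deep training
      params[[sprintf("b%d.gate.b", b)]] <- rep(-1, cout)
    }
  }
  params[["head.w"]] <- matrix(stats::rnorm(ch[length(ch)], 0,
                                            sqrt(1 / ch[length(ch)])), ncol = 1)
  params[["head.b"]] <- 0
  params
}

#' Number of trainable parameters of a CNN risk model
#' @param model a `uo_cnn`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

## ---- forward / backward --------------------------------------------------

.cnn_forward <- function(params, X, cfg, keep_cache = FALSE) {
  n <- nrow(X)
  idx <- lapply(stats::setNames(-6:6, as.character(-6:6)),
                function(s) .shift_index(n, s))
  ## (i, t) with i fastest: column-major flatten of X (n x T) is exactly that
  A <- matrix(as.numeric(X), ncol = 1)
  cache <- list(n = n, blocks = list())
  for (b in seq_len(cfg$conv_block_count)) {
    Zs <- vector("list", length(cfg$kernel_sizes))
    shifted <- list()
    for (j in seq_along(cfg$kernel_sizes)) {
      k <- cfg$kernel_sizes[j]
      pad <- (k - 1L) / 2L
      W <- params[[sprintf("b%d.k%d.W", b, k)]]
      bk <- params[[sprintf("b%d.k%d.b", b, k)]]
      out <- matrix(0, n * .WIN, dim(W)[3])
      for (d in seq_len(k)) {
        s <- d - 1L - pad
        key <- as.character(s)
        if (is.null(shifted[[key]])) shifted[[key]] <- .shift(A, idx[[key]])
        out <- out + shifted[[key]] %*% matrix(W[d, , ], dim(W)[2], dim(W)[3])
      }
      Zs[[j]] <- sweep(out, 2, bk, "+")
    }
    Z <- do.call(cbind, Zs)
    H <- pmax(Z, 0)
    P <- sweep(A %*% params[[sprintf("b%d.proj.W", b)]], 2,
               params[[sprintf("b%d.proj.b", b)]], "+")
    if (cfg$highway_gate) {
      Gpre <- sweep(A %*% params[[sprintf("b%d.gate.W", b)]], 2,
                    params[[sprintf("b%d.gate.b", b)]], "+")
      G <- .sigmoid(Gpre)
      A_next <- G * H + (1 - G) * P
    } else {
      G <- NULL
      A_next <- H + P
    }
    if (keep_cache)
      cache$blocks[[b]] <- list(A = A, Z = Z, H = H, P = P, G = G,
                                shifted = shifted)
    A <- A_next
  }
  C <- ncol(A)
  ## global average pool over time: M[i, c] = mean_t A[(i,t), c]
  M <- matrix(0, n, C)
  for (t in seq_len(.WIN))
    M <- M + A[(t - 1L) * n + seq_len(n), , drop = FALSE]
  M <- M / .WIN
  logits <- as.numeric(M %*% params[["head.w"]]) + params[["head.b"]]
  if (keep_cache) { cache$M <- M; cache$idx <- idx }
  list(p = .sigmoid(logits), logits = logits,
       cache = if (keep_cache) cache else NULL)
}

.cnn_backward <- function(params, cache, dlogits, cfg) {
  n <- cache$n
  grads <- list()
  grads[["head.b"]] <- sum(dlogits)
  grads[["head.w"]] <- t(cache$M) %*% matrix(dlogits, ncol = 1)
  dM <- matrix(dlogits, ncol = 1) %*% t(params[["head.w"]])
  ## un-pool: every time step receives dM / T
  dA <- dM[rep(seq_len(n), .WIN), , drop = FALSE] / .WIN
  idx <- cache$idx
  for (b in rev(seq_len(cfg$conv_block_count))) {
    blk <- cache$blocks[[b]]
    if (cfg$highway_gate) {
      dG <- dA * (blk$H - blk$P)
      dH <- dA * blk$G
      dP <- dA * (1 - blk$G)
      dGpre <- dG * blk$G * (1 - blk$G)
    } else {
      dH <- dA; dP <- dA; dGpre <- NULL
    }
    dZ <- dH * (blk$Z > 0)
    dA_in <- dP %*% t(params[[sprintf("b%d.proj.W", b)]])
    grads[[sprintf("b%d.proj.W", b)]] <- t(blk$A) %*% dP
    grads[[sprintf("b%d.proj.b", b)]] <- colSums(dP)
    if (!is.null(dGpre)) {
      dA_in <- dA_in + dGpre %*% t(params[[sprintf("b%d.gate.W", b)]])
      grads[[sprintf("b%d.gate.W", b)]] <- t(blk$A) %*% dGpre
      grads[[sprintf("b%d.gate.b", b)]] <- colSums(dGpre)
    }
    col0 <- 0L
    for (j in seq_along(cfg$kernel_sizes)) {
      k <- cfg$kernel_sizes[j]
      pad <- (k - 1L) / 2L
      W <- params[[sprintf("b%d.k%d.W", b, k)]]
      nf <- dim(W)[3]
      dZj <- dZ[, col0 + seq_len(nf), drop = FALSE]
      col0 <- col0 + nf
      dW <- array(0, dim = dim(W))
      for (d in seq_len(k)) {
        s <- d - 1L - pad
        key <- as.character(s)
        Xs <- blk$shifted[[key]]
        dW[d, , ] <- t(Xs) %*% dZj
        ## transpose of the shift: scatter back with the opposite offset
        dA_in <- dA_in + .shift(dZj %*% t(matrix(W[d, , ], dim(W)[2], nf)),
                                idx[[as.character(-s)]])
      }
      grads[[sprintf("b%d.k%d.W", b, k)]] <- dW
      grads[[sprintf("b%d.k%d.b", b, k)]] <- colSums(dZj)
    }
    dA <- dA_in
  }
  grads
}

## weighted binary cross-entropy on logits (numerically stable softplus form)
.cnn_loss_grads <- function(params, X, y, w, cfg) {
  fwd <- .cnn_forward(params, X, cfg, keep_cache = TRUE)
  z <- fwd$logits
  wn <- w / sum(w)
  loss <- sum(wn * (log1p(exp(-abs(z))) + pmax(z, 0) - y * z))
  dlogits <- wn * (fwd$p - y)
  grads <- .cnn_backward(params, fwd$cache, dlogits, cfg)
  list(loss = loss, grads = grads, p = fwd$p)
}

## ---- model object --------------------------------------------------------

#' Build an untrained convolutional risk model
#'
#' Initialises the network described by a [model_config()]; identical seeds
#' give identical initial weights.
#'
#' @param config a [model_config()].
#' @return object of class `uo_cnn` mapping 12-value urine-output windows
#'   to probabilities in `(0, 1)`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "cnn_config"))
  params <- with_seed(config$seed, .cnn_init(config))
  structure(list(config = config, params = params, history = NULL),
            class = "uo_cnn")
}

#' @export
print.uo_cnn <- function(x, ...) {
  cat(sprintf("<uo_cnn> %d block(s), kernels {%s}, %d filters/branch, %d parameters%s\n",
              x$config$conv_block_count,
              paste(x$config$kernel_sizes, collapse = ","),
              x$config$filters_per_block, n_parameters(x),
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

#' Predict window probabilities
#'
#' @param object a `uo_cnn`.
#' @param X numeric matrix with 12 columns (one row per window).
#' @param chunk forward-pass chunk size.
#' @param ... unused.
#' @return numeric vector of raw probabilities.
#' @export
predict.uo_cnn <- function(object, X, chunk = 8192L, ...) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == .WIN)
  out <- numeric(nrow(X))
  for (i0 in seq(1L, nrow(X), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(X))
    out[i0:i1] <- .cnn_forward(object$params, X[i0:i1, , drop = FALSE],
                               object$config)$p
  }
  out
}

## ---- window construction -------------------------------------------------

#' Build 12-hour window samples from hourly series
#'
#' One sample per hour `t >= 12` of every stay, holding the urine output of
#' hours `[t-12, t)`. Samples from case stays (whose series were truncated
#' 6 h before onset) are labelled positive wholesale; with
#' `horizon_hours` set, only windows ending within that many hours of onset
#' are positive (the rest of the case's windows are dropped to avoid
#' ambiguous labels). Windows containing missing hours are skipped.
#'
#' @param series list of `hourly_series` (cases truncated).
#' @param labels data.frame with `patient_id`, `label`, and `onset_hour`
#'   (needed when `horizon_hours` is set).
#' @param horizon_hours optional positive-labelling horizon.
#' @return list with matrix `X` (rows = windows), logical `y`, character
#'   `patient_id`, integer `window_end_hour`.
#' @export
make_window_samples <- function(series, labels, horizon_hours = NULL) {
  lab <- stats::setNames(labels$label, labels$patient_id)
  onset <- if ("onset_hour" %in% names(labels))
    stats::setNames(labels$onset_hour, labels$patient_id) else NULL
  xs <- list(); ys <- list(); ids <- list(); ends <- list()
  for (s in series) {
    n <- s$n_hours
    if (n < .WIN) next
    E <- stats::embed(s$uo_mlkg_h, .WIN)[, .WIN:1, drop = FALSE]
    end_hr <- .WIN:n
    ok <- stats::complete.cases(E)
    is_case <- lab[[s$patient_id]] == "case"
    y <- rep(is_case, length(end_hr))
    if (is_case && !is.null(horizon_hours) && !is.null(onset)) {
      keep_pos <- end_hr >= onset[[s$patient_id]] - horizon_hours
      ok <- ok & keep_pos
    }
    if (!any(ok)) next
    xs[[length(xs) + 1L]] <- E[ok, , drop = FALSE]
    ys[[length(ys) + 1L]] <- y[ok]
    ids[[length(ids) + 1L]] <- rep(s$patient_id, sum(ok))
    ends[[length(ends) + 1L]] <- end_hr[ok]
  }
  list(X = do.call(rbind, xs), y = unlist(ys),
       patient_id = unlist(ids), window_end_hour = unlist(ends))
}

## ---- training ------------------------------------------------------------

#' Train the convolutional risk model
#'
#' Minibatch Adam on weighted binary cross-entropy, with early stopping on
#' validation AUC (best weights are kept). Class imbalance is handled by
#' inverse-prevalence loss weights. Fully deterministic for a given seed.
#'
#' @param model an untrained (or warm) `uo_cnn`.
#' @param train,validation window sample lists from [make_window_samples()];
#'   the two must be patient-disjoint (asserted).
#' @param quiet suppress per-epoch messages.
#' @return the trained `uo_cnn`, with a `history` data.frame (epoch,
#'   training loss, validation AUC).
#' @export
train_model <- function(model, train, validation, quiet = TRUE) {
  stopifnot(inherits(model, "uo_cnn"))
  cfg <- model$config
  if (length(unique(train$y)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  if (length(intersect(unique(train$patient_id),
                       unique(validation$patient_id))) > 0L)
    stop("train and validation splits share patients", call. = FALSE)
  w_pos <- if (cfg$class_weight == "balanced")
    length(train$y) / (2 * sum(train$y)) else 1
  w_neg <- if (cfg$class_weight == "balanced")
    length(train$y) / (2 * sum(!train$y)) else 1

  params <- model$params
  m_state <- lapply(params, function(p) p * 0)
  v_state <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best_auc <- -Inf; best_params <- params; bad <- 0L
  hist <- list()

  with_seed(child_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(train$y))
      if (length(ord) > cfg$max_train_windows)
        ord <- ord[seq_len(cfg$max_train_windows)]
      ep_loss <- 0; nb <- 0L
      for (i0 in seq(1L, length(ord), by = cfg$batch_size)) {
        sel <- ord[i0:min(i0 + cfg$batch_size - 1L, length(ord))]
        Xb <- train$X[sel, , drop = FALSE]
        yb <- as.numeric(train$y[sel])
        wb <- ifelse(train$y[sel], w_pos, w_neg)
        lg <- .cnn_loss_grads(params, Xb, yb, wb, cfg)
        step <- step + 1L
        for (nm in names(lg$grads)) {
          g <- lg$grads[[nm]]
          m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
          v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g^2
          mhat <- m_state[[nm]] / (1 - beta1^step)
          vhat <- v_state[[nm]] / (1 - beta2^step)
          params[[nm]] <- params[[nm]] - cfg$learning_rate * mhat /
            (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      }
      model$params <- params
      val_p <- predict.uo_cnn(model, validation$X)
      val_auc <- if (length(unique(validation$y)) == 2L)
        roc_curve_and_auc(val_p, validation$y)$auc else NA_real_
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                  val_auc = val_auc)
      if (!quiet)
        message(sprintf("epoch %d: loss %.4f, val AUC %.4f",
                        epoch, ep_loss / nb, val_auc))
      ## ties count as improvement: among equally discriminating epochs the
      ## later (better-fitted, sharper-probability) weights are kept
      if (!is.na(val_auc) && val_auc >= best_auc - 1e-9) {
        best_auc <- max(best_auc, val_auc); best_params <- params; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) break
      }
    }
  })
  model$params <- best_params
  model$history <- do.call(rbind, hist)
  model
}

## ---- calibration ---------------------------------------------------------

#' Platt calibration of raw model probabilities
#'
#' Fits a logistic regression of the outcome on the raw logit, a monotone
#' (for positive slope) map that leaves the ranking -- and therefore ROC and
#' AUC -- unchanged while improving probability calibration.
#'
#' @param p raw probabilities on the calibration split.
#' @param y logical (or "case"/"control") outcomes; both classes required.
#' @return object of class `platt_calibrator`; apply with `predict()`.
#' @export
platt_calibrator <- function(p, y) {
  y <- .as_case_logical(y)
  if (length(unique(y)) < 2L)
    stop("calibration data contain a single class", call. = FALSE)
  z <- stats::qlogis(pmin(pmax(p, 1e-7), 1 - 1e-7))
  fit <- stats::glm(y ~ z, family = stats::binomial())
  cf <- stats::coef(fit)
  if (is.na(cf[2]) || cf[2] < 0)
    warning("non-positive calibration slope: ranking is not preserved",
            call. = FALSE)
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2])),
            class = "platt_calibrator")
}

#' @export
predict.platt_calibrator <- function(object, p, ...) {
  z <- stats::qlogis(pmin(pmax(p, 1e-7), 1 - 1e-7))
  .sigmoid(object$intercept + object$slope * z)
}

#' Calibrate a trained model on a held-out calibration split
#'
#' @param model a trained `uo_cnn` (or any object with a `predict` method
#'   returning probabilities for `samples$X`).
#' @param samples window samples of the calibration split.
#' @return a `platt_calibrator`.
#' @export
calibrate_model <- function(model, samples) {
  platt_calibrator(stats::predict(model, samples$X), samples$y)
}

#' Expected calibration error
#'
#' Mean absolute gap between predicted probability and observed event rate
#' over equal-width probability bins (a standard reliability summary).
#'
#' @param p probabilities; @param y outcomes; @param bins bin count.
#' @return non-negative scalar.
#' @export
expected_calibration_error <- function(p, y, bins = 10L) {
  y <- .as_case_logical(y)
  bin <- pmin(floor(p * bins) + 1L, bins)
  err <- 0
  for (b in unique(bin)) {
    sel <- bin == b
    err <- err + sum(sel) * abs(mean(p[sel]) - mean(y[sel]))
  }
  err / length(p)
}

## ---- hourly risk scores --------------------------------------------------

#' Hourly 0-100 risk scores for one stay
#'
#' One score per hour `t >= 12`, computed from the urine output of hours
#' `[t-12, t)` and scaled to 0-100 after optional calibration. A score at
#' hour `t` expresses the risk of the diagnostic criteria completing at or
#' after hour `t + 6`. Scores above `alarm_threshold` raise the alarm flag.
#'
#' @param model a trained `uo_cnn`.
#' @param series an `hourly_series` (length >= 12).
#' @param calibrator optional `platt_calibrator`.
#' @param alarm_threshold alarm cut-off on the 0-100 scale (default 70).
#' @return data.frame `patient_id`, `hour`, `score`, `alarm`.
#' @export
predict_risk <- function(model, series, calibrator = NULL,
                         alarm_threshold = 70) {
  stopifnot(inherits(series, "hourly_series"))
  if (series$n_hours < .WIN)
    stop(sprintf("series of %d hours is shorter than the %d-hour input window",
                 series$n_hours, .WIN), call. = FALSE)
  E <- stats::embed(series$uo_mlkg_h, .WIN)[, .WIN:1, drop = FALSE]
  p <- predict.uo_cnn(model, E)
  if (!is.null(calibrator)) p <- stats::predict(calibrator, p)
  score <- pmin(pmax(100 * p, 0), 100)
  data.frame(patient_id = series$patient_id, hour = .WIN:series$n_hours,
             score = score, alarm = score > alarm_threshold)
}

#' Patient-level score summary
#'
#' Collapses hourly scores to one row per stay: the maximum score (a case
#' counts as detected if any pre-onset score exceeds the alarm threshold,
#' a control as false-positive if any score does) and the hour of the first
#' alarm.
#'
#' @param model trained `uo_cnn`; @param series list of `hourly_series`
#'   (cases truncated); @param calibrator optional; @param alarm_threshold
#'   0-100 cut-off.
#' @return data.frame `patient_id`, `score`, `first_alarm_hour`.
#' @export
score_patients <- function(model, series, calibrator = NULL,
                           alarm_threshold = 70) {
  rows <- lapply(series, function(s) {
    if (s$n_hours < .WIN)
      return(data.frame(patient_id = s$patient_id, score = NA_real_,
                        first_alarm_hour = NA_integer_))
    r <- predict_risk(model, s, calibrator, alarm_threshold)
    fa <- if (any(r$alarm)) min(r$hour[r$alarm]) else NA_integer_
    data.frame(patient_id = s$patient_id, score = max(r$score),
               first_alarm_hour = fa)
  })
  do.call(rbind, rows)
}
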