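#' CNN classifier configuration
#'
#' Hyperparameters of the peak/artifact window classifier: four convolutional
#' layers of 8 filters each with kernels 1x64, 1x32, 1x16 and 1x8 sliding
#' along time (the probe axis is untouched until flattening), valid (unpadded)
#' convolution, ReLU activations, 1x4 max-pooling after layers 2-4 only
#' (pooling after layer 1 as well would drive later feature lengths
#' negative), 25% dropout before flattening, then a ReLU dense layer and a
#' sigmoid output unit.
#'
#' @param n_filters Filters per convolutional layer.
#' @param kernels Kernel lengths along time, one per layer.
#' @param pool Max-pooling length.
#' @param pool_after Logical per layer: pool after this layer?
#' @param dropout Dropout rate in \[0, 1).
#' @param dense_units Width of the hidden dense layer.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param min_delta Minimum validation-loss decrease that counts as an
#'   improvement for early stopping.
#' @param folds Cross-validation folds in [train_cnn()]; < 2 skips CV.
#' @param cutoff Default classification probability cutoff.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param validation_fraction Fraction of the training corpus held out for
#'   early stopping in the final fit.
#' @param input_length Window length the network expects (samples).
#' @param seed Integer seed for weight initialization / shuffling / dropout.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(n_filters = 8L, kernels = c(64L, 32L, 16L, 8L),
                       pool = 4L, pool_after = c(FALSE, TRUE, TRUE, TRUE),
                       dropout = 0.25, dense_units = 32L, epochs = 30L,
                       patience = 3L, min_delta = 1e-4, folds = 5L,
                       cutoff = 0.6,
                       learning_rate = 1e-3, batch_size = 32L,
                       validation_fraction = 0.15, input_length = 800L,
                       seed = 1L) {
  cfg <- list(n_filters = as.integer(n_filters), kernels = as.integer(kernels),
              pool = as.integer(pool), pool_after = pool_after,
              dropout = dropout, dense_units = as.integer(dense_units),
              epochs = as.integer(epochs), patience = as.integer(patience),
              min_delta = min_delta, folds = as.integer(folds),
              cutoff = cutoff,
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              validation_fraction = validation_fraction,
              input_length = as.integer(input_length), seed = seed)
  stopifnot(length(cfg$kernels) == length(cfg$pool_after),
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$cutoff >= 0, cfg$cutoff <= 1, cfg$pool >= 1)
  class(cfg) <- "cnn_config"
  cfg
}

#' Feature lengths through the convolution/pooling schedule
#'
#' Valid convolution maps a time axis of length `L` to `L - k + 1`; 1x`pool`
#' max-pooling maps `L` to `floor(L / pool)`. Errors if any stage yields a
#' non-positive length. For the default schedule on input length 800 the
#' trace is 800, 737, 706, 176, 161, 40, 33, 8.
#'
#' @param input_length Time axis length of the input window.
#' @param kernels Kernel lengths per layer.
#' @param pool Pooling length.
#' @param pool_after Logical per layer.
#' @return Integer vector of the time length after each conv and pool stage
#'   (starting with the input length).
#' @export
cnn_feature_lengths <- function(input_length = 800L,
                                kernels = c(64L, 32L, 16L, 8L), pool = 4L,
                                pool_after = c(FALSE, TRUE, TRUE, TRUE)) {
  L <- as.integer(input_length)
  out <- L
  for (l in seq_along(kernels)) {
    L <- L - kernels[l] + 1L
    if (L <= 0) stop(sprintf("invalid feature dimension after conv layer %d (length %d)", l, L))
    out <- c(out, L)
    if (pool_after[l]) {
      L <- L %/% pool
      if (L <= 0) stop(sprintf("invalid feature dimension after pool %d (length %d)", l, L))
      out <- c(out, L)
    }
  }
  out
}

#' Build an untrained CNN
#'
#' Initializes weights (He normal for ReLU layers, Xavier for the sigmoid
#' output) for the architecture described in [cnn_config()] and asserts the
#' layer arithmetic: with defaults the flattened feature count is
#' 2 probes x 8 filters x 8 time steps = 128.
#'
#' @param config A [cnn_config()].
#' @param seed Seed for weight initialization (default `config$seed`).
#' @return An object of class `difc_cnn` (untrained).
#' @export
build_cnn <- function(config = cnn_config(), seed = config$seed) {
  lens <- cnn_feature_lengths(config$input_length, config$kernels,
                              config$pool, config$pool_after)
  final_len <- lens[length(lens)]
  flat <- 2L * config$n_filters * final_len
  seeded_rng(seed)
  params <- list()
  c_in <- 1L
  for (l in seq_along(config$kernels)) {
    k <- config$kernels[l]
    fan_in <- k * c_in
    params[[paste0("cW", l)]] <-
      matrix(stats::rnorm(fan_in * config$n_filters, 0, sqrt(2 / fan_in)),
             fan_in, config$n_filters)
    params[[paste0("cb", l)]] <- numeric(config$n_filters)
    c_in <- config$n_filters
  }
  params$dW1 <- matrix(stats::rnorm(config$dense_units * flat, 0, sqrt(2 / flat)),
                       config$dense_units, flat)
  params$db1 <- numeric(config$dense_units)
  params$dW2 <- matrix(stats::rnorm(config$dense_units, 0, sqrt(1 / config$dense_units)),
                       1, config$dense_units)
  params$db2 <- 0
  structure(list(config = config, params = params, flat_size = flat,
                 feature_lengths = lens, trained = FALSE, history = NULL,
                 fold_metrics = NULL),
            class = "difc_cnn")
}

#' @export
print.difc_cnn <- function(x, ...) {
  cat(sprintf("<difc_cnn> %d conv layers x %d filters (kernels %s), flat %d -> dense %d -> sigmoid; %s\n",
              length(x$config$kernels), x$config$n_filters,
              paste(x$config$kernels, collapse = "/"), x$flat_size,
              x$config$dense_units,
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

# ---- internal forward / backward ------------------------------------------

# Forward pass. x: array (B, 2, L). Convolutions run through the compiled
# im2col kernels (src/conv.cpp). Returns probabilities and, if keep_cache,
# all intermediates needed by cnn_backward.
cnn_forward <- function(net, x, train = FALSE, keep_cache = FALSE) {
  cfg <- net$config
  P <- net$params
  B <- dim(x)[1]
  A <- aperm(x, c(3, 2, 1))
  dim(A) <- c(cfg$input_length, 1L, 2L * B)
  caches <- if (keep_cache) vector("list", length(cfg$kernels)) else NULL
  for (l in seq_along(cfg$kernels)) {
    k <- cfg$kernels[l]
    A_out <- conv1d_forward(A, P[[paste0("cW", l)]], P[[paste0("cb", l)]], k)
    lc <- list(A_in = A, A_out = A_out)  # (T_out, F, B2), post-ReLU
    A <- A_out
    if (cfg$pool_after[l]) {
      pl <- cfg$pool
      Tp <- dim(A)[1] %/% pl
      used <- A[seq_len(Tp * pl), , , drop = FALSE]
      slabs <- lapply(seq_len(pl), function(j)
        used[seq(j, Tp * pl, by = pl), , , drop = FALSE])
      Pm <- Reduce(pmax, slabs)
      if (keep_cache) {
        masks <- vector("list", pl)
        taken <- array(FALSE, dim(Pm))
        for (j in seq_len(pl)) {
          mj <- (slabs[[j]] == Pm) & !taken
          masks[[j]] <- mj
          taken <- taken | mj
        }
        lc$pool_masks <- masks
        lc$pre_pool_dim <- dim(A)
      }
      A <- Pm
    }
    if (keep_cache) caches[[l]] <- lc
  }
  # flatten: (T, F, B2) -> (T*F, B2) -> (2*T*F, B) stacking probe rows per example
  dim(A) <- c(prod(dim(A)[1:2]), dim(A)[3])
  feat <- A
  dim(feat) <- c(2L * nrow(A), B)
  drop_mask <- NULL
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    drop_mask <- matrix((stats::runif(length(feat)) < keep) / keep,
                        nrow(feat), ncol(feat))
    feat <- feat * drop_mask
  }
  H <- P$dW1 %*% feat
  H <- H + P$db1
  relu1 <- H > 0
  H[!relu1] <- 0
  logits <- drop(P$dW2 %*% H) + P$db2
  prob <- 1 / (1 + exp(-logits))
  out <- list(prob = prob, logits = logits)
  if (keep_cache) {
    out$caches <- caches
    out$feat <- feat
    out$drop_mask <- drop_mask
    out$H <- H
    out$relu1 <- relu1
  }
  out
}

# Backward pass: gradients of mean binary cross-entropy w.r.t. all params.
cnn_backward <- function(net, fwd, y) {
  cfg <- net$config
  P <- net$params
  B <- length(y)
  g <- list()
  dlogit <- matrix((fwd$prob - y) / B, 1, B)
  g$db2 <- sum(dlogit)
  g$dW2 <- tcrossprod(dlogit, fwd$H)
  dH <- crossprod(P$dW2, dlogit)
  dH[!fwd$relu1] <- 0
  g$db1 <- rowSums(dH)
  g$dW1 <- tcrossprod(dH, fwd$feat)
  dfeat <- crossprod(P$dW1, dH)
  if (!is.null(fwd$drop_mask)) dfeat <- dfeat * fwd$drop_mask
  # unflatten to (T, F, B2)
  nlay <- length(cfg$kernels)
  lens <- net$feature_lengths
  T_fin <- lens[length(lens)]
  dA <- dfeat
  dim(dA) <- c(T_fin, cfg$n_filters, 2L * B)
  for (l in rev(seq_len(nlay))) {
    lc <- fwd$caches[[l]]
    if (cfg$pool_after[l]) {
      pl <- cfg$pool
      pre <- array(0, lc$pre_pool_dim)
      Tp <- dim(dA)[1]
      for (j in seq_len(pl))
        pre[seq(j, Tp * pl, by = pl), , ] <- dA * lc$pool_masks[[j]]
      dA <- pre
    }
    bw <- conv1d_backward(dA, lc$A_out, lc$A_in, P[[paste0("cW", l)]],
                          cfg$kernels[l], input_grad = l > 1L)
    g[[paste0("cb", l)]] <- as.numeric(bw$db)
    g[[paste0("cW", l)]] <- bw$dW
    if (l > 1L) dA <- bw$dA
  }
  g
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gg <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gg
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gg * gg
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Core optimizer loop with early stopping on validation loss.
fit_cnn <- function(net, x_train, y_train, x_val, y_val, verbose = FALSE) {
  cfg <- net$config
  st <- adam_init(net$params)
  n <- dim(x_train)[1]
  best_val <- Inf
  best_params <- net$params
  best_epoch <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    nb <- ceiling(n / cfg$batch_size)
    tl <- 0
    for (bi in seq_len(nb)) {
      sel <- perm[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
      xb <- x_train[sel, , , drop = FALSE]
      yb <- y_train[sel]
      fwd <- cnn_forward(net, xb, train = TRUE, keep_cache = TRUE)
      g <- cnn_backward(net, fwd, yb)
      up <- adam_step(net$params, g, st, cfg$learning_rate)
      net$params <- up$params
      st <- up$state
      tl <- tl + bce_loss(fwd$prob, yb) * length(sel)
    }
    vp <- predict_in_batches(net, x_val)
    vl <- bce_loss(vp, y_val)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / n,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %02d  train %.4f  val %.4f", epoch, tl / n, vl))
    if (vl < best_val - cfg$min_delta) {
      best_val <- vl
      best_params <- net$params
      best_epoch <- epoch
    } else if (epoch - best_epoch >= cfg$patience) {
      break
    }
  }
  net$params <- best_params
  net$history <- hist
  net$best_epoch <- best_epoch
  net$trained <- TRUE
  net
}

predict_in_batches <- function(net, x, chunk = 256L) {
  n <- dim(x)[1]
  out <- numeric(n)
  at <- 1L
  while (at <= n) {
    sel <- at:min(at + chunk - 1L, n)
    out[sel] <- cnn_forward(net, x[sel, , , drop = FALSE])$prob
    at <- at + chunk
  }
  out
}

# ---- public training / inference API --------------------------------------

corpus_array <- function(windows) {
  if (inherits(windows, "difc_corpus")) return(windows$windows)
  if (inherits(windows, "difc_window")) {
    arr <- array(0, c(1L, 2L, ncol(windows$data)))
    arr[1, , ] <- windows$data
    return(arr)
  }
  if (is.array(windows) && length(dim(windows)) == 3) return(windows)
  stop("windows must be a difc_corpus, difc_window, or M x 2 x L array")
}

#' Train the CNN window classifier
#'
#' Optionally runs k-fold cross-validation (per-fold accuracy, precision,
#' sensitivity, specificity at the configured cutoff) for assessment, then
#' fits the deployed model on the full corpus with an internal validation
#' split used for early stopping: training halts when the validation loss
#' has not improved for `patience` consecutive epochs and the best weights
#' are restored. Minimized loss is binary cross-entropy under the Adam
#' optimizer.
#'
#' @param net An untrained [build_cnn()] model, or a [cnn_config()] (a model
#'   is built from it).
#' @param corpus Labeled `difc_corpus` containing both classes.
#' @param folds Cross-validation folds; < 2 skips CV (default from config).
#' @param seed Integer seed governing shuffling, dropout, the validation
#'   split and (when a config is passed) weight initialization.
#' @param verbose Print per-epoch losses.
#' @return A trained `difc_cnn` with `history` (per-epoch train/validation
#'   loss), `best_epoch`, and `fold_metrics` when CV was run.
#' @export
train_cnn <- function(net, corpus, folds = NULL, seed = NULL, verbose = FALSE) {
  if (inherits(net, "cnn_config")) net <- build_cnn(net)
  stopifnot(inherits(net, "difc_cnn"), inherits(corpus, "difc_corpus"))
  if (anyNA(corpus$labels)) stop("corpus must be fully labeled")
  if (length(unique(corpus$labels)) < 2)
    stop("corpus must contain both classes")
  cfg <- net$config
  if (is.null(folds)) folds <- cfg$folds
  if (is.null(seed)) seed <- cfg$seed
  seeded_rng(seed)
  x <- corpus$windows
  y <- corpus$labels
  n <- dim(x)[1]
  if (dim(x)[3] != cfg$input_length)
    stop("window length does not match classifier input length")
  fold_metrics <- NULL
  if (folds >= 2) {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    rows <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      net_f <- build_cnn(cfg, seed = seed + f)
      net_f <- fit_cnn(net_f, x[tr, , , drop = FALSE], y[tr],
                       x[te, , , drop = FALSE], y[te], verbose = verbose)
      pr <- predict_in_batches(net_f, x[te, , , drop = FALSE])
      cm <- confusion_counts(y[te], as.integer(pr > cfg$cutoff))
      met <- compute_metrics(cm)
      rows[[f]] <- data.frame(fold = f, accuracy = met$accuracy,
                              precision = met$precision,
                              sensitivity = met$sensitivity,
                              specificity = met$specificity,
                              epochs_run = nrow(net_f$history))
    }
    fold_metrics <- do.call(rbind, rows)
  }
  # final fit on the full corpus with an internal early-stopping split
  n_val <- max(1L, round(cfg$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  net <- fit_cnn(net, x[tr_idx, , , drop = FALSE], y[tr_idx],
                 x[val_idx, , , drop = FALSE], y[val_idx], verbose = verbose)
  net$fold_metrics <- fold_metrics
  net
}

#' Predict peak probabilities for candidate windows
#'
#' Deterministic inference (dropout inactive); one probability in \[0, 1\]
#' per window, batch order preserved.
#'
#' @param clf A trained `difc_cnn`.
#' @param windows A `difc_corpus`, `difc_window`, or `M x 2 x L` array.
#' @return Numeric vector of probabilities.
#' @export
predict_proba <- function(clf, windows) {
  x <- corpus_array(windows)
  if (dim(x)[3] != clf$config$input_length)
    stop("window length does not match classifier input length")
  predict_in_batches(clf, x)
}

#' @export
predict.difc_cnn <- function(object, newdata, type = c("prob", "class"),
                             cutoff = object$config$cutoff, ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else as.integer(p > cutoff)
}

#' Classify candidate windows at a probability cutoff
#'
#' Label 1 (Peak_CNN) iff the predicted probability strictly exceeds the
#' cutoff; a probability exactly at the cutoff is labeled 0.
#'
#' @param clf A trained `difc_cnn`.
#' @param windows Windows as in [predict_proba()].
#' @param cutoff Probability cutoff in \[0, 1\] (default 0.6).
#' @return Integer vector of 0/1 labels.
#' @export
classify_windows <- function(clf, windows, cutoff = clf$config$cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  as.integer(predict_proba(clf, windows) > cutoff)
}

#' Select the classification cutoff
#'
#' `"fixed"` returns the configured value (0.6 by default, chosen from ROC
#' analysis and the shape of the predicted-probability distribution);
#' `"youden"` maximizes TPR - FPR over the observed probabilities.
#'
#' @param probabilities Predicted probabilities.
#' @param labels True 0/1 labels (both classes required).
#' @param policy `"fixed"` or `"youden"`.
#' @param fixed_value Value returned by the fixed policy.
#' @return The selected cutoff.
#' @export
select_cutoff <- function(probabilities, labels, policy = c("fixed", "youden"),
                          fixed_value = 0.6) {
  policy <- match.arg(policy)
  if (length(unique(labels)) < 2) stop("both classes required")
  if (policy == "fixed") return(fixed_value)
  thr <- sort(unique(probabilities))
  # classification is prob > cutoff; candidate cutoffs sit below the smallest
  # probability and at midpoints between consecutive distinct probabilities
  cuts <- c(thr[1] - 1, (thr[-1] + thr[-length(thr)]) / 2)
  j <- vapply(cuts, function(ct) {
    pred <- probabilities > ct
    tpr <- sum(pred & labels == 1) / sum(labels == 1)
    fpr <- sum(pred & labels == 0) / sum(labels == 0)
    tpr - fpr
  }, numeric(1))
  cuts[which.max(j)]
}
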