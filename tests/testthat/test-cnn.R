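test_that("layer arithmetic: default schedule is feasible, pooling after layer 1 is not", {
  lens <- cnn_feature_lengths(800)
  expect_equal(lens, c(800, 737, 706, 176, 161, 40, 33, 8))
  net <- build_cnn(cnn_config())
  expect_equal(net$flat_size, 2 * 8 * 8)  # = 128
  # pooling after every layer drives the last convolution negative
  expect_error(cnn_feature_lengths(800, pool_after = rep(TRUE, 4)),
               "invalid feature dimension")
  expect_error(build_cnn(cnn_config(pool_after = rep(TRUE, 4))))
})

test_that("backpropagated gradients match numerical differentiation", {
  cfg <- cnn_config(kernels = c(8L, 4L), pool_after = c(FALSE, TRUE),
                    input_length = 40L, dense_units = 4L, dropout = 0,
                    seed = 61)
  net <- build_cnn(cfg)
  set.seed(62)
  x <- array(runif(5 * 2 * 40), c(5, 2, 40))
  y <- c(0, 1, 1, 0, 1)
  fwd <- difcr:::cnn_forward(net, x, keep_cache = TRUE)
  g <- difcr:::cnn_backward(net, fwd, y)
  eps <- 1e-6
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    for (i in unique(c(1, length(p), sample(length(p), min(3, length(p)))))) {
      up <- net; up$params[[nm]][i] <- p[i] + eps
      dn <- net; dn$params[[nm]][i] <- p[i] - eps
      num <- (difcr:::bce_loss(difcr:::cnn_forward(up, x)$prob, y) -
              difcr:::bce_loss(difcr:::cnn_forward(dn, x)$prob, y)) / (2 * eps)
      expect_equal(as.numeric(g[[nm]][i]), num, tolerance = 1e-5)
    }
  }
})

test_that("a linearly separable toy corpus is learned to 100% accuracy", {
  set.seed(63)
  n <- 60
  arr <- array(0, c(n, 2, 800))
  lab <- rep(0:1, n / 2)
  arr[lab == 1, , ] <- 0.8
  arr <- arr + array(runif(n * 2 * 800, 0, 0.05), c(n, 2, 800))
  corpus <- difc_corpus(arr, labels = lab)
  clf <- train_cnn(cnn_config(epochs = 30, seed = 64, validation_fraction = 0.2),
                   corpus, folds = 0, seed = 64)
  expect_true(clf$trained)
  expect_equal(as.integer(predict_proba(clf, corpus) > 0.5), lab)
})

test_that("training is deterministic given a seed and records early stopping", {
  set.seed(65)
  arr <- array(runif(40 * 2 * 800), c(40, 2, 800))
  lab <- rep(0:1, 20)
  arr[lab == 1, , 300:500] <- arr[lab == 1, , 300:500] + 0.4
  corpus <- difc_corpus(arr, labels = lab)
  cfg <- cnn_config(epochs = 6, seed = 66)
  a <- train_cnn(cfg, corpus, folds = 0, seed = 66)
  b <- train_cnn(cfg, corpus, folds = 0, seed = 66)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
  # early-stopping bookkeeping: if training halted before the epoch budget,
  # it halted exactly patience epochs after the best validation loss
  if (nrow(a$history) < cfg$epochs)
    expect_equal(nrow(a$history), a$best_epoch + cfg$patience)
  expect_equal(a$best_epoch, which.min(a$history$val_loss))
  expect_error(train_cnn(cfg, difc_corpus(arr, labels = rep(1L, 40))),
               "both classes")
})

test_that("cross-validation reports per-fold metrics", {
  set.seed(67)
  arr <- array(runif(30 * 2 * 800, 0, 0.1), c(30, 2, 800))
  lab <- rep(0:1, 15)
  arr[lab == 1, , ] <- arr[lab == 1, , ] + 0.7
  corpus <- difc_corpus(arr, labels = lab)
  clf <- train_cnn(cnn_config(epochs = 4, seed = 68), corpus, folds = 3,
                   seed = 68)
  expect_equal(nrow(clf$fold_metrics), 3)
  expect_true(all(c("accuracy", "precision", "sensitivity", "specificity")
                  %in% names(clf$fold_metrics)))
})

test_that("inference is deterministic, bounded and order-preserving", {
  sc <- small_classifier()
  p <- predict_proba(sc$classifier, sc$corpus)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(p, length(sc$corpus))
  # duplicated window gives an identical probability (dropout inactive)
  one <- sc$corpus$windows[c(1, 1), , , drop = FALSE]
  expect_equal(predict_proba(sc$classifier, one)[1],
               predict_proba(sc$classifier, one)[2])
  # order preserved under permutation
  idx <- c(5, 1, 3)
  expect_equal(predict_proba(sc$classifier,
                             sc$corpus$windows[idx, , , drop = FALSE]),
               p[idx])
  expect_error(predict_proba(sc$classifier, array(0, c(2, 2, 100))), "length")
})

test_that("classification applies a strict cutoff", {
  sc <- small_classifier()
  few <- sc$corpus[1:10]
  p <- predict_proba(sc$classifier, few)
  expect_equal(classify_windows(sc$classifier, few, cutoff = 0),
               rep(1L, 10))  # every probability is positive
  expect_equal(classify_windows(sc$classifier, few, cutoff = 1),
               rep(0L, 10))
  # probability exactly at the cutoff is labeled 0
  expect_equal(classify_windows(sc$classifier, few, cutoff = p[1])[1], 0L)
})

test_that("flip/swap augmentation keeps classifier outputs consistent", {
  sc <- small_classifier()
  few <- sc$corpus[1:40]
  p0 <- predict_proba(sc$classifier, few)
  flipped <- few
  flipped$windows <- flipped$windows[, , 800:1, drop = FALSE]
  swapped <- few
  swapped$windows <- swapped$windows[, 2:1, , drop = FALSE]
  expect_true(all(abs(predict_proba(sc$classifier, flipped) - p0) < 0.5))
  expect_true(all(abs(predict_proba(sc$classifier, swapped) - p0) < 0.5))
})

test_that("cutoff selection: fixed policy and Youden argmax", {
  expect_equal(select_cutoff(c(0.2, 0.9), c(0, 1), "fixed"), 0.6)
  cut <- select_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), "youden")
  expect_gt(cut, 0.2)
  expect_lte(cut, 0.8)
  expect_error(select_cutoff(c(0.1, 0.9), c(1, 1), "youden"), "both classes")
  # agrees with exhaustive search over a dense threshold grid
  set.seed(69)
  for (i in 1:10) {
    p <- round(runif(60), 2)
    y <- rbinom(60, 1, plogis(6 * (p - 0.5)))
    if (length(unique(y)) < 2) next
    cut <- select_cutoff(p, y, "youden")
    j <- function(ct) {
      pr <- p > ct
      sum(pr & y == 1) / sum(y == 1) - sum(pr & y == 0) / sum(y == 0)
    }
    grid <- seq(-0.01, 1.01, by = 0.001)
    expect_equal(j(cut), max(vapply(grid, j, numeric(1))), tolerance = 1e-12)
  }
})
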