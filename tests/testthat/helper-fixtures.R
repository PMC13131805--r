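# Shared fixtures. Heavy objects (the full-scale trained classifier) are
# built once per test run and memoized; all seeds are fixed constants so the
# suite is reproducible.

.fixtures <- new.env(parent = emptyenv())

# Brute-force sliding-window oracles (O(N * W)), kept deliberately naive and
# independent of the package implementations they check.
oracle_sliding_median <- function(x, window) {
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) median(x[max(1, i - h):min(n, i + h)]),
         numeric(1))
}

oracle_sliding_sd <- function(x, window, floor = 1e-12) {
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  out <- vapply(seq_len(n), function(i) {
    win <- x[max(1, i - h):min(n, i + h)]
    if (length(win) < 2) 0 else sd(win)
  }, numeric(1))
  pmax(out, floor)
}

# Pairwise-ranking AUC oracle with half credit for ties.
oracle_auc <- function(prob, labels) {
  pos <- prob[labels == 1]
  neg <- prob[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# A synthetic processed object whose channels are arbitrary vectors, for
# window-extraction tests.
fake_processed <- function(probe1, probe2 = probe1, rate = 2000,
                           scan_id = "fixture") {
  structure(list(probe1 = probe1, probe2 = probe2,
                 sigma1 = rep(1, length(probe1)),
                 sigma2 = rep(1, length(probe1)),
                 norm_params = list(probe1 = c(min = 0, max = 1),
                                    probe2 = c(min = 0, max = 1)),
                 sampling_rate = rate, probe_separation = 3,
                 source = scan_id, annotations = NULL),
            class = "difc_processed")
}

# Cheap labeled corpus backed by random arrays (content-free, for count and
# bookkeeping tests).
stub_corpus <- function(n, label, L = 8L, seed = 1) {
  set.seed(seed)
  difc_corpus(array(runif(n * 2 * L), c(n, 2L, L)),
              labels = rep(as.integer(label), n))
}

# Small simulated corpus + quickly trained classifier for unit tests that
# need a working model but not full-scale accuracy.
small_classifier <- function() {
  if (!is.null(.fixtures$small_clf)) return(.fixtures$small_clf)
  corpus <- build_labeled_corpus(150, 150, seed = 301)
  train <- augment_training_set(corpus, 0.25, seed = 302)
  cfg <- cnn_config(epochs = 8L, seed = 303)
  clf <- train_cnn(cfg, train, folds = 0, seed = 303)
  .fixtures$small_clf <- list(classifier = clf, corpus = corpus)
  .fixtures$small_clf
}

# Full-scale study-condition fixture: 4,400-window balanced corpus, 80/20
# split, 25% augmentation, CNN trained as configured by default. Built once;
# used by the acceptance checks.
full_classifier <- function() {
  if (!is.null(.fixtures$full_clf)) return(.fixtures$full_clf)
  corpus <- build_labeled_corpus(2200, 2200, seed = 101)
  parts <- split_corpus(corpus, 0.8, seed = 102)
  train <- augment_training_set(parts$train, 0.25, seed = 103)
  clf <- train_cnn(cnn_config(seed = 104), train, folds = 0, seed = 104)
  .fixtures$full_clf <- list(classifier = clf, train = train,
                             test = parts$test)
  .fixtures$full_clf
}
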