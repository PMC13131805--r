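test_that("window extraction slices both probes around the center", {
  pp <- fake_processed(seq_len(4000) / 4000, rev(seq_len(4000)) / 4000)
  w <- extract_window(pp, 1001, length = 800)
  # covers samples 601..1400 of both channels
  expect_equal(dim(w$data), c(2, 800))
  expect_equal(w$data[1, ], pp$probe1[601:1400])
  expect_equal(w$data[2, ], pp$probe2[601:1400])
  expect_equal(unname(w$pad), c(0L, 0L))
})

test_that("edge windows are zero-padded with the pad extent recorded", {
  pp <- fake_processed(rep(0.5, 2000))
  w <- extract_window(pp, 10, length = 800)
  expect_equal(dim(w$data), c(2, 800))
  expect_equal(w$pad[["left"]], 391)   # window starts at sample -390
  expect_true(all(w$data[, 1:391] == 0))
  expect_true(all(w$data[, 392:800] == 0.5))
  expect_error(extract_window(pp, 100, length = 3000), "exceeds")
  expect_error(extract_window(pp, 0), "outside")
})

test_that("flip and swap are label-preserving involutions", {
  pp <- fake_processed(runif(3000), runif(3000))
  w <- extract_window(pp, 1500, label = 1L, origin_probe = 2L)
  expect_identical(flip_window(flip_window(w)), w)
  expect_identical(swap_probes(swap_probes(w)), w)
  f <- flip_window(w)
  expect_equal(f$data[1, ], rev(w$data[1, ]))
  expect_equal(f$label, 1L)
  s <- swap_probes(w)
  expect_equal(s$data[1, ], w$data[2, ])
  expect_equal(s$data[2, ], w$data[1, ])
  expect_equal(s$origin_probe, 1L)
  expect_equal(s$label, 1L)
  expect_equal(rowSums(s$data), rowSums(w$data)[2:1])  # permuted, not altered
  # a time-symmetric window is unchanged by flipping
  pal <- w
  pal$data <- (w$data + w$data[, 800:1]) / 2
  expect_equal(flip_window(pal)$data, pal$data)
})

test_that("balanced corpus construction downsamples the larger class", {
  peaks <- stub_corpus(2200, 1, seed = 41)
  artifacts <- stub_corpus(4099, 0, seed = 42)
  bal <- build_balanced_corpus(peaks, artifacts, seed = 43)
  expect_equal(length(bal), 4400)
  expect_equal(unname(class_counts(bal)), c(2200, 2200))
  # equal inputs: everything kept
  bal2 <- build_balanced_corpus(stub_corpus(50, 1), stub_corpus(50, 0),
                                seed = 44)
  expect_equal(length(bal2), 100)
  # class counts equal for arbitrary inputs
  bal3 <- build_balanced_corpus(stub_corpus(17, 1), stub_corpus(61, 0),
                                seed = 45)
  cc <- class_counts(bal3)
  expect_equal(cc[["n_artifact"]], cc[["n_peak"]])
  expect_error(build_balanced_corpus(peaks[0], artifacts), "non-empty")
})

test_that("train/test splitting is a seeded disjoint partition", {
  corpus <- stub_corpus(4400, 1, seed = 46)
  corpus$labels <- rep(0:1, 2200)
  parts <- split_corpus(corpus, 0.8, seed = 47)
  expect_equal(length(parts$train), 3520)
  expect_equal(length(parts$test), 880)
  # union is the corpus, intersection empty: compare window content keys
  key <- function(x) apply(x$windows, 1, function(m) paste(signif(m[1, 1:4], 12), collapse = ","))
  expect_setequal(c(key(parts$train), key(parts$test)), key(corpus))
  parts2 <- split_corpus(corpus, 0.8, seed = 47)
  expect_identical(parts$train$windows, parts2$train$windows)
})

test_that("augmentation expands by twice the drawn subset and keeps labels", {
  corpus <- stub_corpus(3520, 1, seed = 48)
  corpus$labels <- rep(c(0L, 1L), length.out = 3520)
  aug <- augment_training_set(corpus, 0.25, seed = 49)
  expect_equal(length(aug), 5280)
  expect_equal(length(augment_training_set(corpus, 0, seed = 49)), 3520)
  small <- stub_corpus(4, 0, seed = 50)
  expect_equal(length(augment_training_set(small, 0.25, seed = 51)), 6)
  # appended copies are the flip and swap of the same drawn subset
  m <- 880
  orig <- aug$windows[seq_len(3520), , , drop = FALSE]
  flipped <- aug$windows[3520 + seq_len(m), , , drop = FALSE]
  swapped <- aug$windows[3520 + m + seq_len(m), , , drop = FALSE]
  expect_equal(flipped[, , dim(flipped)[3]:1], swapped[, 2:1, ])
  expect_equal(aug$labels[3520 + seq_len(m)], aug$labels[3520 + m + seq_len(m)])
  expect_true(all(grepl("\\+flip$", aug$meta$scan_id[3520 + seq_len(m)])))
  expect_true(all(grepl("\\+swap$", aug$meta$scan_id[3520 + m + seq_len(m)])))
  expect_error(augment_training_set(corpus, 1.2), "fraction")
})

test_that("corpus bookkeeping (subset, bind, counts) stays consistent", {
  a <- stub_corpus(10, 1, seed = 52)
  b <- stub_corpus(15, 0, seed = 53)
  both <- bind_corpora(a, b)
  expect_equal(length(both), 25)
  expect_equal(unname(class_counts(both)), c(15, 10))
  sub <- both[c(2, 12)]
  expect_equal(length(sub), 2)
  expect_equal(sub$labels, c(1L, 0L))
  expect_equal(sub$windows[2, , ], both$windows[12, , ])
})
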