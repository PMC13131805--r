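test_that("the four metrics reproduce the reference worked example", {
  cm <- binary_confusion(tp = 426, tn = 441, fp = 6, fn = 7)
  met <- compute_metrics(cm)
  expect_equal(round(met$accuracy, 2), 98.52)
  expect_equal(round(met$precision, 2), 98.61)
  expect_equal(round(met$sensitivity, 2), 98.38)
  expect_equal(round(met$specificity, 2), 98.66)
  perfect <- compute_metrics(binary_confusion(10, 10, 0, 0))
  expect_equal(unlist(perfect[1:4]), c(accuracy = 100, precision = 100,
                                       sensitivity = 100, specificity = 100))
  expect_error(compute_metrics(binary_confusion(0, 0, 0, 0)), "all-zero")
  # undefined denominators flagged as NA, not NaN
  expect_true(is.na(compute_metrics(binary_confusion(0, 5, 0, 0))$precision))
})

test_that("metrics agree with exact rational arithmetic on random matrices", {
  set.seed(91)
  for (i in 1:200) {
    cm <- binary_confusion(sample(0:500, 1), sample(0:500, 1),
                           sample(0:500, 1), sample(1:500, 1))
    met <- compute_metrics(cm)
    expect_equal(met$accuracy, 100 * (cm$tp + cm$tn) /
                   (cm$tp + cm$tn + cm$fp + cm$fn))
    if (cm$tn + cm$fp > 0) {
      expect_equal(met$specificity + met$fpr, 100)  # Eq-4/Eq-5 identity
    }
  }
})

test_that("ROC AUC equals the pairwise-ranking oracle, ties included", {
  # perfectly separated scores
  expect_equal(roc_curve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1.0)
  set.seed(92)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    prob <- round(runif(n), sample(c(1, 2), 1))  # coarse grid forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    roc <- roc_curve(prob, labels)
    expect_equal(roc$auc, oracle_auc(prob, labels))
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(roc$points$tpr >= 0 & roc$points$tpr <= 1))
  }
  expect_error(roc_curve(runif(5), rep(1, 5)), "both classes")
})

test_that("uninformative scores give chance-level AUC", {
  set.seed(93)
  roc <- roc_curve(runif(4000), rbinom(4000, 1, 0.5))
  expect_equal(roc$auc, 0.5, tolerance = 0.05)
})

test_that("ROC AUC matches an independent implementation", {
  set.seed(94)
  prob <- runif(300)
  labels <- rbinom(300, 1, plogis(4 * (prob - 0.5)))
  expect_equal(roc_curve(prob, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, prob, quiet = TRUE))))
})

test_that("extended confusion assigns one predicted label per truth event", {
  truth <- ground_truth_events(
    sample_index = c(1000L, 1060L, 3000L, 5000L, 7000L),
    probe = c(1L, 2L, 1L, 2L, 1L),
    kind = c("peak", "peak", "artifact", "artifact", "peak"),
    pair_id = c(1L, 1L, NA, NA, NA),
    direction = c("forward", "forward", NA, NA, NA))
  records <- data.frame(
    probe = c(1L, 2L, 1L, 2L),
    sample_index = c(1001L, 1061L, 3002L, 5001L),
    label = c("forward", "forward", "artifact", "coincident"))
  ext <- extended_confusion(truth, records)
  expect_equal(ext["forward", "forward"], 2L)
  expect_equal(ext["artifact", "artifact"], 2L)  # coincident counts as artifact
  expect_equal(ext["unmatched", "missed"], 1L)   # lone truth peak undetected
  expect_equal(sum(ext), nrow(truth))
  # empty predictions: every event lands in the missed column
  ext0 <- extended_confusion(truth, records[0, ])
  expect_equal(sum(ext0[, "missed"]), nrow(truth))
  # spurious candidates accrue to the artifact truth row
  extra <- rbind(records,
                 data.frame(probe = 2L, sample_index = 9000L, label = "unmatched"))
  ext2 <- extended_confusion(truth, extra)
  expect_equal(sum(ext2), nrow(truth) + 1)
  expect_equal(ext2["artifact", "unmatched"], 1L)
})

test_that("row sums are conserved for any prediction", {
  truth <- ground_truth_events(
    sample_index = c(500L, 560L, 2000L, 4000L),
    probe = c(1L, 2L, 1L, 2L),
    kind = c("peak", "peak", "artifact", "artifact"),
    pair_id = c(1L, 1L, NA, NA),
    direction = c("forward", "forward", NA, NA))
  set.seed(95)
  for (i in 1:10) {
    labs <- sample(c("artifact", "forward", "reverse", "unmatched"), 4,
                   replace = TRUE)
    rec <- data.frame(probe = truth$probe,
                      sample_index = truth$sample_index + sample(-3:3, 4, TRUE),
                      label = labs)
    ext <- extended_confusion(truth, rec)
    expect_equal(unname(rowSums(ext)),
                 c(2, 2, 0, 0))  # 2 artifacts, 2 forward, no reverse/unmatched
  }
})

test_that("match tallies implement the correct/incorrect definitions", {
  tab <- matrix(0L, 4, 5, dimnames = list(
    truth = c("artifact", "forward", "reverse", "unmatched"),
    predicted = c("artifact", "forward", "reverse", "unmatched", "missed")))
  tab["forward", "forward"] <- 30L
  tab["reverse", "reverse"] <- 4L
  tab["artifact", "artifact"] <- 50L
  ext <- structure(tab, class = c("extended_confusion", class(tab)))
  tl <- tally_matches(ext)
  expect_equal(tl$correct_matches, 34)
  expect_equal(tl$incorrect_matches, 0)
  tab["artifact", "forward"] <- 5L
  tab["unmatched", "reverse"] <- 2L
  tab["forward", "unmatched"] <- 3L  # a miss, but not an "incorrect match"
  ext2 <- structure(tab, class = c("extended_confusion", class(tab)))
  expect_equal(tally_matches(ext2)$incorrect_matches, 7)
})
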