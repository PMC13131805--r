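test_that("peak measurement recovers Gaussian FWHM and triangle half-width", {
  rate <- 2000
  t <- seq_len(4000)
  # Gaussian with sigma_t = 4.25 ms -> FWHM = 2.355 * 4.25 = 10.0 ms
  sig_t <- 0.00425 * rate
  g <- exp(-(t - 2000)^2 / (2 * sig_t^2))
  f <- measure_peak(g, 2000, rate)
  expect_equal(f$width, 2 * sqrt(2 * log(2)) * 0.00425, tolerance = 0.5 / 2000 / 0.010)
  expect_false(f$degenerate)
  # symmetric triangle of base 100 samples: width at half max = 50 samples
  tri <- pmax(0, 1 - abs(t - 2000) / 50)
  f2 <- measure_peak(tri, 2000, rate)
  expect_equal(f2$width * rate, 50, tolerance = 0.03)
  # flat window is degenerate
  f3 <- measure_peak(rep(0.2, 4000), 2000, rate)
  expect_true(f3$degenerate)
})

test_that("speed estimation and delay intervals follow the transit geometry", {
  expect_equal(estimate_speed(0.010, 1.0), 100)   # 10 ms peak -> 100 mm/s
  expect_equal(estimate_speed(0.020, 1.0), 50)
  expect_equal(estimate_speed(0.010, 1.0), 2 * estimate_speed(0.020, 1.0))
  expect_error(estimate_speed(0, 1), "width")
  iv <- expected_delay_interval(100, 3.0, 0.5)
  expect_equal(iv, c(0.015, 0.045))                # tau = 30 ms
  expect_true(iv[1] <= 0.03 && 0.03 <= iv[2])
  iv2 <- expected_delay_interval(100, 3.0, 1e-9)
  expect_equal(iv2[1], iv2[2], tolerance = 1e-6)
})

test_that("coincident peaks are excluded inclusively at the tolerance", {
  f <- function(times, probe) data.frame(
    probe = probe, sample_index = round(times * 2000) + 1L, time = times,
    height = 1, width = 0.01, speed = 100, degenerate = FALSE)
  # identical timestamps: both excluded
  rc <- remove_coincident(f(1.0, 1L), f(1.0, 2L), tolerance = 0.005)
  expect_equal(nrow(rc$filtered1), 0)
  expect_equal(nrow(rc$filtered2), 0)
  expect_equal(nrow(rc$coincident), 2)
  # 100 ms apart: untouched
  rc2 <- remove_coincident(f(1.0, 1L), f(1.1, 2L), tolerance = 0.005)
  expect_equal(nrow(rc2$coincident), 0)
  # exactly at tolerance: removed (inclusive boundary)
  rc3 <- remove_coincident(f(1.0, 1L), f(1.005, 2L), tolerance = 0.005)
  expect_equal(nrow(rc3$coincident), 2)
})

test_that("similarity score is a symmetric mean relative difference", {
  f <- function(w, h, s) data.frame(width = w, height = h, speed = s)
  a <- f(0.01, 1, 100)
  expect_equal(similarity_score(a, a), 0)
  b <- f(0.02, 1, 100)
  expect_equal(similarity_score(a, b), similarity_score(b, a))
  # width ratio 2, height and speed equal: (1/2 + 0 + 0) / 3 = 1/6
  expect_equal(similarity_score(a, f(0.02, 1, 100)), 1 / 6)
})

test_that("matching labels forward/reverse pairs and leaves loners unmatched", {
  feat <- function(t, probe) data.frame(
    probe = probe, sample_index = round(t * 2000) + 1L, time = t, height = 1,
    width = 0.01, speed = 100, degenerate = FALSE)
  # probe-1 peak then identical probe-2 peak 30 ms later: forward pair
  rec <- match_peaks(feat(1.0, 1L), feat(1.03, 2L))
  expect_equal(rec$label, c("forward", "forward"))
  expect_equal(unique(rec$delay), 0.03)
  # mirrored: probe-2 peak precedes its probe-1 partner -> reverse
  rec2 <- match_peaks(feat(1.03, 1L), feat(1.0, 2L))
  expect_equal(rec2$label, c("reverse", "reverse"))
  # lone candidate
  rec3 <- match_peaks(feat(1.0, 1L), feat(1.0, 2L)[0, ])
  expect_equal(rec3$label, "unmatched")
  # delay outside the interval: no pairing
  rec4 <- match_peaks(feat(1.0, 1L), feat(1.1, 2L))
  expect_equal(sort(rec4$label), c("unmatched", "unmatched"))
  # among two in-interval partners the more similar feature wins
  p2 <- rbind(feat(1.025, 2L), feat(1.035, 2L))
  p2$height[1] <- 0.4
  rec5 <- match_peaks(feat(1.0, 1L), p2)
  expect_equal(rec5$partner_index[rec5$probe == 1],
               feat(1.035, 2L)$sample_index)
})

test_that("every candidate receives exactly one label and pairs come in twos", {
  scan <- assemble_scan(sim_config(duration = 60, repetitions = 6, seed = 71))
  pp <- preprocess_scan(scan)
  rec <- run_matching(pp$processed, pp$candidates)
  expect_equal(nrow(rec), nrow(pp$candidates))
  expect_true(all(rec$label %in% c("forward", "reverse", "unmatched",
                                   "coincident")))
  tal <- table(factor(rec$label, c("forward", "reverse")))
  expect_true(all(tal %% 2 == 0))  # two events per pair
  # partners reference each other symmetrically
  fw <- rec[rec$label == "forward", ]
  for (i in seq_len(nrow(fw))) {
    j <- which(fw$sample_index == fw$partner_index[i])
    expect_equal(fw$partner_index[j], fw$sample_index[i])
  }
})

test_that("matched delays recover the simulated transit delays", {
  # bright peaks so candidate apexes sit within a sample of the true centers
  scan <- assemble_scan(sim_config(duration = 60, repetitions = 6, seed = 72,
                                   peak_snr_median = 30))
  pp <- preprocess_scan(scan)
  rec <- run_matching(pp$processed, pp$candidates)
  fw <- rec[rec$label == "forward" & rec$probe == 1, ]
  expect_equal(nrow(fw), 6)
  truth <- scan$transits
  for (i in seq_len(nrow(fw))) {
    pid <- scan$annotations$pair_id[
      which.min(abs(scan$annotations$sample_index - fw$sample_index[i]))]
    expect_lte(abs(fw$delay[i] * 2000 - truth$delay_samples[truth$pair_id == pid]),
               2 + 1e-9)
  }
})

test_that("time-reversing both channels swaps forward and reverse counts", {
  scan <- assemble_scan(sim_config(duration = 60, repetitions = 6, seed = 73))
  count_labels <- function(s) {
    pp <- preprocess_scan(s)
    rec <- run_matching(pp$processed, pp$candidates)
    table(factor(rec$label, c("forward", "reverse", "unmatched", "coincident")))
  }
  fwd <- count_labels(scan)
  rev_scan <- difc_scan(rev(scan$probe1), rev(scan$probe2),
                        sampling_rate = scan$sampling_rate,
                        probe_separation = scan$probe_separation,
                        scan_id = "reversed")
  bwd <- count_labels(rev_scan)
  expect_equal(unname(fwd[["forward"]]), unname(bwd[["reverse"]]))
  expect_equal(unname(fwd[["reverse"]]), unname(bwd[["forward"]]))
})
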