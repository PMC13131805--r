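#' Measure peak features of a candidate
#'
#' Extracts height, full width at half maximum (FWHM) and an inferred cell
#' speed for one candidate on a processed channel. Height is the apex value
#' above a local baseline (median of the outer 10% of the analysis window at
#' each end); width is the time between the half-height crossings nearest the
#' apex, located by linear interpolation; speed is `fov_width / width`.
#'
#' @param values Processed (normalized) intensity vector for the candidate's
#'   probe.
#' @param sample_index 1-based apex position (a local maximum).
#' @param sampling_rate Samples per second.
#' @param probe Probe number carried into the feature record.
#' @param window_length Analysis window length, samples.
#' @param fov_width Effective field-of-view width, mm.
#' @return One-row data.frame: `probe`, `sample_index`, `time` (s), `height`,
#'   `width` (s), `speed` (mm/s), `degenerate` (TRUE when no half-height
#'   crossing exists inside the window, in which case width spans the
#'   window).
#' @export
measure_peak <- function(values, sample_index, sampling_rate = 2000,
                         probe = 1L, window_length = 800, fov_width = 1.0) {
  n <- length(values)
  c0 <- as.integer(sample_index)
  lo <- max(1L, c0 - window_length %/% 2L)
  hi <- min(n, c0 + window_length %/% 2L - 1L)
  win <- values[lo:hi]
  edge <- max(1L, round(0.1 * length(win)))
  baseline <- stats::median(c(win[seq_len(edge)],
                              win[seq(length(win) - edge + 1L, length(win))]))
  apex <- values[c0]
  height <- apex - baseline
  degenerate <- FALSE
  if (height <= 0) {
    return(data.frame(probe = probe, sample_index = c0,
                      time = (c0 - 1) / sampling_rate, height = 0,
                      width = (hi - lo + 1) / sampling_rate,
                      speed = fov_width / ((hi - lo + 1) / sampling_rate),
                      degenerate = TRUE))
  }
  half <- baseline + height / 2
  # nearest crossing left of the apex
  left <- NA_real_
  for (i in seq(c0 - 1L, lo, by = -1L)) {
    if (values[i] < half) {
      left <- i + (half - values[i]) / (values[i + 1L] - values[i])
      break
    }
  }
  right <- NA_real_
  if (c0 < hi) for (i in seq(c0 + 1L, hi)) {
    if (values[i] < half) {
      right <- i - 1L + (values[i - 1L] - half) / (values[i - 1L] - values[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    degenerate <- TRUE
    width_samples <- hi - lo + 1
  } else {
    width_samples <- right - left
  }
  width <- width_samples / sampling_rate
  data.frame(probe = probe, sample_index = c0,
             time = (c0 - 1) / sampling_rate, height = height, width = width,
             speed = estimate_speed(width, fov_width), degenerate = degenerate)
}

#' Infer cell speed from peak width
#'
#' A cell crossing a field of view of width `fov_width` mm in `width` seconds
#' moves at `fov_width / width` mm/s; a 10 ms FWHM with the default 1 mm FOV
#' gives 100 mm/s, the typical arterial flow speed in the measured vessels.
#'
#' @param width Peak FWHM in seconds (> 0).
#' @param fov_width Field-of-view width in mm.
#' @return Speed in mm/s.
#' @export
estimate_speed <- function(width, fov_width = 1.0) {
  if (any(width <= 0)) stop("width must be > 0")
  fov_width / width
}

#' Expected inter-probe delay search interval
#'
#' A cell moving at `speed` mm/s crosses the `separation` mm between probes
#' in `tau = separation / speed` seconds; the search interval is
#' `[tau (1 - alpha), tau (1 + alpha)]`.
#'
#' @param speed Estimated cell speed, mm/s (> 0).
#' @param separation Probe separation, mm.
#' @param alpha Fractional half-width of the interval, in (0, 1).
#' @return Numeric `c(tau_min, tau_max)` in seconds.
#' @export
expected_delay_interval <- function(speed, separation = 3.0, alpha = 0.5) {
  stopifnot(speed > 0, alpha > 0, alpha < 1)
  tau <- separation / speed
  c(tau * (1 - alpha), tau * (1 + alpha))
}

#' Exclude coincident peaks
#'
#' Peaks appearing simultaneously on both probes (time difference at most
#' `tolerance`, inclusive) cannot be one cell seen twice and are excluded
#' from matching as artifacts. Each candidate is consumed by at most one
#' coincident pairing (nearest partner first).
#'
#' @param feats1,feats2 Feature tables from [measure_peak()] for probes 1 and
#'   2, time-sorted.
#' @param tolerance Coincidence tolerance in seconds.
#' @return list with `filtered1`, `filtered2` (surviving features) and
#'   `coincident` (feature rows removed, both probes).
#' @export
remove_coincident <- function(feats1, feats2, tolerance = 0.005) {
  used2 <- rep(FALSE, nrow(feats2))
  co1 <- logical(nrow(feats1))
  for (i in seq_len(nrow(feats1))) {
    dt <- abs(feats2$time - feats1$time[i])
    dt[used2] <- Inf
    if (nrow(feats2) && min(dt) <= tolerance) {
      j <- which.min(dt)
      used2[j] <- TRUE
      co1[i] <- TRUE
    }
  }
  list(filtered1 = feats1[!co1, , drop = FALSE],
       filtered2 = feats2[!used2, , drop = FALSE],
       coincident = rbind(feats1[co1, , drop = FALSE],
                          feats2[used2, , drop = FALSE]))
}

#' Similarity score between two peak features
#'
#' Mean absolute relative difference (|a - b| / max(a, b)) of width, height
#' and inferred speed; 0 for identical features, symmetric, bounded by 1.
#' Lower is more similar.
#'
#' @param f1,f2 One-row feature records from [measure_peak()].
#' @return Non-negative dimensionless score.
#' @export
similarity_score <- function(f1, f2) {
  rel <- function(a, b) {
    m <- max(a, b)
    if (m == 0) 0 else abs(a - b) / m
  }
  mean(c(rel(f1$width, f2$width), rel(f1$height, f2$height),
         rel(f1$speed, f2$speed)))
}

#' Match candidate peaks across probes and label flow direction
#'
#' Greedy, time-ordered matching: for each unconsumed candidate (earliest
#' first), opposite-probe candidates whose delay falls inside the candidate's
#' expected delay interval (from its width-derived speed) are gathered; the
#' partner minimizing the feature [similarity_score()] wins, with ties broken
#' by smallest deviation of the delay from the expected `tau`, then by the
#' earliest partner. A pair whose probe-1 peak precedes its probe-2 partner
#' is `forward`; the opposite is `reverse`. Both members are consumed;
#' leftovers are `unmatched`.
#'
#' @param feats1,feats2 Coincidence-filtered feature tables for probes 1
#'   and 2.
#' @param separation Probe separation, mm.
#' @param alpha Fractional half-width of the delay interval.
#' @return data.frame of match records: `probe`, `sample_index`, `time`,
#'   `label`, `partner_index`, `delay` (s, NA if unmatched), `score`.
#' @export
match_peaks <- function(feats1, feats2, separation = 3.0, alpha = 0.5) {
  all_f <- rbind(feats1, feats2)
  if (!nrow(all_f)) {
    return(data.frame(probe = integer(0), sample_index = integer(0),
                      time = numeric(0), label = character(0),
                      partner_index = integer(0), delay = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  all_f <- all_f[order(all_f$time, all_f$probe), , drop = FALSE]
  n <- nrow(all_f)
  consumed <- rep(FALSE, n)
  label <- rep("unmatched", n)
  partner <- rep(NA_integer_, n)
  delay <- rep(NA_real_, n)
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (consumed[i]) next
    iv <- expected_delay_interval(all_f$speed[i], separation, alpha)
    dt <- all_f$time - all_f$time[i]
    ok <- !consumed & all_f$probe != all_f$probe[i] &
      dt >= iv[1] & dt <= iv[2]
    ok[i] <- FALSE
    js <- which(ok)
    if (!length(js)) next
    sc <- vapply(js, function(j) similarity_score(all_f[i, ], all_f[j, ]),
                 numeric(1))
    tau <- separation / all_f$speed[i]
    dev <- abs(dt[js] - tau)
    ord <- order(sc, dev, all_f$time[js])
    j <- js[ord[1]]
    consumed[i] <- consumed[j] <- TRUE
    lab <- if (all_f$probe[i] == 1L) "forward" else "reverse"
    label[c(i, j)] <- lab
    partner[i] <- all_f$sample_index[j]
    partner[j] <- all_f$sample_index[i]
    delay[c(i, j)] <- dt[j]
    score[c(i, j)] <- sc[ord[1]]
  }
  data.frame(probe = all_f$probe, sample_index = all_f$sample_index,
             time = all_f$time, label = label, partner_index = partner,
             delay = delay, score = score, stringsAsFactors = FALSE)
}

#' Run directional matching on detected candidates
#'
#' Measures features for every candidate, excludes coincident peaks, and
#' matches the remainder; every input candidate receives exactly one label
#' from \{forward, reverse, unmatched, coincident\}.
#'
#' @param processed A `difc_processed` object.
#' @param candidates Candidate table from [preprocess_scan()] (columns
#'   `probe`, `sample_index`).
#' @param config A [difc_config()].
#' @return data.frame of match records sorted by time, with the `coincident`
#'   rows appended to the matcher output.
#' @export
run_matching <- function(processed, candidates, config = difc_config()) {
  rate <- processed$sampling_rate
  feats <- vector("list", 2)
  for (p in 1:2) {
    rows <- candidates[candidates$probe == p, , drop = FALSE]
    vals <- if (p == 1) processed$probe1 else processed$probe2
    feats[[p]] <- if (nrow(rows) == 0) measure_empty() else
      do.call(rbind, c(lapply(rows$sample_index, function(ci)
        measure_peak(vals, ci, rate, probe = p,
                     window_length = config$window_length,
                     fov_width = config$fov_width)),
        list(make.row.names = FALSE)))
  }
  rc <- remove_coincident(feats[[1]], feats[[2]],
                          tolerance = config$coincidence_tolerance)
  rec <- match_peaks(rc$filtered1, rc$filtered2,
                     separation = processed$probe_separation,
                     alpha = config$delay_tolerance)
  if (nrow(rc$coincident)) {
    co <- data.frame(probe = rc$coincident$probe,
                     sample_index = rc$coincident$sample_index,
                     time = rc$coincident$time, label = "coincident",
                     partner_index = NA_integer_, delay = NA_real_,
                     score = NA_real_, stringsAsFactors = FALSE)
    rec <- rbind(rec, co)
  }
  rec[order(rec$time, rec$probe), , drop = FALSE]
}

measure_empty <- function() {
  data.frame(probe = integer(0), sample_index = integer(0), time = numeric(0),
             height = numeric(0), width = numeric(0), speed = numeric(0),
             degenerate = logical(0))
}
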