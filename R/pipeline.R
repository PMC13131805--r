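#' Threshold-based end-to-end pipeline
#'
#' Preprocesses the scan and passes every amplitude-threshold peak candidate
#' (Peak_cand at `k` sigma_bg) straight to directional matching — the
#' classical approach with no shape-based filtering.
#'
#' @param scan A [difc_scan()].
#' @param config A [difc_config()].
#' @return An object of class `difc_result`: `scan_id`, `mode`, `k`,
#'   `n_candidates`, `records` (one row per candidate: `probe`,
#'   `sample_index`, `time`, `prob`, `label`, ...), and `tallies` (label
#'   counts).
#' @export
run_threshold_pipeline <- function(scan, config = difc_config()) {
  pp <- preprocess_scan(scan, config)
  rec <- run_matching(pp$processed, pp$candidates, config)
  rec$prob <- NA_real_
  new_result(scan, "threshold", config, rec)
}

#' ML-integrated end-to-end pipeline
#'
#' Preprocesses the scan, extracts a two-probe window around every candidate,
#' scores each window with the CNN classifier, and passes only candidates
#' whose peak probability exceeds the cutoff (Peak_CNN) to directional
#' matching; rejected candidates are labeled `artifact`.
#'
#' @param scan A [difc_scan()].
#' @param classifier A trained [difc_cnn][build_cnn()].
#' @param config A [difc_config()]; `config$cnn_cutoff` is the probability
#'   cutoff.
#' @return A `difc_result` (see [run_threshold_pipeline()]); every candidate
#'   carries its CNN probability.
#' @export
run_ml_pipeline <- function(scan, classifier, config = difc_config()) {
  pp <- preprocess_scan(scan, config)
  cands <- pp$candidates
  n <- nrow(cands)
  if (n == 0) return(new_result(scan, "ml", config, empty_records()))
  arr <- array(0, c(n, 2L, config$window_length))
  for (i in seq_len(n)) {
    w <- extract_window(pp$processed, cands$sample_index[i],
                        length = config$window_length,
                        origin_probe = cands$probe[i])
    arr[i, , ] <- w$data
  }
  prob <- predict_proba(classifier, arr)
  keep <- prob > config$cnn_cutoff
  rec <- run_matching(pp$processed, cands[keep, , drop = FALSE], config)
  rec$prob <- prob[keep][match(paste(rec$probe, rec$sample_index),
                               paste(cands$probe[keep],
                                     cands$sample_index[keep]))]
  if (any(!keep)) {
    rej <- data.frame(probe = cands$probe[!keep],
                      sample_index = cands$sample_index[!keep],
                      time = (cands$sample_index[!keep] - 1) /
                        scan$sampling_rate,
                      label = "artifact", partner_index = NA_integer_,
                      delay = NA_real_, score = NA_real_,
                      prob = prob[!keep], stringsAsFactors = FALSE)
    rec <- rbind(rec, rej)
  }
  rec <- rec[order(rec$time, rec$probe), , drop = FALSE]
  new_result(scan, "ml", config, rec)
}

empty_records <- function() {
  data.frame(probe = integer(0), sample_index = integer(0), time = numeric(0),
             label = character(0), partner_index = integer(0),
             delay = numeric(0), score = numeric(0), prob = numeric(0),
             stringsAsFactors = FALSE)
}

new_result <- function(scan, mode, config, records) {
  structure(list(scan_id = scan$scan_id, mode = mode, k = config$k,
                 n_candidates = nrow(records),
                 records = records,
                 tallies = table(factor(records$label,
                                        levels = c("artifact", "forward",
                                                   "reverse", "unmatched",
                                                   "coincident")))),
            class = "difc_result")
}

#' @export
print.difc_result <- function(x, ...) {
  cat(sprintf("<difc_result> '%s' (%s pipeline, k = %g): %d candidates\n",
              x$scan_id, x$mode, x$k, x$n_candidates))
  print(x$tallies)
  invisible(x)
}

#' Score a pipeline result against ground truth
#'
#' Convenience wrapper building the [extended_confusion()] table and
#' [tally_matches()] for a pipeline result on an annotated scan.
#'
#' @param result A `difc_result`.
#' @param truth A [ground_truth_events()] table (e.g. `scan$annotations`).
#' @param tolerance Association tolerance in samples.
#' @return list with `confusion` and `tally`.
#' @export
score_result <- function(result, truth, tolerance = 100L) {
  ext <- extended_confusion(truth, result$records, tolerance = tolerance)
  list(confusion = ext, tally = tally_matches(ext))
}
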