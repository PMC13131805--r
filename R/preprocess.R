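#' Sliding-median background subtraction
#'
#' Removes slowly varying autofluorescence background by subtracting a
#' sliding median (default window 5000 samples = 2.5 s at 2000 Hz) from the
#' raw signal. Even window lengths are incremented to the next odd value so
#' the window is centered; at the boundaries the window shrinks (truncated,
#' no padding).
#'
#' @param signal Numeric vector of raw intensities.
#' @param window Window length in samples (>= 1).
#' @return Background-subtracted vector of the same length.
#' @export
subtract_background <- function(signal, window = 5000) {
  check_series(signal)
  stopifnot(window >= 1)
  signal - sliding_median(signal, window)
}

check_series <- function(x) {
  if (length(x) < 1) stop("empty signal")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  invisible(x)
}

# Centered sliding median with truncated (shrinking) edge windows.
# Interior positions use stats::runmed (O(n log w)); only the w/2 edge
# positions on each side are recomputed directly.
sliding_median <- function(x, window) {
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  h <- (w - 1L) %/% 2L
  if (w >= n || n <= 2L * h + 2L) {
    return(vapply(seq_len(n), function(i)
      stats::median(x[max(1L, i - h):min(n, i + h)]), numeric(1)))
  }
  med <- as.vector(stats::runmed(x, w, endrule = "keep"))
  edge <- function(i) stats::median(x[max(1L, i - h):min(n, i + h)])
  for (i in seq_len(h)) {
    med[i] <- edge(i)
    med[n - i + 1L] <- edge(n - i + 1L)
  }
  med
}

#' Moving-average smoothing
#'
#' Applies a moving-average filter (default 6 samples = 0.003 s at 2000 Hz).
#' The window is used at its exact length: for even lengths it is centered
#' with a half-sample offset, covering samples `[i - w/2, i + w/2 - 1]`, so a
#' unit impulse smoothed with window 6 yields six samples of value 1/6. Edge
#' windows are truncated.
#'
#' @param signal Numeric vector.
#' @param window Window length in samples (>= 1).
#' @return Smoothed vector of the same length.
#' @export
smooth_signal <- function(signal, window = 6) {
  check_series(signal)
  stopifnot(window >= 1)
  w <- as.integer(window)
  n <- length(signal)
  lo <- pmax(1L, seq_len(n) - (w %/% 2L))
  hi <- pmin(n, seq_len(n) + ((w + 1L) %/% 2L) - 1L)
  cs <- c(0, cumsum(signal))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Local noise-scale (sigma_bg) estimation
#'
#' Per-sample standard deviation of the background-subtracted signal over a
#' centered sliding window (default the background window, 5000 samples),
#' with truncated edge windows. This is the sigma_bg unit in which detection
#' thresholds (e.g. 4 sigma_bg) are expressed. A small positive floor guards
#' degenerate constant stretches.
#'
#' @param signal Background-subtracted (and typically smoothed) vector.
#' @param window Window length in samples (>= 2); even values incremented to
#'   odd.
#' @param floor Lower bound for the returned scale (default 1e-12).
#' @return Vector of positive noise scales, same length as `signal`.
#' @export
estimate_sigma <- function(signal, window = 5000, floor = 1e-12) {
  check_series(signal)
  stopifnot(window >= 2, floor > 0)
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(signal)
  h <- (w - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  m <- hi - lo + 1L
  xc <- signal - mean(signal)  # center globally to limit cancellation error
  s1 <- c(0, cumsum(xc))
  s2 <- c(0, cumsum(xc * xc))
  sum1 <- s1[hi + 1L] - s1[lo]
  sum2 <- s2[hi + 1L] - s2[lo]
  v <- (sum2 - sum1^2 / m) / pmax(m - 1L, 1L)
  sg <- sqrt(pmax(v, 0))
  pmax(sg, floor)
}

#' Amplitude-threshold peak-candidate detection
#'
#' Identifies local maxima of the processed signal whose amplitude exceeds
#' `k` times the local noise scale (default 4 sigma_bg). Retained maxima are
#' separated by at least `min_separation` samples; when two exceed-threshold
#' maxima fall closer, the higher one wins.
#'
#' @param signal Processed (background-subtracted, smoothed) vector.
#' @param sigma Noise-scale vector from [estimate_sigma()], same length.
#' @param k Threshold multiple of sigma_bg (> 0).
#' @param min_separation Minimum spacing between retained candidates, samples.
#' @return data.frame with columns `sample_index`, `raw_height` (amplitude
#'   above baseline, pre-normalization units) and `snr` (`raw_height /
#'   sigma`), sorted by `sample_index`.
#' @export
detect_candidates <- function(signal, sigma, k = 4, min_separation = 400) {
  check_series(signal)
  if (k <= 0) stop("threshold multiple k must be > 0")
  if (length(sigma) != length(signal)) stop("signal/sigma length mismatch")
  n <- length(signal)
  empty <- data.frame(sample_index = integer(0), raw_height = numeric(0),
                      snr = numeric(0))
  if (n < 3) return(empty)
  i <- 2:(n - 1)
  is_max <- signal[i] > signal[i - 1] & signal[i] >= signal[i + 1]
  cand <- i[is_max & signal[i] > k * sigma[i]]
  if (!length(cand)) return(empty)
  ord <- cand[order(signal[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (m in ord) {
    if (!length(kept) || all(abs(kept - m) >= min_separation))
      kept <- c(kept, m)
  }
  kept <- sort(kept)
  data.frame(sample_index = kept, raw_height = signal[kept],
             snr = signal[kept] / sigma[kept])
}

#' Min-max normalization to [0, 1]
#'
#' Scales a channel by its own scan minimum and maximum, recording both so
#' the mapping can be inverted.
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return list with `values` (normalized vector) and `params = c(min, max)`.
#' @export
normalize_channel <- function(x) {
  check_series(x)
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) stop("cannot normalize a constant channel")
  list(values = (x - lo) / (hi - lo), params = c(min = lo, max = hi))
}

#' @rdname normalize_channel
#' @param values Normalized vector.
#' @param params `c(min, max)` as returned by `normalize_channel`.
#' @export
denormalize_channel <- function(values, params) {
  values * (params[["max"]] - params[["min"]]) + params[["min"]]
}

#' Full preprocessing of a two-probe scan
#'
#' Per channel, in fixed order: background subtraction (sliding median) ->
#' moving-average smoothing -> local sigma estimation -> candidate detection
#' at `k` sigma_bg -> min-max normalization to \[0, 1\]. Candidate detection
#' precedes normalization: thresholds are in sigma_bg units, and candidate
#' `raw_height`/`snr` are recorded on the pre-normalization scale.
#'
#' @param scan A [difc_scan()].
#' @param config A [difc_config()].
#' @return list with `processed` (class `difc_processed`: normalized
#'   channels, per-sample sigma, normalization parameters, metadata) and
#'   `candidates` (data.frame with `probe`, `sample_index`, `raw_height`,
#'   `snr`).
#' @export
preprocess_scan <- function(scan, config = difc_config()) {
  validate_scan(scan)
  chans <- list(scan$probe1, scan$probe2)
  out <- vector("list", 2)
  cands <- vector("list", 2)
  for (p in 1:2) {
    bg <- subtract_background(chans[[p]], config$median_window)
    sm <- smooth_signal(bg, config$smooth_window)
    sg <- estimate_sigma(sm, config$sigma_window, config$sigma_floor)
    cd <- detect_candidates(sm, sg, config$k, config$min_separation)
    # degenerate constant channel (e.g. an all-flat test scan): map to zeros
    # rather than failing min-max normalization
    nm <- if (max(sm) > min(sm)) normalize_channel(sm) else
      list(values = sm * 0, params = c(min = min(sm), max = min(sm)))
    out[[p]] <- list(values = nm$values, sigma = sg, params = nm$params)
    cands[[p]] <- if (nrow(cd)) cbind(probe = p, cd) else
      data.frame(probe = integer(0), sample_index = integer(0),
                 raw_height = numeric(0), snr = numeric(0))
  }
  processed <- structure(
    list(probe1 = out[[1]]$values, probe2 = out[[2]]$values,
         sigma1 = out[[1]]$sigma, sigma2 = out[[2]]$sigma,
         norm_params = list(probe1 = out[[1]]$params, probe2 = out[[2]]$params),
         sampling_rate = scan$sampling_rate,
         probe_separation = scan$probe_separation,
         source = scan$scan_id, annotations = scan$annotations),
    class = "difc_processed")
  list(processed = processed, candidates = rbind(cands[[1]], cands[[2]]))
}

#' @export
print.difc_processed <- function(x, ...) {
  cat(sprintf("<difc_processed> from '%s': %d samples/channel, normalized [0,1]\n",
              x$source, length(x$probe1)))
  invisible(x)
}
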