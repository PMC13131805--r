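#' Extract a two-probe candidate window
#'
#' Cuts a fixed-length slice (default 800 samples = 0.4 s at 2000 Hz) from
#' both normalized channels, centered on a candidate. The window covers
#' samples `[center - length/2, center + length/2 - 1]`; positions outside
#' the scan are zero-padded and the pad extent is recorded.
#'
#' @param processed A `difc_processed` object from [preprocess_scan()].
#' @param center 1-based sample index of the window center.
#' @param length Window length in samples (default 800).
#' @param origin_probe Probe on which the candidate was detected (1 or 2).
#' @param label Optional class label: 1 = peak, 0 = artifact.
#' @return An object of class `difc_window`: a `2 x length` matrix `data`
#'   (row 1 = probe 1, row 2 = probe 2) plus `center`, `origin_probe`,
#'   `label`, `scan_id` and `pad = c(left, right)`.
#' @export
extract_window <- function(processed, center, length = 800,
                           origin_probe = 1L, label = NA_integer_) {
  n <- base::length(processed$probe1)
  L <- as.integer(length)
  if (L > n) stop("window length exceeds scan length")
  if (center < 1 || center > n) stop("center outside scan")
  lo <- as.integer(center) - L %/% 2L
  hi <- lo + L - 1L
  src <- max(1L, lo):min(n, hi)
  dat <- matrix(0, 2L, L)
  cols <- src - lo + 1L
  dat[1, cols] <- processed$probe1[src]
  dat[2, cols] <- processed$probe2[src]
  new_window(dat, center = as.integer(center), origin_probe = origin_probe,
             label = label, scan_id = processed$source,
             pad = c(left = max(0L, 1L - lo), right = max(0L, hi - n)))
}

new_window <- function(data, center, origin_probe, label, scan_id,
                       pad = c(left = 0L, right = 0L)) {
  if (!is.na(label) && !label %in% c(0L, 1L)) stop("label must be 0 or 1")
  structure(list(data = data, center = center,
                 origin_probe = as.integer(origin_probe),
                 label = as.integer(label), scan_id = scan_id, pad = pad),
            class = "difc_window")
}

#' Time-reversal (flipped-window) augmentation operator
#'
#' Reverses both probe rows along time while retaining the label; an
#' involution (`flip(flip(w)) == w`).
#'
#' @param w A `difc_window`.
#' @export
flip_window <- function(w) {
  w$data <- w$data[, ncol(w$data):1, drop = FALSE]
  w
}

#' Probe-swap augmentation operator
#'
#' Exchanges the probe-1 and probe-2 rows, retaining the label and toggling
#' `origin_probe`; an involution.
#'
#' @param w A `difc_window`.
#' @export
swap_probes <- function(w) {
  w$data <- w$data[2:1, , drop = FALSE]
  w$origin_probe <- 3L - w$origin_probe
  w
}

#' Window corpus
#'
#' An ordered collection of candidate windows with labels and provenance,
#' stored as an `M x 2 x L` array for efficient batched classification.
#'
#' @param windows Either a list of `difc_window` objects or an `M x 2 x L`
#'   numeric array.
#' @param labels Integer vector of labels (0 = artifact, 1 = peak, NA =
#'   unlabeled); required when `windows` is an array.
#' @param meta Optional data.frame of per-window provenance (`center`,
#'   `origin_probe`, `scan_id`).
#' @param provenance Free-text description of corpus origin.
#' @return An object of class `difc_corpus`.
#' @export
difc_corpus <- function(windows, labels = NULL, meta = NULL,
                        provenance = "") {
  if (is.list(windows) && !is.array(windows)) {
    stopifnot(all(vapply(windows, inherits, logical(1), "difc_window")))
    M <- length(windows)
    if (M == 0) stop("empty window list")
    L <- ncol(windows[[1]]$data)
    arr <- array(0, c(M, 2L, L))
    for (i in seq_len(M)) arr[i, , ] <- windows[[i]]$data
    labels <- vapply(windows, function(w) w$label, integer(1))
    meta <- data.frame(
      center = vapply(windows, function(w) w$center, integer(1)),
      origin_probe = vapply(windows, function(w) w$origin_probe, integer(1)),
      scan_id = vapply(windows, function(w) w$scan_id, character(1)),
      stringsAsFactors = FALSE)
    windows <- arr
  }
  stopifnot(is.array(windows), length(dim(windows)) == 3, dim(windows)[2] == 2)
  M <- dim(windows)[1]
  if (is.null(labels)) labels <- rep(NA_integer_, M)
  stopifnot(length(labels) == M, all(is.na(labels) | labels %in% 0:1))
  if (is.null(meta))
    meta <- data.frame(center = rep(NA_integer_, M),
                       origin_probe = rep(NA_integer_, M),
                       scan_id = rep("", M), stringsAsFactors = FALSE)
  structure(list(windows = windows, labels = as.integer(labels), meta = meta,
                 provenance = provenance),
            class = "difc_corpus")
}

#' @export
length.difc_corpus <- function(x) dim(x$windows)[1]

#' Class counts of a corpus
#' @param corpus A `difc_corpus`.
#' @return Named integer vector `c(n_artifact, n_peak)`.
#' @export
class_counts <- function(corpus) {
  c(n_artifact = sum(corpus$labels == 0L, na.rm = TRUE),
    n_peak = sum(corpus$labels == 1L, na.rm = TRUE))
}

#' @export
print.difc_corpus <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<difc_corpus> %d windows (2 x %d), %d artifact / %d peak%s\n",
              length(x), dim(x$windows)[3], cc[1], cc[2],
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Subset a corpus
#' @param x A `difc_corpus`.
#' @param i Index vector.
#' @param ... Unused.
#' @export
`[.difc_corpus` <- function(x, i, ...) {
  difc_corpus(x$windows[i, , , drop = FALSE], labels = x$labels[i],
              meta = x$meta[i, , drop = FALSE], provenance = x$provenance)
}

#' Concatenate corpora
#' @param ... `difc_corpus` objects of equal window length.
#' @param provenance Provenance string for the result.
#' @export
bind_corpora <- function(..., provenance = "") {
  xs <- list(...)
  L <- dim(xs[[1]]$windows)[3]
  stopifnot(all(vapply(xs, function(x) dim(x$windows)[3], numeric(1)) == L))
  M <- sum(vapply(xs, length, numeric(1)))
  arr <- array(0, c(M, 2L, L))
  at <- 0L
  for (x in xs) {
    m <- length(x)
    if (m) arr[at + seq_len(m), , ] <- x$windows
    at <- at + m
  }
  difc_corpus(arr, labels = unlist(lapply(xs, `[[`, "labels")),
              meta = do.call(rbind, lapply(xs, `[[`, "meta")),
              provenance = provenance)
}

#' Build a class-balanced corpus
#'
#' Subsamples the larger class uniformly without replacement down to the size
#' of the smaller class, concatenates, and shuffles. 2,200 peaks combined
#' with 4,099 artifacts therefore yield 4,400 windows, 2,200 per class.
#'
#' @param peaks Corpus of peak windows (label 1).
#' @param artifacts Corpus of artifact windows (label 0).
#' @param seed Integer seed for the subsample and shuffle.
#' @return A balanced, shuffled `difc_corpus`.
#' @export
build_balanced_corpus <- function(peaks, artifacts, seed = NULL) {
  if (length(peaks) == 0 || length(artifacts) == 0)
    stop("both classes must be non-empty")
  if (anyNA(peaks$labels) || anyNA(artifacts$labels))
    stop("corpora must be labeled")
  seeded_rng(seed)
  m <- min(length(peaks), length(artifacts))
  take <- function(x) if (length(x) > m) x[sort(sample.int(length(x), m))] else x
  out <- bind_corpora(take(peaks), take(artifacts), provenance = "balanced")
  out[sample.int(length(out))]
}

#' Split a corpus into train and test partitions
#'
#' Disjoint random partition with `round(train_fraction * N)` training
#' windows (4,400 at 0.8 gives 3,520 / 880); deterministic per seed.
#'
#' @param corpus A `difc_corpus`.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return list with `train` and `test` corpora.
#' @export
split_corpus <- function(corpus, train_fraction = 0.8, seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  seeded_rng(seed)
  n <- length(corpus)
  n_train <- round(train_fraction * n)
  idx <- sample.int(n, n_train)
  list(train = corpus[sort(idx)], test = corpus[sort(setdiff(seq_len(n), idx))])
}

#' Augment a training corpus by time reversal and probe swapping
#'
#' Draws `floor(fraction * N)` windows uniformly without replacement and
#' appends, for each drawn window, one time-reversed copy and one
#' probe-swapped copy with the original labels, expanding N to
#' `N + 2 * floor(fraction * N)` (3,520 -> 5,280 at the default 25%).
#' Augmentation is intended for the training partition only; apply it after
#' [split_corpus()] so the test set contains no trivially transformed twins.
#'
#' @param corpus Labeled training `difc_corpus`.
#' @param fraction Fraction of windows to augment, in \[0, 1\].
#' @param seed Integer seed for the subset draw.
#' @return Augmented `difc_corpus`; augmented copies carry `scan_id`
#'   suffixes `"+flip"` / `"+swap"`.
#' @export
augment_training_set <- function(corpus, fraction = 0.25, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (anyNA(corpus$labels)) stop("corpus must be labeled")
  seeded_rng(seed)
  n <- length(corpus)
  m <- floor(fraction * n)
  if (m == 0) return(corpus)
  sel <- sort(sample.int(n, m))
  L <- dim(corpus$windows)[3]
  flipped <- corpus[sel]
  flipped$windows <- flipped$windows[, , L:1, drop = FALSE]
  flipped$meta$scan_id <- paste0(flipped$meta$scan_id, "+flip")
  swapped <- corpus[sel]
  swapped$windows <- swapped$windows[, 2:1, , drop = FALSE]
  swapped$meta$origin_probe <- 3L - swapped$meta$origin_probe
  swapped$meta$scan_id <- paste0(swapped$meta$scan_id, "+swap")
  bind_corpora(corpus, flipped, swapped,
               provenance = paste0(corpus$provenance, "+augmented"))
}
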