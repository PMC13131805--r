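#' In-silico scan simulation configuration
#'
#' Defaults encode the reference in-silico study conditions: a 10 min
#' two-probe scan at 2000 samples/s assembled from a repeated block sequence
#' (background, artifact on probe 2, a forward cell transit seen by probe 1
#' then probe 2, artifact on probe 1, background), repeated 40 times with
#' background spacers, yielding exactly 80 true-peak events (40 forward
#' transits) and 80 artifact events with an exact ground-truth ledger.
#'
#' Peak amplitude (SNR in sigma_bg units) is lognormal with median 8; transit
#' speed is normal with mean 100 mm/s (the typical arterial flow speed) and
#' SD 20, truncated positive, and sets both the inter-probe delay
#' (`separation / speed`) and the peak FWHM (`fov_width / speed`). Artifact
#' spikes are 1-3 samples wide with lognormal SNR of median 30 — markedly
#' brighter-but-narrower transients, as electrical noise appears in real
#' recordings.
#'
#' @param duration Scan duration, seconds.
#' @param repetitions Number of block-sequence repetitions (transits).
#' @param sampling_rate Samples per second.
#' @param noise_sd Background noise standard deviation (sigma_bg unit).
#' @param drift_amplitude Amplitude of the slow sinusoidal baseline drift.
#' @param drift_period Drift period, seconds.
#' @param peak_snr_median,peak_snr_sdlog Lognormal peak SNR parameters.
#' @param artifact_snr_median,artifact_snr_sdlog Lognormal artifact SNR
#'   parameters.
#' @param speed_mean,speed_sd Transit speed distribution, mm/s (truncated
#'   > 20 mm/s to keep delays and widths physiological).
#' @param probe_separation Probe separation, mm.
#' @param fov_width Effective field-of-view width, mm.
#' @param block_length Length of peak/artifact blocks, samples.
#' @param spike_widths Candidate artifact spike widths, samples.
#' @param artifact_kind `"spike"` (single-probe electrical spike) or
#'   `"motion"` (coincident bump inserted on both probes).
#' @param endpoint_tolerance Maximum block endpoint excursion, in noise_sd
#'   units.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 600, repetitions = 40, sampling_rate = 2000,
                       noise_sd = 1, drift_amplitude = 0.2, drift_period = 60,
                       peak_snr_median = 8, peak_snr_sdlog = 0.3,
                       artifact_snr_median = 30, artifact_snr_sdlog = 0.3,
                       speed_mean = 100, speed_sd = 20,
                       probe_separation = 3.0, fov_width = 1.0,
                       block_length = 800L, spike_widths = 1:3,
                       artifact_kind = c("spike", "motion"),
                       endpoint_tolerance = 2, seed = NULL) {
  cfg <- list(duration = duration, repetitions = as.integer(repetitions),
              sampling_rate = sampling_rate, noise_sd = noise_sd,
              drift_amplitude = drift_amplitude, drift_period = drift_period,
              peak_snr_median = peak_snr_median,
              peak_snr_sdlog = peak_snr_sdlog,
              artifact_snr_median = artifact_snr_median,
              artifact_snr_sdlog = artifact_snr_sdlog,
              speed_mean = speed_mean, speed_sd = speed_sd,
              probe_separation = probe_separation, fov_width = fov_width,
              block_length = as.integer(block_length),
              spike_widths = as.integer(spike_widths),
              artifact_kind = match.arg(artifact_kind),
              endpoint_tolerance = endpoint_tolerance, seed = seed)
  stopifnot(cfg$duration > 0, cfg$repetitions >= 1, cfg$noise_sd > 0,
            cfg$block_length >= 16)
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic background block
#'
#' Mean-removed white noise of standard deviation `noise_sd` plus a slow
#' sinusoidal drift (random phase), emulating pre-processed autofluorescence
#' with minimal fluctuation.
#'
#' @param duration Block length in samples.
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return Numeric vector of length `duration`.
#' @export
synth_background <- function(duration, config = sim_config(), seed = NULL) {
  stopifnot(duration >= 1)
  seeded_rng(seed)
  t <- seq_len(duration) / config$sampling_rate
  x <- stats::rnorm(duration, 0, config$noise_sd) +
    config$drift_amplitude *
    sin(2 * pi * t / config$drift_period + stats::runif(1, 0, 2 * pi))
  x - mean(x)
}

# Unit-free bell pulse: apex `amplitude` at `center`, full width at half
# maximum `fwhm` (samples), evaluated on 1..n. Endpoints decay to ~0.
gaussian_pulse <- function(n, center, fwhm, amplitude) {
  i <- seq_len(n)
  amplitude * exp(-4 * log(2) * (i - center)^2 / fwhm^2)
}

#' Synthetic true-peak block
#'
#' A bell-shaped (Gaussian) pulse centered in an 800-sample block, apex
#' `snr * noise_sd`, specified FWHM, superimposed on background noise. The
#' bell is a parametric stand-in for the probe sensitivity profile a cell
#' traces as it crosses the field of view; block endpoints stay within the
#' configured tolerance of the noise floor.
#'
#' @param config A [sim_config()].
#' @param snr Apex amplitude in noise_sd units.
#' @param fwhm_s Full width at half maximum, seconds.
#' @param seed Optional seed.
#' @return Numeric vector of `config$block_length` samples.
#' @export
synth_peak_block <- function(config = sim_config(), snr = config$peak_snr_median,
                             fwhm_s = config$fov_width / config$speed_mean,
                             seed = NULL) {
  n <- config$block_length
  fwhm <- fwhm_s * config$sampling_rate
  stopifnot(fwhm < n)
  seeded_rng(seed)
  gaussian_pulse(n, (n + 1) / 2, fwhm, snr * config$noise_sd) +
    synth_background(n, config)
}

#' Synthetic artifact block
#'
#' `"spike"`: an abrupt rectangular impulse 1-3 samples wide at
#' `snr * noise_sd`, emulating instrument electrical noise on a single probe.
#' `"motion"`: a broad bump flagged for coincident insertion on both probes
#' by the assembler (simultaneous two-probe signal, as animal motion
#' produces).
#'
#' @param config A [sim_config()].
#' @param snr Apex amplitude in noise_sd units.
#' @param kind `"spike"` or `"motion"`.
#' @param width Spike width in samples (drawn from `config$spike_widths` when
#'   NULL).
#' @param seed Optional seed.
#' @return Numeric vector of `config$block_length` samples with attributes
#'   `kind` and `dual_probe` (TRUE for motion artifacts).
#' @export
synth_artifact_block <- function(config = sim_config(),
                                 snr = config$artifact_snr_median,
                                 kind = config$artifact_kind, width = NULL,
                                 seed = NULL) {
  n <- config$block_length
  seeded_rng(seed)
  x <- synth_background(n, config)
  mid <- (n + 1L) %/% 2L
  if (kind == "spike") {
    if (is.null(width)) width <- sample(config$spike_widths, 1)
    at <- mid + seq_len(width) - 1L - width %/% 2L
    x[at] <- x[at] + snr * config$noise_sd
  } else {
    x <- x + gaussian_pulse(n, mid, 0.05 * config$sampling_rate,
                            snr * config$noise_sd / 3)
  }
  structure(x, kind = kind, dual_probe = identical(kind, "motion"))
}

rtrunc_speed <- function(n, mean, sd, lower = 20) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= lower))
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Assemble a two-probe in-silico scan with ground truth
#'
#' Builds a full scan from the structured block sequence (see [sim_config()])
#' repeated `repetitions` times with background spacers drawn to fill the
#' requested duration exactly. Each repetition contributes one forward
#' transit — a peak on probe 1 followed by its partner on probe 2 after
#' `separation / speed` seconds, with matched widths and heights (small
#' jitter) — and one artifact on each probe, all recorded in the ground-truth
#' ledger. The opposite channel under any single-probe event carries
#' background only. Defaults produce exactly `2 * repetitions` peak events
#' and `2 * repetitions` artifact events.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return A [difc_scan()] with `annotations` filled in, plus a `transits`
#'   data.frame (pair_id, drawn speed, realized delay and FWHM in samples)
#'   for delay-recovery checks.
#' @export
assemble_scan <- function(config = sim_config(), seed = config$seed) {
  seeded_rng(seed)
  rate <- config$sampling_rate
  n <- as.integer(round(config$duration * rate))
  reps <- config$repetitions
  bl <- config$block_length
  # per repetition: artifact(p2), transit region, artifact(p1) = 3 blocks
  used <- reps * 3L * bl
  n_spacers <- 3L * reps + 1L
  free <- n - used
  if (free < n_spacers)
    stop("infeasible packing: duration too short for requested repetitions")
  w <- stats::runif(n_spacers, 0.5, 1.5)
  spacer <- floor(free * w / sum(w))
  spacer[n_spacers] <- spacer[n_spacers] + (free - sum(spacer))
  ch <- list(synth_background(n, config), synth_background(n, config))
  ev <- list()
  pos <- 1L + spacer[1]
  si <- 2L
  add_event <- function(idx, probe, kind, pair_id = NA, direction = NA)
    ev[[length(ev) + 1L]] <<- list(sample_index = idx, probe = probe,
                                   kind = kind, pair_id = pair_id,
                                   direction = direction)
  insert_spike <- function(probe, at) {
    width <- sample(config$spike_widths, 1)
    snr <- stats::rlnorm(1, log(config$artifact_snr_median),
                         config$artifact_snr_sdlog)
    cols <- at + seq_len(width) - 1L - width %/% 2L
    ch[[probe]][cols] <<- ch[[probe]][cols] + snr * config$noise_sd
    if (config$artifact_kind == "motion") {
      other <- 3L - probe
      bump <- gaussian_pulse(bl, bl %/% 2L, 0.05 * rate,
                             snr * config$noise_sd / 3)
      span <- (at - bl %/% 2L) + seq_len(bl) - 1L
      keep <- span >= 1L & span <= n
      ch[[probe]][span[keep]] <<- ch[[probe]][span[keep]] + bump[keep]
      ch[[other]][span[keep]] <<- ch[[other]][span[keep]] + bump[keep]
      add_event(at, other, "artifact")
    }
    add_event(at, probe, "artifact")
  }
  pair_id <- 0L
  transits <- vector("list", reps)
  for (r in seq_len(reps)) {
    # artifact on probe 2
    insert_spike(2L, pos + bl %/% 2L)
    pos <- pos + bl + spacer[si]; si <- si + 1L
    # forward transit: probe 1 peak then probe 2 peak, delay = sep / speed
    speed <- rtrunc_speed(1, config$speed_mean, config$speed_sd)
    delay <- as.integer(round(config$probe_separation / speed * rate))
    fwhm <- config$fov_width / speed * rate
    snr <- stats::rlnorm(1, log(config$peak_snr_median), config$peak_snr_sdlog)
    c1 <- pos + as.integer(0.4 * bl)
    c2 <- c1 + delay
    pair_id <- pair_id + 1L
    jit <- stats::runif(2, 0.98, 1.02)
    span <- pos:(pos + bl - 1L)
    ch[[1]][span] <- ch[[1]][span] +
      gaussian_pulse(bl, c1 - pos + 1L, fwhm, snr * config$noise_sd * jit[1])
    ch[[2]][span] <- ch[[2]][span] +
      gaussian_pulse(bl, c2 - pos + 1L, fwhm * jit[2], snr * config$noise_sd)
    add_event(c1, 1L, "peak", pair_id, "forward")
    add_event(c2, 2L, "peak", pair_id, "forward")
    transits[[r]] <- data.frame(pair_id = pair_id, speed = speed,
                                delay_samples = delay,
                                fwhm_samples = fwhm)
    pos <- pos + bl + spacer[si]; si <- si + 1L
    # artifact on probe 1
    insert_spike(1L, pos + bl %/% 2L)
    pos <- pos + bl + spacer[si]; si <- si + 1L
  }
  evd <- do.call(rbind, lapply(ev, as.data.frame))
  ann <- ground_truth_events(evd$sample_index, evd$probe, evd$kind,
                             pair_id = evd$pair_id, direction = evd$direction)
  scan <- difc_scan(ch[[1]], ch[[2]], sampling_rate = rate,
                    probe_separation = config$probe_separation,
                    scan_id = sprintf("insilico_seed%s",
                                      if (is.null(seed)) "NA" else format(seed)),
                    annotations = ann)
  # in-memory extra: per-transit drawn speed and realized delay, for
  # delay-recovery checks (not part of the on-disk scan format)
  scan$transits <- do.call(rbind, transits)
  scan
}

#' Build a labeled window corpus from simulated scans
#'
#' Generates dense simulated scans, runs the real preprocessing chain
#' ([preprocess_scan()]) on them, matches detected candidates to ground-truth
#' events, and extracts labeled two-probe windows from the normalized
#' channels. Labeling candidates through the actual pipeline (rather than
#' synthesizing isolated windows) guarantees training windows share the
#' normalization and amplitude statistics of windows the deployed classifier
#' will see.
#'
#' @param n_peaks,n_artifacts Number of labeled windows per class (>= 1).
#' @param config A [sim_config()]; repetitions/duration are overridden to fit
#'   the requested counts.
#' @param pipeline A [difc_config()] used for preprocessing.
#' @param seed Integer seed.
#' @return A labeled `difc_corpus` with `n_peaks + n_artifacts` windows,
#'   values in \[0, 1\].
#' @export
build_labeled_corpus <- function(n_peaks = 2200, n_artifacts = 2200,
                                 config = sim_config(),
                                 pipeline = difc_config(), seed = NULL) {
  stopifnot(n_peaks >= 1, n_artifacts >= 1)
  seeded_rng(seed)
  rate <- config$sampling_rate
  # each repetition yields 2 peak and 2 artifact events (spike mode); build
  # in chunks of at most 250 repetitions to bound per-scan memory
  need_reps <- ceiling(max(n_peaks, n_artifacts) / 2 * 1.05) + 2L
  got_p <- 0L; got_a <- 0L
  peak_w <- list(); art_w <- list()
  chunk_id <- 0L
  while (got_p < n_peaks || got_a < n_artifacts) {
    chunk_id <- chunk_id + 1L
    reps <- min(250L, need_reps)
    need_reps <- max(need_reps - reps, 25L)
    cfg <- config
    cfg$repetitions <- reps
    cfg$duration <- ceiling(reps * (3 * cfg$block_length + 3 * 600) / rate) + 2
    scan <- assemble_scan(cfg, seed = NULL)  # RNG stream continues from seed
    pp <- preprocess_scan(scan, pipeline)
    lab <- label_candidates(pp$candidates, scan$annotations,
                            tol = cfg$block_length %/% 4L)
    for (i in seq_len(nrow(lab))) {
      if (is.na(lab$label[i])) next
      w <- extract_window(pp$processed, lab$sample_index[i],
                          length = pipeline$window_length,
                          origin_probe = lab$probe[i], label = lab$label[i])
      if (lab$label[i] == 1L && got_p < n_peaks) {
        peak_w[[length(peak_w) + 1L]] <- w; got_p <- got_p + 1L
      } else if (lab$label[i] == 0L && got_a < n_artifacts) {
        art_w[[length(art_w) + 1L]] <- w; got_a <- got_a + 1L
      }
    }
    if (chunk_id > 40L) stop("could not collect requested window counts")
  }
  out <- bind_corpora(difc_corpus(peak_w), difc_corpus(art_w),
                      provenance = "simulated labeled corpus")
  out[sample.int(length(out))]
}

# Assign each candidate the kind of the nearest same-probe ground-truth event
# within tol samples (label 1 = peak, 0 = artifact, NA = no event nearby).
label_candidates <- function(candidates, annotations, tol = 200L) {
  lab <- rep(NA_integer_, nrow(candidates))
  for (p in 1:2) {
    ci <- which(candidates$probe == p)
    ei <- which(annotations$probe == p)
    if (!length(ci) || !length(ei)) next
    for (i in ci) {
      d <- abs(annotations$sample_index[ei] - candidates$sample_index[i])
      j <- which.min(d)
      if (d[j] <= tol)
        lab[i] <- as.integer(annotations$kind[ei[j]] == "peak")
    }
  }
  cbind(candidates, label = lab)
}
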