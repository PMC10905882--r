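#' Data-cleaning thresholds
#'
#' Configuration of the automated surrogate for the study's manual
#' screening of recordings. All levels are relative to the recording's
#' peak smoothed envelope unless stated otherwise.
#'
#' @param silent_level minimum peak envelope for a non-silent recording
#'   (absolute amplitude).
#' @param min_duration_s minimum recording duration (seconds).
#' @param smooth_s envelope smoothing window (seconds).
#' @param peak_level envelope level that opens a flight episode.
#' @param valley_level envelope level that must be crossed downwards
#'   before a second episode can open (episode separation).
#' @param clip_level absolute amplitude counted as saturated.
#' @param clip_fraction saturated-sample fraction above which a
#'   recording is a wall hit.
#' @param edge_level envelope level at the first/last samples above
#'   which the transit is considered truncated (wall hit).
#' @return list of thresholds for [clean_recording()].
#' @export
cleaning_config <- function(silent_level = 0.05, min_duration_s = 0.02,
                            smooth_s = 0.01, peak_level = 0.55,
                            valley_level = 0.35, clip_level = 0.985,
                            clip_fraction = 0.02, edge_level = 0.5) {
  list(
    silent_level = silent_level, min_duration_s = min_duration_s,
    smooth_s = smooth_s, peak_level = peak_level,
    valley_level = valley_level, clip_level = clip_level,
    clip_fraction = clip_fraction, edge_level = edge_level
  )
}

#' Screen a recording for validity
#'
#' Automated replacement for the manual data-cleaning step: recordings
#' whose smoothed amplitude envelope shows two separated flight episodes
#' are flagged `DOUBLE_FLIGHT`; recordings with a saturated signal or an
#' envelope truncated at an edge (the insect striking the tube wall) are
#' flagged `WALL_HIT`; degenerate inputs are `TOO_SHORT` or `SILENT`.
#'
#' @param rec a `wb_recording` (or list with `samples`, `sample_rate`).
#' @param config thresholds from [cleaning_config()].
#' @return list with `valid` (logical) and `reason` (one of `"OK"`,
#'   `"DOUBLE_FLIGHT"`, `"WALL_HIT"`, `"TOO_SHORT"`, `"SILENT"`);
#'   `valid` is `TRUE` iff `reason == "OK"`.
#' @export
clean_recording <- function(rec, config = cleaning_config()) {
  x <- rec$samples
  if (is.null(x) || length(x) == 0) stop("empty waveform")
  sr <- rec$sample_rate
  verdict <- function(reason) list(valid = reason == "OK", reason = reason)

  if (length(x) < config$min_duration_s * sr) return(verdict("TOO_SHORT"))
  env <- smooth_envelope(x, max(1L, round(config$smooth_s * sr)))
  peak <- max(env)
  if (peak < config$silent_level) return(verdict("SILENT"))

  clipped <- mean(abs(x) >= config$clip_level)
  edge_n <- max(1L, round(0.02 * length(env)))
  edge <- max(mean(env[seq_len(edge_n)]), mean(env[seq(length(env) - edge_n + 1, length(env))]))
  if (clipped > config$clip_fraction || edge > config$edge_level * peak) {
    return(verdict("WALL_HIT"))
  }

  if (count_episodes(env, config$peak_level * peak, config$valley_level * peak) >= 2) {
    return(verdict("DOUBLE_FLIGHT"))
  }
  verdict("OK")
}

# Moving-average of |x| with edge padding.
smooth_envelope <- function(x, k) {
  a <- abs(x)
  if (k <= 1) return(a)
  padded <- c(rep(a[1], k), a, rep(a[length(a)], k))
  cs <- cumsum(padded)
  w <- 2L * (k %/% 2L) + 1L
  sm <- (cs[seq_along(a) + k + k %/% 2L] - cs[seq_along(a) + k - k %/% 2L - 1L]) / w
  sm
}

# Count flight episodes: an episode opens when the envelope rises above
# `high` while armed, and the detector re-arms only after the envelope
# falls below `low`.
count_episodes <- function(env, high, low) {
  episodes <- 0L
  armed <- TRUE
  for (v in env) {
    if (armed && v >= high) {
      episodes <- episodes + 1L
      armed <- FALSE
    } else if (!armed && v < low) {
      armed <- TRUE
    }
  }
  episodes
}

#' Spectrogram feature settings
#'
#' @param window_length STFT window length (samples).
#' @param overlap fractional window overlap in \[0, 1).
#' @param max_freq upper frequency bound of the retained bins (Hz);
#'   2000 Hz covers the wingbeat fundamentals and first harmonics of the
#'   modelled classes at the default 8 kHz sampling rate.
#' @param f0_min,f0_max search bounds for the fundamental estimate (Hz).
#' @param n_harmonics harmonics multiplied in the harmonic product
#'   spectrum.
#' @return list of settings for [compute_spectrogram()].
#' @export
spectrogram_config <- function(window_length = 256, overlap = 0.5,
                               max_freq = 2000, f0_min = 100, f0_max = 1200,
                               n_harmonics = 3) {
  stopifnot(overlap >= 0, overlap < 1, window_length >= 8)
  list(
    window_length = as.integer(window_length), overlap = overlap,
    max_freq = max_freq, f0_min = f0_min, f0_max = f0_max,
    n_harmonics = n_harmonics
  )
}

#' Short-time Fourier features of a recording
#'
#' Computes the Hann-windowed STFT magnitude matrix cropped to
#' `[0, max_freq]`, a fixed-length flat feature vector (per-frequency-bin
#' mean magnitude over frames, so transits of different duration map to
#' the same feature length), and a fundamental-frequency estimate from
#' the harmonic product spectrum, refined on a zero-padded full-signal
#' spectrum to sub-bin resolution.
#'
#' @param rec a `wb_recording` (or list with `samples`, `sample_rate`).
#' @param config settings from [spectrogram_config()].
#' @return a `wb_spectrogram`: list with `mag` (bins x frames, >= 0),
#'   `freq`, `time`, `freq_resolution` (Hz/bin), `time_resolution`
#'   (s/frame), `flat_vector`, `f0_estimate` (Hz; `NA` when undefined)
#'   and `f0_defined`.
#' @export
compute_spectrogram <- function(rec, config = spectrogram_config()) {
  x <- rec$samples
  sr <- rec$sample_rate
  if (config$window_length > length(x)) {
    stop("window_length (", config$window_length, ") exceeds signal length (",
         length(x), ")")
  }
  n <- config$window_length
  hop <- n - round(config$overlap * n)
  sp <- signal::specgram(x, n = n, Fs = sr, window = signal::hanning(n),
                         overlap = n - hop)
  mag <- abs(sp$S)
  keep <- sp$f <= config$max_freq
  f0 <- estimate_f0(x, sr, config)
  structure(
    list(
      mag = mag[keep, , drop = FALSE],
      freq = sp$f[keep], time = sp$t,
      freq_resolution = sr / n, time_resolution = hop / sr,
      flat_vector = rowMeans(mag[keep, , drop = FALSE]),
      f0_estimate = f0, f0_defined = !is.na(f0)
    ),
    class = "wb_spectrogram"
  )
}

# Fundamental estimate: coarse peak of a weighted harmonic-sum spectrum
# (geometric down-weighting of higher harmonics suppresses the
# subharmonic ambiguity of the plain harmonic product, and a missing
# harmonic — e.g. a pure tone — does not zero the score), refined by an
# argmax on a zero-padded spectrum (~0.5 Hz resolution at 8 kHz).
estimate_f0 <- function(x, sr, config = spectrogram_config()) {
  if (max(abs(x)) == 0) return(NA_real_)
  nfft <- 2^ceiling(log2(max(length(x) * 8, 4096)))
  spec <- Mod(stats::fft(c(x * hann_window(length(x)), rep(0, nfft - length(x)))))
  spec <- spec[seq_len(nfft %/% 2)]
  freq <- (seq_along(spec) - 1) * sr / nfft
  band <- which(freq >= config$f0_min & freq <= config$f0_max)
  if (length(band) == 0) return(NA_real_)
  score <- rep(0, length(band))
  for (h in seq_len(config$n_harmonics)) {
    idx <- pmin((band - 1) * h + 1, length(spec))
    score <- score + 0.7^(h - 1) * spec[idx]
  }
  if (max(score) == 0) return(NA_real_)
  coarse <- freq[band[which.max(score)]]
  # refine on the raw spectrum within a narrow window around the peak
  win <- which(freq >= coarse - 40 & freq <= coarse + 40)
  freq[win[which.max(spec[win])]]
}

#' Extract a feature table from a recording set
#'
#' Runs [clean_recording()] and, for recordings passing the screen (or
#' all recordings when `keep_invalid = TRUE`), computes
#' [compute_spectrogram()] features. The flat spectrogram vector and the
#' fundamental estimate form the feature columns consumed by the
#' classifier and the target-detection density.
#'
#' @param recordings list of `wb_recording` objects.
#' @param config [spectrogram_config()] settings.
#' @param cleaning [cleaning_config()] thresholds; `NULL` skips
#'   screening.
#' @param keep_invalid keep rows for screened-out recordings (their
#'   feature columns are still computed).
#' @return data frame with `id`, `label`, `temperature`, `validity`
#'   (simulator ground truth, `NA` for real data), `verdict` (cleaning
#'   outcome), `f0_estimate` and spectrogram columns `sp001` ...; the
#'   feature columns are `f0_estimate` plus the `sp*` columns (see
#'   [feature_columns()]).
#' @export
extract_features <- function(recordings, config = spectrogram_config(),
                             cleaning = cleaning_config(),
                             keep_invalid = FALSE) {
  if (length(recordings) == 0) {
    return(data.frame(id = integer(), label = character(),
                      temperature = numeric(), validity = character(),
                      verdict = character(), f0_estimate = numeric()))
  }
  verdicts <- if (is.null(cleaning)) {
    rep("OK", length(recordings))
  } else {
    vapply(recordings, function(r) clean_recording(r, cleaning)$reason, "")
  }
  use <- if (keep_invalid) seq_along(recordings) else which(verdicts == "OK")
  feats <- lapply(use, function(i) {
    sp <- compute_spectrogram(recordings[[i]], config)
    c(sp$f0_estimate, sp$flat_vector)
  })
  fm <- do.call(rbind, feats)
  colnames(fm) <- c("f0_estimate", sprintf("sp%03d", seq_len(ncol(fm) - 1)))
  out <- data.frame(
    id = use,
    label = vapply(recordings[use], `[[`, "", "label"),
    temperature = vapply(recordings[use], `[[`, 0, "temperature"),
    validity = vapply(recordings[use], function(r) {
      if (is.null(r$validity)) NA_character_ else r$validity
    }, ""),
    verdict = verdicts[use]
  )
  cbind(out, as.data.frame(fm))
}

#' Names of the feature columns in a feature table
#'
#' @param df a feature table from [extract_features()].
#' @return character vector: `f0_estimate` then the `sp*` columns.
#' @export
feature_columns <- function(df) {
  c("f0_estimate", grep("^sp[0-9]+$", names(df), value = TRUE))
}

#' Write a feature table to CSV
#'
#' One row per recording: id, label, f0 estimate, then the flat
#' spectrogram columns.
#'
#' @param features table from [extract_features()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
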