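# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# Small laboratory corpus with the study's 7.5% invalid fraction.
lab_corpus_small <- function() {
  fixture("lab_corpus_small", {
    recs <- simulate_lab_dataset(n_per_cell = 30, invalid_fraction = 0.075,
                                 seed = 42)
    list(recordings = recs, features = extract_features(recs))
  })
}

# Well-separated classes (tight f0 spread): the classifier problem is
# designed to be easy, so accuracy bounds are guaranteed by construction.
separable_params <- function() {
  lapply(default_wingbeat_params(), function(p) {
    wingbeat_params(p$f0_base, f0_sd = 5, temp_coeff = p$temp_coeff,
                    n_harmonics = p$n_harmonics,
                    harmonic_decay = p$harmonic_decay)
  })
}

separable_features <- function() {
  fixture("separable_features", {
    recs <- simulate_lab_dataset(n_per_cell = 25, invalid_fraction = 0,
                                 params = separable_params(), seed = 43)
    extract_features(recs)
  })
}

# Synthetic labelled feature table with no waveforms behind it (for the
# balancing/splitting contracts, which are label book-keeping).
toy_labelled_table <- function(counts, seed = 1) {
  withr::with_seed(seed, {
    label <- rep(names(counts), counts)
    data.frame(
      row_id = seq_along(label), label = label,
      temperature = sample(c(18, 23, 28), length(label), replace = TRUE),
      f0_estimate = stats::rnorm(length(label), 500, 50),
      sp001 = stats::rnorm(length(label)), sp002 = stats::rnorm(length(label))
    )
  })
}

# Minimal per-cycle count table builder.
make_cycle_counts <- function(sensor, manual, nontarget,
                              excluded = rep(FALSE, nrow(sensor))) {
  stopifnot(ncol(sensor) == 4, ncol(manual) == 4)
  df <- data.frame(cycle_id = sprintf("C%02d", seq_len(nrow(sensor))))
  cols <- c("AeF", "AeM", "CxF", "CxM")
  for (j in 1:4) df[[paste0("sensor_", cols[j])]] <- sensor[, j]
  df$sensor_target_total <- rowSums(sensor)
  for (j in 1:4) df[[paste0("manual_", cols[j])]] <- manual[, j]
  df$manual_nontarget <- nontarget
  df$excluded <- excluded
  df$exclusion_reason <- ifelse(excluded, "depredation", "")
  df
}

# Independent FFT-peak oracle: argmax of the zero-padded magnitude
# spectrum in a frequency band (no reuse of package internals).
fft_peak_oracle <- function(samples, sample_rate, f_lo = 100, f_hi = 1200) {
  nfft <- 2^ceiling(log2(length(samples) * 16))
  spec <- Mod(stats::fft(c(samples, rep(0, nfft - length(samples)))))
  freq <- (seq_len(nfft) - 1) * sample_rate / nfft
  band <- freq >= f_lo & freq <= f_hi
  freq[band][which.max(spec[band])]
}
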