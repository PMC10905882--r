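#' Simulate the optical signal of one insect transit
#'
#' Synthesises the waveform an optical wingbeat sensor records while a
#' single insect passes through its sensing zone: the wing flap
#' modulates the light beam periodically at the wingbeat fundamental and
#' its harmonics, while the body's passage through the beam imposes a
#' smooth transit envelope (raised cosine) on the oscillation. The
#' individual's fundamental is drawn around the class base frequency and
#' scaled by ambient temperature:
#' `f0 = (f0_base + N(0, f0_sd^2)) * (1 + temp_coeff * (T - 28))`.
#'
#' Two invalid-recording morphologies can be requested, mirroring the
#' events a data-cleaning step must reject: `DOUBLE_FLIGHT` superimposes
#' a second insect's transit overlapping the first by at least 25% of
#' its duration, and `WALL_HIT` truncates the envelope abruptly
#' mid-transit with the signal driven into clipping (at least 5% of the
#' active samples saturated).
#'
#' @param label one of [class_labels()].
#' @param temperature ambient temperature (degrees C).
#' @param params a [wingbeat_params()] object for this class; defaults
#'   to the class entry of [default_wingbeat_params()].
#' @param duration transit duration (seconds), > 0.
#' @param sample_rate sampling rate (Hz), > 0.
#' @param noise_sd standard deviation of additive Gaussian sensor noise
#'   (amplitude units).
#' @param amplitude peak envelope amplitude in (0, 1]; if `NULL`, drawn
#'   uniformly in \[0.45, 0.9\] to mimic insects crossing the beam at
#'   different depths.
#' @param validity `"VALID"`, `"DOUBLE_FLIGHT"` or `"WALL_HIT"`.
#' @param timestamp capture date-time (`POSIXct`).
#' @param humidity relative humidity (%).
#' @param seed integer seed; identical seeds give bit-identical
#'   recordings. `NULL` uses the ambient RNG stream.
#' @return a `wb_recording`: list with `samples` (amplitudes in
#'   \[-1, 1\]), `sample_rate`, `timestamp`, `temperature`, `humidity`,
#'   `label`, `validity`, and the simulator ground truth `f0_true` (Hz,
#'   the drawn fundamental of the first insect).
#' @export
simulate_flight_waveform <- function(label, temperature,
                                     params = default_wingbeat_params()[[label]],
                                     duration = 0.1, sample_rate = 8000,
                                     noise_sd = 0.02, amplitude = NULL,
                                     validity = c("VALID", "DOUBLE_FLIGHT", "WALL_HIT"),
                                     timestamp = as.POSIXct("2021-07-01 12:00:00", tz = "UTC"),
                                     humidity = 60, seed = NULL) {
  label <- match.arg(label, class_labels())
  validity <- match.arg(validity)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("`duration` must be a single positive number")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number")
  }
  stopifnot(inherits(params, "wingbeat_params"), noise_sd >= 0)

  with_rng(seed, {
    n <- max(8L, round(duration * sample_rate))
    tt <- seq_len(n) / sample_rate
    f0 <- draw_f0(params, temperature)
    if (params$n_harmonics * f0 > 0.5 * sample_rate) {
      warning("highest harmonic (", round(params$n_harmonics * f0), " Hz) exceeds Nyquist; ",
              "it will alias")
    }
    if (is.null(amplitude)) amplitude <- stats::runif(1, 0.45, 0.9)

    x <- switch(validity,
      VALID = amplitude * hann_window(n) * harmonic_tone(f0, params, tt),
      DOUBLE_FLIGHT = {
        # two transits, each half the window, the second starting at
        # 37.5%: the envelopes overlap by 25% of their duration
        len <- round(0.5 * n)
        e1 <- c(hann_window(len), rep(0, n - len))
        off <- round(0.375 * n)
        e2 <- c(rep(0, off), hann_window(min(len, n - off)))
        e2 <- c(e2, rep(0, n - length(e2)))
        f0b <- draw_f0(params, temperature)
        amplitude * (e1 * harmonic_tone(f0, params, tt) +
                     e2 * harmonic_tone(f0b, params, tt))
      },
      WALL_HIT = {
        # envelope rises normally, then the insect strikes the tube wall:
        # the oscillation stops dead and the preceding signal saturates
        cut <- round(0.55 * n)
        half <- hann_window(2L * cut)[seq_len(cut)]
        env <- c(half, rep(0, n - cut))
        2.4 * env * harmonic_tone(f0, params, tt)
      }
    )
    x <- x + stats::rnorm(n, sd = noise_sd)
    x <- pmin(1, pmax(-1, x))

    structure(
      list(
        samples = x, sample_rate = sample_rate, timestamp = timestamp,
        temperature = temperature, humidity = humidity, label = label,
        validity = validity, f0_true = f0
      ),
      class = "wb_recording"
    )
  })
}

draw_f0 <- function(params, temperature) {
  (params$f0_base + stats::rnorm(1, 0, params$f0_sd)) *
    (1 + params$temp_coeff * (temperature - 28))
}

harmonic_tone <- function(f0, params, tt) {
  h <- seq_len(params$n_harmonics)
  amps <- params$harmonic_decay^(h - 1)
  phases <- stats::runif(length(h), 0, 2 * pi)
  tone <- rep(0, length(tt))
  for (i in seq_along(h)) {
    tone <- tone + amps[i] * sin(2 * pi * h[i] * f0 * tt + phases[i])
  }
  tone / sum(amps)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' @export
print.wb_recording <- function(x, ...) {
  cat(sprintf(
    "<wb_recording> %s %s | %.0f ms @ %g Hz | %.1f degC, %.0f%% RH | f0 = %.1f Hz\n",
    x$label, x$validity, 1000 * length(x$samples) / x$sample_rate,
    x$sample_rate, x$temperature, x$humidity, x$f0_true
  ))
  invisible(x)
}
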