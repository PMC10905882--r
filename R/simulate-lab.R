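#' Simulate a laboratory flight-assay dataset
#'
#' Emulates the laboratory protocol used to build the training corpus:
#' mosquitoes of the four target classes are assayed in a climatic
#' chamber at a ladder of ambient temperatures — both genera at 18, 23
#' and 28 degrees C, *Aedes* additionally at 33 degrees C (close to the upper end
#' of its activity range, beyond that of *Culex pipiens*) — and a known
#' fraction of recordings is corrupted (double flights, wall hits) so
#' the automated cleaning step can be validated against exact ground
#' truth.
#'
#' @param n_per_cell recordings per class-by-temperature cell, used when
#'   `config` is `NULL`.
#' @param invalid_fraction proportion of recordings carrying an invalid
#'   morphology, in \[0, 1); each invalid recording is a double flight
#'   or a wall hit with equal probability.
#' @param config optional data frame with columns `label`,
#'   `temperature`, `n` overriding the default design. Requesting
#'   `CULEX_*` at 33 degrees C triggers a warning and is honoured only when
#'   `allow_culex_33 = TRUE` (the species is not normally assayed there).
#' @param params named list of per-class [wingbeat_params()].
#' @param duration,sample_rate,noise_sd passed to
#'   [simulate_flight_waveform()].
#' @param seed integer seed for reproducibility.
#' @return list of `wb_recording` objects with class, temperature and
#'   validity ground truth attached.
#' @export
simulate_lab_dataset <- function(n_per_cell = 25, invalid_fraction = 0.075,
                                 config = NULL,
                                 params = default_wingbeat_params(),
                                 duration = 0.1, sample_rate = 8000,
                                 noise_sd = 0.02, allow_culex_33 = FALSE,
                                 seed = NULL) {
  stopifnot(invalid_fraction >= 0, invalid_fraction < 1)
  if (is.null(config)) {
    config <- lab_design(n_per_cell)
  }
  stopifnot(all(c("label", "temperature", "n") %in% names(config)),
            all(config$n >= 0), all(config$label %in% class_labels()))
  bad <- startsWith(config$label, "CULEX") & config$temperature >= 33
  if (any(bad)) {
    warning("Culex assays at >= 33 degrees C requested; ",
            if (allow_culex_33) "honouring as configured" else "dropping those cells")
    if (!allow_culex_33) config <- config[!bad, , drop = FALSE]
  }
  config <- config[config$n > 0, , drop = FALSE]
  if (nrow(config) == 0) return(list())

  with_rng(seed, {
    rows <- config[rep(seq_len(nrow(config)), config$n), c("label", "temperature")]
    total <- nrow(rows)
    validity <- ifelse(
      stats::runif(total) < invalid_fraction,
      sample(c("DOUBLE_FLIGHT", "WALL_HIT"), total, replace = TRUE),
      "VALID"
    )
    t0 <- as.POSIXct("2021-03-01 09:00:00", tz = "UTC")
    lapply(seq_len(total), function(i) {
      simulate_flight_waveform(
        label = rows$label[i], temperature = rows$temperature[i],
        params = params[[rows$label[i]]], duration = duration,
        sample_rate = sample_rate, noise_sd = noise_sd,
        validity = validity[i],
        timestamp = t0 + 60 * (i - 1),
        humidity = stats::runif(1, 40, 90), seed = NULL
      )
    })
  })
}

# Default assay design: Aedes classes at 18/23/28/33 degC, Culex at 18/23/28.
lab_design <- function(n_per_cell) {
  aedes <- expand.grid(
    label = c("AEDES_F", "AEDES_M"), temperature = c(18, 23, 28, 33),
    stringsAsFactors = FALSE
  )
  culex <- expand.grid(
    label = c("CULEX_F", "CULEX_M"), temperature = c(18, 23, 28),
    stringsAsFactors = FALSE
  )
  design <- rbind(aedes, culex)
  design$n <- n_per_cell
  design
}
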