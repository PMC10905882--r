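#' Define a field-trial scenario
#'
#' A scenario describes the stochastic structure of a field deployment:
#' a sequence of collection cycles (the interval between placing and
#' collecting the catch bag), per-class expected captures per cycle,
#' per-genus diel activity profiles, a seasonal month-by-month
#' multiplier, and which cycles are invalidated (depredated catch,
#' connectivity loss).
#'
#' @param cycles data frame with columns `cycle_id`, `trial`, `start`,
#'   `end` (`POSIXct`), `excluded` (logical), `exclusion_reason`
#'   (character, `""` when not excluded). Intervals must be disjoint and
#'   ordered.
#' @param class_intensities expected captures per cycle for each class:
#'   either a named numeric vector over [class_labels()] (recycled to
#'   every cycle) or a matrix with one row per cycle and those column
#'   names. Values are Poisson means before the seasonal multiplier.
#' @param diel_profiles named list `Aedes`, `Culex`, `NonTarget`, each a
#'   vector of 24 non-negative weights over hour-of-day summing to 1.
#' @param seasonal_trend numeric vector of 12 multipliers indexed by
#'   calendar month.
#' @return a `field_scenario` object.
#' @export
field_scenario <- function(cycles, class_intensities,
                           diel_profiles = default_diel_profiles(),
                           seasonal_trend = rep(1, 12)) {
  stopifnot(
    is.data.frame(cycles),
    all(c("cycle_id", "start", "end") %in% names(cycles)),
    inherits(cycles$start, "POSIXct"), inherits(cycles$end, "POSIXct"),
    all(cycles$end > cycles$start),
    length(seasonal_trend) == 12, all(seasonal_trend >= 0)
  )
  if (is.null(cycles$trial)) cycles$trial <- 1L
  if (is.null(cycles$excluded)) cycles$excluded <- FALSE
  if (is.null(cycles$exclusion_reason)) cycles$exclusion_reason <- ""
  o <- order(cycles$start)
  if (any(utils::head(cycles$end[o], -1) > cycles$start[o][-1])) {
    stop("collection cycles must be disjoint")
  }
  if (is.null(dim(class_intensities))) {
    stopifnot(all(class_labels() %in% names(class_intensities)))
    class_intensities <- matrix(
      rep(class_intensities[class_labels()], each = nrow(cycles)),
      nrow = nrow(cycles), dimnames = list(NULL, class_labels())
    )
  }
  stopifnot(
    nrow(class_intensities) == nrow(cycles),
    all(class_labels() %in% colnames(class_intensities)),
    all(class_intensities >= 0)
  )
  for (g in c("Aedes", "Culex", "NonTarget")) {
    w <- diel_profiles[[g]]
    stopifnot(length(w) == 24, all(w >= 0))
    if (abs(sum(w) - 1) > 1e-8) stop("diel profile `", g, "` must sum to 1")
  }
  structure(
    list(
      cycles = cycles,
      class_intensities = class_intensities[, class_labels(), drop = FALSE],
      diel_profiles = diel_profiles,
      seasonal_trend = seasonal_trend
    ),
    class = "field_scenario"
  )
}

#' Default diel activity profiles
#'
#' Hour-of-day capture weights reflecting the genera's known behaviour:
#' *Aedes* (day-active) is bimodal with a dawn peak at 06:00 and a dusk
#' peak at 19:00; *Culex* is nocturnal/crepuscular, most active around
#' 23:00 with a smaller post-sunrise shoulder; the pooled non-target
#' insects are mildly day-biased.
#'
#' @return named list of 24-weight vectors (`Aedes`, `Culex`,
#'   `NonTarget`), each summing to 1.
#' @export
default_diel_profiles <- function() {
  h <- 0:23
  wrap <- function(mu, sd) {
    stats::dnorm(h, mu, sd) + stats::dnorm(h - 24, mu, sd) + stats::dnorm(h + 24, mu, sd)
  }
  aedes <- 0.02 + wrap(6, 1) + wrap(19, 1)
  culex <- 0.02 + wrap(23, 2.5) + 0.6 * wrap(6, 1.2)
  nontarget <- 0.5 + wrap(15, 5)
  list(
    Aedes = aedes / sum(aedes),
    Culex = culex / sum(culex),
    NonTarget = nontarget / sum(nontarget)
  )
}

#' Scenario emulating the published two-trial field design
#'
#' Two deployments in a Mediterranean climate: trial 1 with 32
#' collection cycles of 24 h starting mid-July (3 invalidated: 2
#' depredation, 1 connectivity), trial 2 the following year with 21
#' cycles of 48 h starting mid-June (6 invalidated: 5 depredation, 1
#' connectivity), leaving 29 + 15 = 44 analysable cycles. Per-cycle
#' class intensities reproduce the manually-counted catch composition of
#' the study (Culex females dominating the targets; non-target insects
#' roughly half the catch), scaled by a summer-peaked seasonal trend.
#'
#' @param intensity_scale multiplier applied to all class intensities
#'   (1 = published catch sizes; reduce for quick experiments).
#' @return a [field_scenario()].
#' @export
default_field_scenario <- function(intensity_scale = 1) {
  t1_start <- as.POSIXct("2021-07-15 09:00:00", tz = "UTC")
  t1 <- data.frame(
    cycle_id = sprintf("T1C%02d", 1:32), trial = 1L,
    start = t1_start + (0:31) * 86400, end = t1_start + (1:32) * 86400
  )
  t2_start <- as.POSIXct("2022-06-15 09:00:00", tz = "UTC")
  t2 <- data.frame(
    cycle_id = sprintf("T2C%02d", 1:21), trial = 2L,
    start = t2_start + (0:20) * 2 * 86400, end = t2_start + (1:21) * 2 * 86400
  )
  cycles <- rbind(t1, t2)
  cycles$excluded <- FALSE
  cycles$exclusion_reason <- ""
  dep <- c("T1C10", "T1C20", "T2C03", "T2C07", "T2C11", "T2C15", "T2C19")
  conn <- c("T1C27", "T2C21")
  cycles$excluded[cycles$cycle_id %in% c(dep, conn)] <- TRUE
  cycles$exclusion_reason[cycles$cycle_id %in% dep] <- "depredation"
  cycles$exclusion_reason[cycles$cycle_id %in% conn] <- "connectivity"

  per_trial <- rbind(
    c(AEDES_F = 8.1, AEDES_M = 2.5, CULEX_F = 41.5, CULEX_M = 2.1, NON_TARGET = 113.2),
    c(AEDES_F = 24.3, AEDES_M = 11.8, CULEX_F = 86.3, CULEX_M = 6.2, NON_TARGET = 144.3)
  )
  intens <- per_trial[cycles$trial, , drop = FALSE] * intensity_scale
  season <- c(1, 1, 1, 1, 1, 0.9, 1.15, 1.05, 0.7, 0.45, 1, 1)
  field_scenario(cycles, intens, seasonal_trend = season)
}

#' Simulate a field-trial capture stream
#'
#' Draws, for every collection cycle and class, a Poisson number of
#' captures (mean = cycle intensity x seasonal multiplier of the cycle's
#' starting month) with time stamps distributed over the cycle according
#' to the genus diel profile. The returned `truth` table holds the
#' simulated manual (ground-truth) counts per cycle in the same schema
#' used for real per-cycle count tables.
#'
#' Optionally the event stream is degraded by a simple event-level
#' detector-noise model (`detector_noise`), producing per-cycle sensor
#' counts without synthesising waveforms — useful for validating the
#' count-based evaluation against designed error rates. Alternatively
#' `waveforms = TRUE` attaches a full `wb_recording` per event so the
#' complete gate-plus-classifier pipeline can be run on the stream.
#'
#' @param scenario a [field_scenario()].
#' @param detector_noise optional list with elements `miss` (probability
#'   a target event is not counted), `false_alarm` (probability a
#'   non-target event is counted as a target) and optionally
#'   `class_confusion` (4x4 row-stochastic matrix over target classes,
#'   rows = true class, columns = called class; identity when absent).
#' @param waveforms if `TRUE`, synthesise a recording per event.
#' @param params per-class [wingbeat_params()] for waveform synthesis.
#' @param duration,sample_rate,noise_sd waveform synthesis settings.
#' @param seed integer seed.
#' @return list with `events` (data frame: `event_id`, `cycle_id`,
#'   `timestamp`, `true_label`, `temperature`, `humidity`, `excluded`),
#'   `truth` (per-cycle manual counts, Table-S2-style schema),
#'   `recordings` (list of `wb_recording`, when `waveforms = TRUE`) and
#'   `sensor` (per-cycle sensor counts, when `detector_noise` given).
#' @export
simulate_field_trial <- function(scenario, detector_noise = NULL,
                                 waveforms = FALSE,
                                 params = default_wingbeat_params(),
                                 duration = 0.1, sample_rate = 8000,
                                 noise_sd = 0.02, seed = NULL) {
  stopifnot(inherits(scenario, "field_scenario"))
  with_rng(seed, {
    cyc <- scenario$cycles
    ev_list <- vector("list", nrow(cyc) * 5L)
    k <- 0L
    for (i in seq_len(nrow(cyc))) {
      month <- as.integer(format(cyc$start[i], "%m"))
      mult <- scenario$seasonal_trend[month]
      for (lab in class_labels()) {
        lambda <- scenario$class_intensities[i, lab] * mult
        n <- stats::rpois(1, lambda)
        if (n == 0) next
        ts <- draw_diel_times(n, cyc$start[i], cyc$end[i],
                              diel_weights(scenario, lab))
        k <- k + 1L
        ev_list[[k]] <- data.frame(
          cycle_id = cyc$cycle_id[i], timestamp = ts, true_label = lab,
          excluded = cyc$excluded[i]
        )
      }
    }
    if (k == 0) {
      events <- data.frame(
        event_id = integer(), cycle_id = character(),
        timestamp = as.POSIXct(character(), tz = "UTC"),
        true_label = character(), temperature = numeric(),
        humidity = numeric(), excluded = logical()
      )
    } else {
      events <- do.call(rbind, ev_list[seq_len(k)])
      events <- events[order(events$timestamp), , drop = FALSE]
      events$temperature <- ambient_temperature(events$timestamp)
      events$humidity <- stats::runif(nrow(events), 40, 95)
      events <- data.frame(event_id = seq_len(nrow(events)), events,
                           row.names = NULL)
    }

    truth <- truth_counts(cyc, events)
    out <- list(events = events, truth = truth)

    if (!is.null(detector_noise)) {
      out$sensor <- apply_detector_noise(events, detector_noise, seed = NULL)
    }
    if (waveforms) {
      out$recordings <- lapply(seq_len(nrow(events)), function(j) {
        simulate_flight_waveform(
          label = events$true_label[j], temperature = events$temperature[j],
          params = params[[events$true_label[j]]], duration = duration,
          sample_rate = sample_rate, noise_sd = noise_sd,
          timestamp = events$timestamp[j], humidity = events$humidity[j]
        )
      })
    }
    out
  })
}

diel_weights <- function(scenario, label) {
  genus <- if (label == "NON_TARGET") "NonTarget" else label_genus(label)
  scenario$diel_profiles[[genus]]
}

# Rejection-sample time stamps in [start, end) with the hour-of-day
# weight profile (piecewise constant per hour).
draw_diel_times <- function(n, start, end, weights) {
  wmax <- max(weights)
  span <- as.numeric(difftime(end, start, units = "secs"))
  out <- as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    cand <- start + stats::runif(m, 0, span)
    hr <- as.integer(format(cand, "%H"))
    keep <- stats::runif(m) < weights[hr + 1L] / wmax
    take <- min(sum(keep), n - got)
    if (take > 0) {
      out[(got + 1L):(got + take)] <- cand[keep][seq_len(take)]
      got <- got + take
    }
  }
  out
}

# Smooth seasonal + diurnal ambient temperature with small noise.
ambient_temperature <- function(ts) {
  month_mean <- c(14, 14, 16, 18, 21, 24, 27, 26, 23, 19, 16, 14)
  m <- as.integer(format(ts, "%m"))
  hr <- as.integer(format(ts, "%H")) + as.integer(format(ts, "%M")) / 60
  month_mean[m] + 4 * cos(2 * pi * (hr - 15) / 24) + stats::rnorm(length(ts), 0, 1)
}

# Per-cycle ground-truth (manual) counts in the per-cycle count schema.
truth_counts <- function(cycles, events) {
  cols <- class_column_map()
  out <- cycles[, c("cycle_id", "trial", "start", "end", "excluded", "exclusion_reason")]
  for (lab in target_labels()) {
    tab <- table(events$cycle_id[events$true_label == lab])
    out[[paste0("manual_", cols[[lab]])]] <-
      as.integer(tab[match(out$cycle_id, names(tab))])
  }
  tab <- table(events$cycle_id[events$true_label == "NON_TARGET"])
  out$manual_nontarget <- as.integer(tab[match(out$cycle_id, names(tab))])
  for (cc in grep("^manual_", names(out), value = TRUE)) {
    out[[cc]][is.na(out[[cc]])] <- 0L
  }
  row.names(out) <- NULL
  out
}

class_column_map <- function() {
  c(AEDES_F = "AeF", AEDES_M = "AeM", CULEX_F = "CxF", CULEX_M = "CxM")
}

#' Degrade a simulated event stream with detector noise
#'
#' Event-level error model used to validate the count-based evaluation:
#' each target event is counted with probability `1 - miss` and, when
#' counted, assigned a called class from the `class_confusion` row of
#' its true class; each non-target event is falsely counted as a target
#' with probability `false_alarm`, with a uniformly-drawn class call.
#'
#' @param events event table from [simulate_field_trial()].
#' @param noise list with `miss`, `false_alarm`, optional
#'   `class_confusion` (4x4 row-stochastic, identity when absent).
#' @param seed integer seed.
#' @return per-cycle sensor counts: `cycle_id`, `sensor_AeF` ...
#'   `sensor_CxM`, `sensor_target_total`.
#' @export
apply_detector_noise <- function(events, noise, seed = NULL) {
  stopifnot(is.list(noise), !is.null(noise$miss), !is.null(noise$false_alarm))
  conf <- noise$class_confusion
  if (is.null(conf)) conf <- diag(4)
  stopifnot(all(dim(conf) == c(4, 4)), all(abs(rowSums(conf) - 1) < 1e-8))
  with_rng(seed, {
    calls <- rep(NA_character_, nrow(events))
    is_target <- events$true_label %in% target_labels()
    for (j in which(is_target)) {
      if (stats::runif(1) >= noise$miss) {
        row <- match(events$true_label[j], target_labels())
        calls[j] <- sample(target_labels(), 1, prob = conf[row, ])
      }
    }
    for (j in which(!is_target)) {
      if (stats::runif(1) < noise$false_alarm) {
        calls[j] <- sample(target_labels(), 1)
      }
    }
    sensor_counts(events$cycle_id, calls, unique(events$cycle_id))
  })
}

# Aggregate per-event class calls (NA = not counted) into per-cycle
# sensor counts.
sensor_counts <- function(cycle_id, calls, all_cycles) {
  cols <- class_column_map()
  out <- data.frame(cycle_id = all_cycles)
  for (lab in target_labels()) {
    tab <- table(cycle_id[!is.na(calls) & calls == lab])
    out[[paste0("sensor_", cols[[lab]])]] <-
      as.integer(tab[match(out$cycle_id, names(tab))])
  }
  for (cc in grep("^sensor_", names(out), value = TRUE)) {
    out[[cc]][is.na(out[[cc]])] <- 0L
  }
  out$sensor_target_total <- out$sensor_AeF + out$sensor_AeM +
    out$sensor_CxF + out$sensor_CxM
  out
}
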