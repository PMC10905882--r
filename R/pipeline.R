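#' Pipeline configuration
#'
#' Nested configuration shared by the laboratory and field pipelines.
#' Any argument omitted keeps its default; unknown keys are rejected to
#' catch typos in config files.
#'
#' @param simulation list: `lab` (`n_per_cell`, `invalid_fraction`,
#'   `noise_sd`, `duration`, `sample_rate`), `field`
#'   (`intensity_scale`), `calibration` (`n_target`, `n_nontarget` for
#'   the threshold-calibration stream).
#' @param features list: `window_length`, `overlap`, `max_freq`,
#'   `f0_min`, `f0_max`, `n_harmonics`, and `cleaning` thresholds (see
#'   [cleaning_config()]).
#' @param classifier list: `n_folds`, `n_test`, `grid`.
#' @param detection list: `ridge`, `n_components`, `threshold` (numeric
#'   log-density, or `"calibrate"`).
#' @param evaluation list: `orientation` (`"sensor_on_manual"` or
#'   `"manual_on_sensor"`; both are always computed, this names the
#'   headline one).
#' @return nested configuration list of class `wb_config`.
#' @export
pipeline_config <- function(simulation = list(), features = list(),
                            classifier = list(), detection = list(),
                            evaluation = list()) {
  defaults <- list(
    simulation = list(
      lab = list(n_per_cell = 60, invalid_fraction = 0.075, noise_sd = 0.02,
                 duration = 0.1, sample_rate = 8000),
      field = list(intensity_scale = 1),
      calibration = list(n_target = 400, n_nontarget = 400)
    ),
    features = c(spectrogram_config(), list(cleaning = cleaning_config())),
    classifier = list(n_folds = 4, n_test = 200,
                      grid = default_hyperparameter_grid()),
    detection = list(ridge = 1e-6, n_components = 8, threshold = "calibrate"),
    evaluation = list(orientation = "sensor_on_manual")
  )
  user <- list(simulation = simulation, features = features,
               classifier = classifier, detection = detection,
               evaluation = evaluation)
  cfg <- merge_config(defaults, user, path = "config")
  class(cfg) <- "wb_config"
  cfg
}

# Recursive override of defaults; unknown keys error with their path.
merge_config <- function(defaults, user, path) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s) under ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  for (key in names(user)) {
    defaults[[key]] <- if (is.list(defaults[[key]]) && !is.data.frame(defaults[[key]])) {
      merge_config(defaults[[key]], user[[key]], paste(path, key, sep = "$"))
    } else {
      user[[key]]
    }
  }
  defaults
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the same nested sections as [pipeline_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `wb_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("simulation", "features", "classifier", "detection", "evaluation")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$classifier$grid)) {
    raw$classifier$grid <- as.data.frame(raw$classifier$grid)
  }
  do.call(pipeline_config, raw)
}

cfg_spectrogram <- function(config) {
  f <- config$features
  spectrogram_config(
    window_length = f$window_length, overlap = f$overlap,
    max_freq = f$max_freq, f0_min = f$f0_min, f0_max = f$f0_max,
    n_harmonics = f$n_harmonics
  )
}

#' Run the laboratory pipeline
#'
#' Simulates the laboratory flight assays, screens the recordings,
#' extracts features, balances the classes, holds out a stratified test
#' set, trains and evaluates the genus-and-sex classifier, fits the
#' target-detection density on the training features, and calibrates
#' the detection threshold on a labelled calibration stream (simulated
#' captures of target mosquitoes and non-target insects, standing in
#' for the study's unpublished prior field data).
#'
#' @param config a [pipeline_config()].
#' @param seed integer root seed; every stage derives its own child
#'   stream, so runs are reproducible end to end.
#' @param out_dir optional directory for artifacts (feature CSV,
#'   confusion CSV, metrics JSON, model files, run manifest).
#' @return list with `report` (classifier evaluation), `model`,
#'   `detector`, `threshold`, `features` (valid-recording feature
#'   table), `counts` (received / rejected / used / train / test
#'   reconciliation) and `manifest`.
#' @export
run_lab_pipeline <- function(config = pipeline_config(), seed = 1,
                             out_dir = NULL) {
  stopifnot(inherits(config, "wb_config"))
  lab <- config$simulation$lab
  sp_cfg <- cfg_spectrogram(config)
  cl_cfg <- do.call(cleaning_config, config$features$cleaning)

  recs <- simulate_lab_dataset(
    n_per_cell = lab$n_per_cell, invalid_fraction = lab$invalid_fraction,
    noise_sd = lab$noise_sd, duration = lab$duration,
    sample_rate = lab$sample_rate, seed = child_seed(seed, 1)
  )
  feats <- extract_features(recs, sp_cfg, cl_cfg)
  balanced <- balance_by_undersampling(feats, seed = child_seed(seed, 2))
  split <- split_test_set(balanced, config$classifier$n_test,
                          seed = child_seed(seed, 3))
  model <- train_classifier(split$train, n_folds = config$classifier$n_folds,
                            grid = config$classifier$grid,
                            seed = child_seed(seed, 4))
  report <- evaluate_classifier(model, split$test)

  detector <- fit_detection_model(
    split$train, n_components = config$detection$n_components,
    ridge = config$detection$ridge
  )
  threshold <- if (identical(config$detection$threshold, "calibrate")) {
    calib <- simulate_calibration_stream(config, seed = child_seed(seed, 5))
    calibrate_threshold(detector$density,
                        project_scores(detector, calib$features),
                        calib$is_target)
  } else {
    detection_threshold(config$detection$threshold)
  }

  counts <- c(
    received = length(recs),
    rejected = length(recs) - nrow(feats),
    used = nrow(feats),
    balanced = nrow(balanced),
    train = nrow(split$train),
    test = nrow(split$test)
  )
  manifest <- run_manifest(seed, config, stage = "lab")
  result <- list(
    report = report, model = model, detector = detector,
    threshold = threshold, features = feats, counts = counts,
    manifest = manifest
  )
  if (!is.null(out_dir)) write_lab_artifacts(result, out_dir)
  result
}

# Labelled capture stream for threshold calibration: target mosquitoes
# across classes/temperatures plus non-target insects.
simulate_calibration_stream <- function(config, seed) {
  lab <- config$simulation$lab
  n_t <- config$simulation$calibration$n_target
  n_n <- config$simulation$calibration$n_nontarget
  sp_cfg <- cfg_spectrogram(config)
  with_rng(seed, {
    labels <- c(sample(target_labels(), n_t, replace = TRUE),
                rep("NON_TARGET", n_n))
    temps <- sample(c(18, 23, 28, 33), length(labels), replace = TRUE)
    recs <- lapply(seq_along(labels), function(i) {
      simulate_flight_waveform(
        labels[i], temps[i], duration = lab$duration,
        sample_rate = lab$sample_rate, noise_sd = lab$noise_sd
      )
    })
    feats <- extract_features(recs, sp_cfg, cleaning = NULL)
    list(features = feats, is_target = feats$label != "NON_TARGET")
  })
}

project_scores <- function(detector, features) {
  X <- detector_matrix(features)[, detector$columns, drop = FALSE]
  scale(X, center = detector$center, scale = detector$scale) %*%
    detector$rotation
}

#' Run the field pipeline
#'
#' Streams a simulated field deployment through the trained artifacts:
#' each recording is screened, gated by the Gaussian target detector,
#' and — when called a target — classified by genus and sex; per-cycle
#' sensor counts are joined with the simulated manual counts and
#' evaluated with the count-based procedures (detection and
#' genus-and-sex balanced accuracy, Pearson correlation, linear
#' regression in both orientations, hourly-by-month activity profiles).
#'
#' @param config a [pipeline_config()].
#' @param model trained `wb_classifier` from [run_lab_pipeline()].
#' @param detector fitted `wb_detector`.
#' @param threshold a [detection_threshold()].
#' @param scenario a [field_scenario()]; defaults to
#'   [default_field_scenario()] scaled by the config's
#'   `intensity_scale`.
#' @param seed integer root seed.
#' @param out_dir optional artifact directory.
#' @return list with `cycle_counts` (per-cycle sensor + manual table),
#'   `detection` and `genus_sex` evaluations, `correlation`,
#'   `regression` (both orientations, target detection and genus-sex),
#'   `activity` (profile table), `reconciliation` (received /
#'   screened-out / gated non-target / classified counts) and
#'   `manifest`.
#' @export
run_field_pipeline <- function(config, model, detector, threshold,
                               scenario = NULL, seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "wb_config"), inherits(model, "wb_classifier"),
            inherits(detector, "wb_detector"))
  if (is.null(scenario)) {
    scenario <- default_field_scenario(config$simulation$field$intensity_scale)
  }
  lab <- config$simulation$lab
  sp_cfg <- cfg_spectrogram(config)
  cl_cfg <- do.call(cleaning_config, config$features$cleaning)

  sim <- simulate_field_trial(
    scenario, waveforms = TRUE, duration = lab$duration,
    sample_rate = lab$sample_rate, noise_sd = lab$noise_sd,
    seed = child_seed(seed, 11)
  )
  n_ev <- nrow(sim$events)
  calls <- rep(NA_character_, n_ev)
  screened_out <- 0L
  gated_nontarget <- 0L
  if (n_ev > 0) {
    feats <- extract_features(sim$recordings, sp_cfg, cleaning = NULL)
    verdict_ok <- vapply(
      sim$recordings, function(r) clean_recording(r, cl_cfg)$valid, TRUE
    )
    screened_out <- sum(!verdict_ok)
    ld <- detection_log_density(detector, feats)
    thr <- if (inherits(threshold, "detection_threshold")) threshold$value else threshold
    is_target_call <- verdict_ok & (ld >= thr)
    gated_nontarget <- sum(verdict_ok & !is_target_call)
    if (any(is_target_call)) {
      calls[is_target_call] <- predict(model, feats[is_target_call, , drop = FALSE])
    }
  }
  sensor <- sensor_counts(sim$events$cycle_id, calls, sim$truth$cycle_id)
  cycle_counts <- merge(sim$truth, sensor, by = "cycle_id", sort = FALSE)

  active <- cycle_counts[!cycle_counts$excluded, , drop = FALSE]
  detection_eval <- evaluate_target_detection(cycle_counts)
  genus_eval <- evaluate_genus_sex(cycle_counts)
  manual_tot <- manual_target_total(active)
  correlation <- list(
    target_detection = pearson_correlation(active$sensor_target_total, manual_tot)
  )
  cols <- class_column_map()
  class_sensor <- unlist(lapply(unname(cols), function(s) active[[paste0("sensor_", s)]]))
  class_manual <- unlist(lapply(unname(cols), function(s) active[[paste0("manual_", s)]]))
  correlation$genus_sex <- pearson_correlation(class_sensor, class_manual)
  regression <- list(
    target_detection = list(
      sensor_on_manual = linear_regression(active$sensor_target_total, manual_tot),
      manual_on_sensor = linear_regression(manual_tot, active$sensor_target_total)
    ),
    genus_sex = list(
      sensor_on_manual = linear_regression(class_sensor, class_manual),
      manual_on_sensor = linear_regression(class_manual, class_sensor)
    )
  )

  target_events <- which(!is.na(calls))
  activity <- compute_activity_profile(
    data.frame(
      timestamp = sim$events$timestamp[target_events],
      genus = label_genus(calls[target_events])
    ),
    period_start = min(scenario$cycles$start),
    period_end = max(scenario$cycles$end)
  )

  reconciliation <- c(
    received = n_ev, screened_out = screened_out,
    gated_nontarget = gated_nontarget,
    classified_target = sum(!is.na(calls))
  )
  stopifnot(sum(reconciliation[-1]) == reconciliation[["received"]])

  manifest <- run_manifest(seed, config, stage = "field")
  result <- list(
    cycle_counts = cycle_counts, detection = detection_eval,
    genus_sex = genus_eval, correlation = correlation,
    regression = regression, activity = activity,
    reconciliation = reconciliation, manifest = manifest
  )
  if (!is.null(out_dir)) write_field_artifacts(result, out_dir)
  result
}

run_manifest <- function(seed, config, stage) {
  list(
    stage = stage, seed = seed,
    package_version = as.character(utils::packageVersion("wingbeatr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = strip_config(config)
  )
}

strip_config <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (is.list(x)) return(lapply(unclass(x), strip_config))
  x
}

write_lab_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_features_csv(result$features, file.path(out_dir, "lab_features.csv"))
  utils::write.csv(as.data.frame.matrix(result$report$confusion),
                   file.path(out_dir, "confusion.csv"))
  jsonlite::write_json(
    list(
      mean_ba = result$report$mean_ba,
      per_class_ba = as.list(result$report$per_class_ba),
      counts = as.list(result$counts),
      threshold = result$threshold$value,
      calibration_ba = result$threshold$calibration_ba
    ),
    file.path(out_dir, "lab_metrics.json"), auto_unbox = TRUE, digits = NA
  )
  save_classifier(result$model, file.path(out_dir, "classifier"))
  save_detector(result$detector, file.path(out_dir, "detector"),
                threshold = result$threshold)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

write_field_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cycle_counts(result$cycle_counts, file.path(out_dir, "cycle_counts.csv"))
  utils::write.csv(result$detection$per_cycle,
                   file.path(out_dir, "detection_per_cycle.csv"), row.names = FALSE)
  utils::write.csv(result$genus_sex$per_cycle,
                   file.path(out_dir, "genus_sex_per_cycle.csv"), row.names = FALSE)
  utils::write.csv(result$activity, file.path(out_dir, "activity_profile.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(
      detection_summary = result$detection$summary,
      genus_sex_per_class = result$genus_sex$per_class,
      genus_sex_overall = result$genus_sex$overall,
      correlation = result$correlation,
      regression = result$regression,
      reconciliation = as.list(result$reconciliation)
    ),
    file.path(out_dir, "field_metrics.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
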