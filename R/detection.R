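#' Fit a multivariate Gaussian density to laboratory features
#'
#' Computes the sample mean and covariance of the target-mosquito
#' feature rows and precomputes the Cholesky factor and log
#' normalisation constant, so the density is evaluable entirely in log
#' space. A small ridge (relative to the mean diagonal) keeps the
#' covariance positive definite.
#'
#' @param x numeric matrix (rows = recordings, columns = features).
#' @param ridge non-negative ridge added to the diagonal as
#'   `ridge * mean(diag(cov))` (or `ridge * I` when the covariance is
#'   identically zero). Must be > 0 when `nrow(x) < ncol(x) + 1`.
#' @return a `gaussian_density`: `mean`, `covariance` (ridged), `ridge`,
#'   `chol`, `log_norm_const`.
#' @export
fit_density <- function(x, ridge = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least 2 rows are required to fit a density")
  stopifnot(ridge >= 0)
  d <- ncol(x)
  if (nrow(x) < d + 1 && ridge == 0) {
    stop("fewer rows (", nrow(x), ") than dimension + 1 (", d + 1,
         "): a positive `ridge` is required")
  }
  mu <- colMeans(x)
  S <- stats::cov(x)
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  S <- S + diag(ridge * scale, d)
  ch <- tryCatch(chol(S), error = function(e) {
    stop("covariance is not positive definite; increase `ridge`")
  })
  structure(
    list(
      mean = mu, covariance = S, ridge = ridge, chol = ch,
      log_norm_const = -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))))
    ),
    class = "gaussian_density"
  )
}

#' Multivariate normal log-density
#'
#' Exact log-density
#' `-0.5 * ((x - mu)' Sigma^-1 (x - mu) + log det(2 pi Sigma))`
#' evaluated via the model's Cholesky factor.
#'
#' @param model a [fit_density()] object.
#' @param x numeric vector of the model dimension, or a matrix with one
#'   row per point.
#' @return numeric vector of log densities.
#' @export
log_density <- function(model, x) {
  stopifnot(inherits(model, "gaussian_density"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean)) {
    stop("dimension mismatch: model has ", length(model$mean),
         " features, input has ", ncol(x))
  }
  centered <- sweep(x, 2, model$mean)
  z <- backsolve(model$chol, t(centered), transpose = TRUE)
  model$log_norm_const - 0.5 * colSums(z^2)
}

#' Detection threshold on the log-density scale
#'
#' @param value log-density threshold (finite).
#' @param calibration_ba balanced accuracy achieved on the calibration
#'   set (%), if known.
#' @return a `detection_threshold`.
#' @export
detection_threshold <- function(value, calibration_ba = NA_real_) {
  stopifnot(is.numeric(value), length(value) == 1, !is.na(value))
  structure(list(value = value, calibration_ba = calibration_ba),
            class = "detection_threshold")
}

#' Gate recordings as target mosquitoes or non-targets
#'
#' A recording is called `TARGET` when its log-density under the
#' laboratory model is greater than *or equal to* the threshold
#' (equality counts as a target), otherwise `NON_TARGET`.
#'
#' @param model a [fit_density()] object.
#' @param threshold a [detection_threshold()] (or a bare number on the
#'   log-density scale).
#' @param x feature vector or matrix of rows.
#' @return character vector of `"TARGET"` / `"NON_TARGET"`.
#' @export
classify_target <- function(model, threshold, x) {
  if (inherits(threshold, "detection_threshold")) threshold <- threshold$value
  ld <- log_density(model, x)
  ifelse(ld >= threshold, "TARGET", "NON_TARGET")
}

#' Calibrate the detection threshold on a labelled stream
#'
#' Scans every observed log-density (plus infinite sentinels) as a
#' candidate threshold and returns the one maximising the event-level
#' balanced accuracy (mean of the target-recall and non-target-recall),
#' emulating the study's fine-tuning of the gate on previously collected
#' labelled captures. Ties are broken toward the higher (stricter)
#' threshold.
#'
#' @param model a [fit_density()] object.
#' @param x calibration features (matrix or feature-table rows).
#' @param is_target logical vector: `TRUE` for target mosquitoes.
#' @return a [detection_threshold()] with `calibration_ba` in %.
#' @export
calibrate_threshold <- function(model, x, is_target) {
  stopifnot(is.logical(is_target))
  if (!any(is_target) || all(is_target)) {
    stop("calibration set must contain both target and non-target rows")
  }
  ld <- log_density(model, x)
  stopifnot(length(ld) == length(is_target))
  candidates <- c(-Inf, sort(unique(ld)), Inf)
  ba <- vapply(candidates, function(th) {
    pred <- ld >= th
    (mean(pred[is_target]) + mean(!pred[!is_target])) / 2
  }, 0)
  best <- max(ba)
  # ties toward the stricter (higher) threshold; the +Inf sentinel is
  # replaced by a value just above the largest observation
  pick <- max(which(ba == best))
  value <- candidates[pick]
  if (!is.finite(value)) {
    value <- if (value > 0) max(ld) + 1 else min(ld) - 1
  }
  detection_threshold(value, calibration_ba = 100 * best)
}

#' Fit the target-detection model in a reduced feature space
#'
#' The classifier's feature space (flat spectrogram vector plus
#' fundamental estimate) is high-dimensional relative to desk-scale
#' corpora, so the density is fitted on the leading principal components
#' of the standardised laboratory target features (default 8). The
#' projection (centering, scaling, rotation) is stored so field
#' recordings map through identically.
#'
#' @param features feature table of laboratory *target* recordings
#'   ([extract_features()] output) or a bare numeric matrix.
#' @param n_components number of principal components retained.
#' @param ridge ridge passed to [fit_density()].
#' @return a `wb_detector`: projection parameters plus the
#'   `gaussian_density` over scores.
#' @export
fit_detection_model <- function(features, n_components = 8, ridge = 1e-6) {
  X <- detector_matrix(features)
  keep <- apply(X, 2, stats::var) > 0
  if (!any(keep)) stop("all feature columns have zero variance")
  X <- X[, keep, drop = FALSE]
  n_components <- min(n_components, ncol(X), nrow(X) - 1)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  structure(
    list(
      columns = colnames(X), kept = keep,
      center = pc$center, scale = pc$scale,
      rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
      density = fit_density(scores, ridge = ridge),
      n_components = n_components
    ),
    class = "wb_detector"
  )
}

detector_matrix <- function(features) {
  if (is.matrix(features)) {
    X <- features
    if (is.null(colnames(X))) colnames(X) <- sprintf("V%03d", seq_len(ncol(X)))
    X
  } else {
    as.matrix(features[, feature_columns(features), drop = FALSE])
  }
}

#' Log-density of recordings under a fitted detector
#'
#' @param detector a [fit_detection_model()] object.
#' @param features feature table or matrix with the detector's columns.
#' @return numeric vector of log densities in the component space.
#' @export
detection_log_density <- function(detector, features) {
  X <- detector_matrix(features)
  X <- X[, detector$columns, drop = FALSE]
  scores <- scale(X, center = detector$center, scale = detector$scale) %*%
    detector$rotation
  log_density(detector$density, scores)
}

#' Persist / restore a detection model as CSV + JSON header
#'
#' The density is stored as plain text: a CSV whose first row is the
#' mean and remaining rows the covariance, plus a JSON header with the
#' projection and threshold metadata.
#'
#' @param detector a `wb_detector`.
#' @param path directory for `density.csv`, `projection.csv`,
#'   `header.json`.
#' @param threshold optional [detection_threshold()] recorded in the
#'   header.
#' @return `path` (`save_detector`) or the restored `wb_detector` with
#'   `$threshold` (`load_detector`).
#' @export
save_detector <- function(detector, path, threshold = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    rbind(detector$density$mean, detector$density$covariance),
    file.path(path, "density.csv"), row.names = FALSE
  )
  proj <- data.frame(
    column = detector$columns, center = detector$center,
    scale = detector$scale, detector$rotation
  )
  utils::write.csv(proj, file.path(path, "projection.csv"), row.names = FALSE)
  header <- list(
    format = "wingbeatr-detector/1",
    ridge = detector$density$ridge, dimension = detector$n_components,
    threshold = if (is.null(threshold)) NULL else threshold$value,
    calibration_ba = if (is.null(threshold)) NULL else threshold$calibration_ba
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  dens <- as.matrix(utils::read.csv(file.path(path, "density.csv")))
  proj <- utils::read.csv(file.path(path, "projection.csv"))
  scores_cov <- dens[-1, , drop = FALSE]
  mu <- dens[1, ]
  rot <- as.matrix(proj[, -(1:3), drop = FALSE])
  d <- length(mu)
  ch <- chol(scores_cov)
  detector <- structure(
    list(
      columns = proj$column, kept = NULL,
      center = stats::setNames(proj$center, proj$column),
      scale = stats::setNames(proj$scale, proj$column),
      rotation = rot,
      density = structure(
        list(mean = mu, covariance = scores_cov, ridge = header$ridge,
             chol = ch,
             log_norm_const = -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))))),
        class = "gaussian_density"
      ),
      n_components = header$dimension
    ),
    class = "wb_detector"
  )
  if (!is.null(header$threshold)) {
    detector$threshold <- detection_threshold(
      header$threshold,
      calibration_ba = header$calibration_ba %||% NA_real_
    )
  }
  detector
}

`%||%` <- function(a, b) if (is.null(a)) b else a
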