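#' Balance a labelled feature table by random under-sampling
#'
#' Every target class is reduced to the size of the smallest class by
#' sampling rows without replacement, mirroring the study's balancing of
#' the laboratory corpus before training.
#'
#' @param data feature table with a `label` column restricted to
#'   [target_labels()].
#' @param seed integer seed; the selected subset is deterministic given
#'   the seed.
#' @return the balanced feature table.
#' @export
balance_by_undersampling <- function(data, seed = NULL) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  counts <- table(data$label)
  if (any(counts == 0)) {
    stop("class has no rows: ", paste(names(counts)[counts == 0], collapse = ", "))
  }
  m <- min(counts)
  with_rng(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(data)), data$label), function(idx) {
      if (length(idx) == m) idx else sample(idx, m)
    }), use.names = FALSE)
    data[sort(keep), , drop = FALSE]
  })
}

#' Set aside a class-stratified test set
#'
#' Holds out `n_test` rows, `n_test / 4` from each target class, before
#' any training takes place (the study reserved 1000 flights this way).
#'
#' @param data feature table with a `label` column.
#' @param n_test total test rows; must be divisible by the number of
#'   classes present and leave at least one training row per class.
#' @param seed integer seed.
#' @return list with `train` and `test` tables; the two share no rows.
#' @export
split_test_set <- function(data, n_test, seed = NULL) {
  stopifnot(is.data.frame(data), "label" %in% names(data), n_test >= 0)
  classes <- sort(unique(data$label))
  if (n_test == 0) {
    return(list(train = data, test = data[0, , drop = FALSE]))
  }
  if (n_test %% length(classes) != 0) {
    stop("`n_test` must be divisible by the number of classes (",
         length(classes), ")")
  }
  per_class <- n_test / length(classes)
  counts <- table(data$label)
  if (any(counts <= per_class)) {
    stop("`n_test` too large: class ",
         names(counts)[which.min(counts)], " has only ", min(counts), " rows")
  }
  with_rng(seed, {
    test_idx <- unlist(lapply(split(seq_len(nrow(data)), data$label), function(idx) {
      sample(idx, per_class)
    }), use.names = FALSE)
    list(
      train = data[setdiff(seq_len(nrow(data)), test_idx), , drop = FALSE],
      test = data[sort(test_idx), , drop = FALSE]
    )
  })
}

#' Default hyper-parameter grid for the gradient-boosted classifier
#'
#' A small grid over tree depth and learning rate searched by
#' cross-validated mean balanced accuracy.
#'
#' @return data frame with columns `max_depth`, `eta`, `nrounds`.
#' @export
default_hyperparameter_grid <- function() {
  expand.grid(max_depth = c(3, 6), eta = c(0.1, 0.3), nrounds = 60)
}

#' Train the genus-and-sex classifier
#'
#' Fits a gradient-boosted decision-tree ensemble (XGBoost, softmax over
#' the four target classes) on laboratory features. Hyper-parameters are
#' selected from a small grid by stratified k-fold cross-validation
#' (folds stratified jointly by class and, when present, temperature,
#' since both factors structure the laboratory corpus); the winning
#' configuration is refit on the full training set.
#'
#' @param train feature table with `label` (target classes) and the
#'   [feature_columns()]; a `temperature` column, when present, enters
#'   the fold stratification (it is not a predictor).
#' @param n_folds number of cross-validation folds (>= 2; the study used
#'   4).
#' @param grid hyper-parameter grid, see [default_hyperparameter_grid()].
#' @param seed integer seed; fold assignment and tree fitting are
#'   deterministic given the seed (single-threaded).
#' @return a `wb_classifier`: the fitted booster, feature names, class
#'   levels, per-configuration CV results (`cv_results`, mean BA in %)
#'   and the selected row (`best`).
#' @export
train_classifier <- function(train, n_folds = 4,
                             grid = default_hyperparameter_grid(),
                             seed = NULL) {
  stopifnot(is.data.frame(train), "label" %in% names(train), n_folds >= 2)
  classes <- target_labels()[target_labels() %in% unique(train$label)]
  stopifnot(all(train$label %in% classes))
  if (any(table(train$label) < n_folds)) {
    stop("each class needs at least `n_folds` rows")
  }
  fcols <- feature_columns(train)
  X <- as.matrix(train[, fcols, drop = FALSE])
  storage.mode(X) <- "double"
  if (all(apply(X, 2, stats::var, na.rm = TRUE) == 0)) {
    stop("degenerate features: zero variance in every column")
  }
  y <- match(train$label, classes) - 1L

  with_rng(seed, {
    folds <- stratified_folds(train$label, train$temperature, n_folds)
    cv <- grid
    cv$mean_ba <- NA_real_
    for (g in seq_len(nrow(grid))) {
      bas <- numeric(n_folds)
      for (k in seq_len(n_folds)) {
        hold <- folds == k
        bst <- fit_xgb(X[!hold, , drop = FALSE], y[!hold], grid[g, ],
                       n_class = length(classes))
        pred <- predict_xgb(bst, X[hold, , drop = FALSE], length(classes))
        cm <- confusion_matrix(classes[y[hold] + 1L], classes[pred], classes)
        bas[k] <- mean(per_class_ba(cm), na.rm = TRUE)
      }
      cv$mean_ba[g] <- mean(bas)
    }
    best <- which.max(cv$mean_ba)
    booster <- fit_xgb(X, y, grid[best, ], n_class = length(classes))
    structure(
      list(
        booster = booster, feature_names = fcols, classes = classes,
        cv_results = cv, best = grid[best, , drop = FALSE],
        n_folds = n_folds
      ),
      class = "wb_classifier"
    )
  })
}

# Fold assignment stratified by class x temperature.
stratified_folds <- function(label, temperature, n_folds) {
  strata <- if (is.null(temperature)) label else paste(label, temperature)
  folds <- integer(length(label))
  for (idx in split(seq_along(label), strata)) {
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

fit_xgb <- function(X, y, hp, n_class) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = list(
      objective = "multi:softprob", num_class = n_class,
      max_depth = hp$max_depth, eta = hp$eta,
      nthread = 1, verbosity = 0
    ),
    data = dtrain, nrounds = hp$nrounds, verbose = 0
  )
}

# Class index predictions (1-based); argmax ties broken toward the
# lowest class index for determinism.
predict_xgb <- function(booster, X, n_class) {
  max.col(softprob_matrix(booster, X, n_class), ties.method = "first")
}

softprob_matrix <- function(booster, X, n_class) {
  p <- predict(booster, xgboost::xgb.DMatrix(X))
  if (is.matrix(p)) p else matrix(p, ncol = n_class, byrow = TRUE)
}

#' Predict classes or class probabilities
#'
#' @param object a `wb_classifier`.
#' @param newdata feature table (or matrix) with the model's feature
#'   columns.
#' @param type `"class"` for labels, `"prob"` for the probability
#'   matrix.
#' @param ... unused.
#' @return character vector of labels, or a numeric matrix of class
#'   probabilities.
#' @export
predict.wb_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else {
    as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  storage.mode(X) <- "double"
  p <- softprob_matrix(object$booster, X, length(object$classes))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

#' Evaluate the classifier on a held-out test set
#'
#' Builds the test confusion matrix and the per-class one-vs-rest
#' balanced accuracies at the event level: for each class,
#' `Se = TP / (TP + FN)` over its own rows and `Sp = TN / (TN + FP)`
#' pooling all other classes as negatives, with `BA = (Se + Sp) / 2`.
#' The headline figure is the unweighted mean of the four per-class BAs.
#'
#' @param model a `wb_classifier`.
#' @param test feature table with `label` and the model's feature
#'   columns.
#' @return a `wb_classifier_report`: `confusion` (true class x predicted
#'   class), `per_class_ba` (named, %; `NA` with a flag for classes
#'   absent from the test set), `mean_ba` (%), `n`.
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(nrow(test) > 0)
  pred <- predict(model, test)
  cm <- confusion_matrix(test$label, pred, model$classes)
  ba <- per_class_ba(cm)
  structure(
    list(
      confusion = cm,
      per_class_ba = 100 * ba,
      undefined_classes = names(ba)[is.na(ba)],
      mean_ba = 100 * mean(ba, na.rm = TRUE),
      n = nrow(test)
    ),
    class = "wb_classifier_report"
  )
}

confusion_matrix <- function(truth, pred, classes) {
  table(
    true = factor(truth, levels = classes),
    predicted = factor(pred, levels = classes)
  )
}

# One-vs-rest BA per class from a confusion matrix (proportions, NA for
# classes with no true rows).
per_class_ba <- function(cm) {
  total <- sum(cm)
  vapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    if (tp + fn == 0) return(NA_real_)
    se <- tp / (tp + fn)
    sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    mean(c(se, sp), na.rm = TRUE)
  }, 0, USE.NAMES = FALSE) -> ba
  names(ba) <- rownames(cm)
  ba
}

#' @export
print.wb_classifier_report <- function(x, ...) {
  cat("<wb_classifier_report>\n")
  cat(sprintf("  test rows: %d\n", x$n))
  cat(sprintf("  mean balanced accuracy: %.1f%%\n", x$mean_ba))
  for (cl in names(x$per_class_ba)) {
    cat(sprintf("    %-10s %.1f%%\n", cl, x$per_class_ba[cl]))
  }
  invisible(x)
}

#' Persist / restore a trained classifier
#'
#' The booster is stored via XGBoost's own serialisation with a JSON
#' header (format version, feature names, classes, CV table).
#'
#' @param model a `wb_classifier`.
#' @param path directory to write `model.ubj` + `header.json` into.
#' @return `path` (`save_classifier`) or the restored `wb_classifier`
#'   (`load_classifier`).
#' @export
save_classifier <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(path, "model.ubj"))
  header <- list(
    format = "wingbeatr-classifier/1", classes = model$classes,
    feature_names = model$feature_names, best = as.list(model$best),
    cv_results = model$cv_results, n_folds = model$n_folds
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  structure(
    list(
      booster = xgboost::xgb.load(file.path(path, "model.ubj")),
      feature_names = header$feature_names, classes = header$classes,
      cv_results = header$cv_results, best = as.data.frame(header$best),
      n_folds = header$n_folds
    ),
    class = "wb_classifier"
  )
}
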