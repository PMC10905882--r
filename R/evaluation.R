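#' Count-based confusion from aggregate per-cycle counts
#'
#' The field evaluation has no per-event ground truth, only aggregate
#' counts per collection cycle, so the confusion counts follow the
#' count-matching rule: `TP` is the minimum common value of the sensor
#' and manual counts; if the sensor count exceeds the manual count the
#' excess is `FP`, otherwise the deficit is `FN`; `TN` is the manual
#' negative count minus `FP` (floored at zero with a flag when the
#' false positives exceed the available negatives).
#'
#' @param sensor_pos sensor count of the positive class (vectorised).
#' @param manual_pos manual count of the positive class.
#' @param manual_neg manual count of the negative class(es).
#' @return data frame with `tp`, `fp`, `fn`, `tn` and
#'   `tn_deficit` (`TRUE` where `fp > manual_neg`).
#' @export
count_confusion <- function(sensor_pos, manual_pos, manual_neg) {
  if (any(c(sensor_pos, manual_pos, manual_neg) < 0)) {
    stop("counts must be non-negative")
  }
  tp <- pmin(sensor_pos, manual_pos)
  fp <- pmax(sensor_pos - manual_pos, 0)
  fn <- pmax(manual_pos - sensor_pos, 0)
  data.frame(
    tp = tp, fp = fp, fn = fn,
    tn = pmax(manual_neg - fp, 0),
    tn_deficit = fp > manual_neg
  )
}

#' Sensitivity, specificity and balanced accuracy from confusion counts
#'
#' `Se = TP / (TP + FN)`, `Sp = TN / (TN + FP)`,
#' `BA = (Se + Sp) / 2`. Components with an empty denominator are
#' undefined (`NA`): when only one component is defined the BA equals
#' that component and is flagged `ba_partial`; when neither is defined
#' the BA is `NA` (such cycles drop out of averages).
#'
#' @param confusion data frame from [count_confusion()] (columns `tp`,
#'   `fp`, `fn`, `tn`).
#' @return data frame with `se`, `sp`, `ba` (proportions in \[0, 1\]),
#'   `se_defined`, `sp_defined`, `ba_partial`.
#' @export
balanced_accuracy <- function(confusion) {
  se <- ifelse(confusion$tp + confusion$fn > 0,
               confusion$tp / (confusion$tp + confusion$fn), NA_real_)
  sp <- ifelse(confusion$tn + confusion$fp > 0,
               confusion$tn / (confusion$tn + confusion$fp), NA_real_)
  ba <- rowMeans(cbind(se, sp), na.rm = TRUE)
  ba[is.nan(ba)] <- NA_real_
  data.frame(
    se = se, sp = sp, ba = ba,
    se_defined = !is.na(se), sp_defined = !is.na(sp),
    ba_partial = xor(is.na(se), is.na(sp))
  )
}

#' Distribution summary of a percentage-scale metric
#'
#' Mean, median, first and third quartiles (linear interpolation
#' between order statistics, R's default quantile convention) and IQR,
#' all in percent.
#'
#' @param x numeric vector of proportions in \[0, 1\]; `NA`s are
#'   dropped.
#' @return named list `mean`, `median`, `iqr`, `q1`, `q3` (%).
#' @export
summary_stats <- function(x) {
  x <- 100 * x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(mean = mean(x), median = q[2], iqr = q[3] - q[1], q1 = q[1], q3 = q[3])
}

#' Read / write a per-cycle count table
#'
#' CSV schema mirroring the study's supplementary per-cycle table, so a
#' real export can be dropped in: one row per collection cycle with
#' columns `cycle_id`, `start`, `end`, `sensor_AeF`, `sensor_AeM`,
#' `sensor_CxF`, `sensor_CxM`, `sensor_target_total`, `manual_AeF`,
#' `manual_AeM`, `manual_CxF`, `manual_CxM`, `manual_nontarget`,
#' `excluded`, `exclusion_reason` (plus optional `trial`).
#'
#' @param path CSV file path.
#' @param cycles per-cycle count data frame.
#' @return `read_cycle_counts`: the validated data frame;
#'   `write_cycle_counts`: `path`, invisibly.
#' @export
read_cycle_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cycle_counts(df)
}

#' @rdname read_cycle_counts
#' @export
write_cycle_counts <- function(cycles, path) {
  utils::write.csv(cycles, path, row.names = FALSE)
  invisible(path)
}

count_cols <- function() {
  c("sensor_AeF", "sensor_AeM", "sensor_CxF", "sensor_CxM",
    "sensor_target_total", "manual_AeF", "manual_AeM", "manual_CxF",
    "manual_CxM", "manual_nontarget")
}

validate_cycle_counts <- function(df) {
  needed <- c("cycle_id", count_cols())
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("per-cycle table is missing columns: ", paste(missing, collapse = ", "))
  }
  for (cc in count_cols()) {
    if (any(df[[cc]] < 0, na.rm = TRUE)) stop("negative counts in ", cc)
  }
  if (is.null(df$excluded)) df$excluded <- FALSE
  df$excluded <- as.logical(df$excluded)
  df
}

manual_target_total <- function(cycles) {
  cycles$manual_AeF + cycles$manual_AeM + cycles$manual_CxF + cycles$manual_CxM
}

active_cycles <- function(cycles) {
  cycles <- validate_cycle_counts(cycles)
  out <- cycles[!cycles$excluded, , drop = FALSE]
  if (nrow(out) == 0) stop("all cycles are excluded")
  out
}

#' Per-cycle evaluation of target-mosquito detection
#'
#' For each non-excluded collection cycle the positives are the target
#' mosquitoes (sensor target total vs. the sum of the four manual class
#' counts) and the negatives the manually counted non-target insects;
#' count-based confusion and balanced accuracy are computed per cycle
#' and summarised over cycles.
#'
#' @param cycles per-cycle count table (see [read_cycle_counts()]).
#' @return list with `per_cycle` (cycle id, confusion counts, `se`,
#'   `sp`, `ba`) and `summary` ([summary_stats()] of the per-cycle BA,
#'   in %).
#' @export
evaluate_target_detection <- function(cycles) {
  cyc <- active_cycles(cycles)
  conf <- count_confusion(cyc$sensor_target_total, manual_target_total(cyc),
                          cyc$manual_nontarget)
  met <- balanced_accuracy(conf)
  per_cycle <- cbind(cyc[, "cycle_id", drop = FALSE], conf, met)
  list(per_cycle = per_cycle, summary = summary_stats(met$ba))
}

#' Per-cycle evaluation of genus-and-sex classification
#'
#' One-vs-rest count-based evaluation of the four target classes: for
#' each class and cycle the positives are that class's counts and the
#' negatives the sum of the other three classes' manual counts.
#' Summaries are per class over cycles, plus an overall table: the
#' overall average BA is the unweighted mean of the four per-class mean
#' BAs, and the overall distribution statistics pool the per-cycle
#' per-class BA values.
#'
#' @param cycles per-cycle count table (see [read_cycle_counts()]).
#' @return list with `per_cycle` (long table: cycle id, class,
#'   confusion, `se`, `sp`, `ba`), `per_class` (per-class
#'   [summary_stats()]), and `overall` (`mean_ba` plus pooled summary).
#' @export
evaluate_genus_sex <- function(cycles) {
  cyc <- active_cycles(cycles)
  cols <- class_column_map()
  long <- lapply(target_labels(), function(lab) {
    sfx <- cols[[lab]]
    manual_pos <- cyc[[paste0("manual_", sfx)]]
    others <- setdiff(unname(cols), sfx)
    manual_neg <- Reduce(`+`, lapply(paste0("manual_", others), function(cc) cyc[[cc]]))
    conf <- count_confusion(cyc[[paste0("sensor_", sfx)]], manual_pos, manual_neg)
    met <- balanced_accuracy(conf)
    cbind(data.frame(cycle_id = cyc$cycle_id, class = lab), conf, met)
  })
  per_cycle <- do.call(rbind, long)
  per_class <- lapply(stats::setNames(long, target_labels()),
                      function(df) summary_stats(df$ba))
  class_means <- vapply(per_class, `[[`, 0, "mean")
  list(
    per_cycle = per_cycle,
    per_class = per_class,
    overall = c(
      list(mean_ba = mean(class_means)),
      list(pooled = summary_stats(per_cycle$ba))
    )
  )
}

#' Pearson correlation between per-cycle counts
#'
#' Standard Pearson coefficient with the two-sided p-value from the
#' t-statistic on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of per-cycle counts (length >= 3, both
#'   with non-zero variance).
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("at least 3 cycles are required")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Ordinary least-squares regression between per-cycle counts
#'
#' Fits `response = intercept + slope * predictor` and reports the
#' coefficient of determination and the slope's two-sided t-test
#' p-value. A slope below one (with sensor counts as the response and
#' manual counts as the predictor) reads as the sensor systematically
#' undercounting.
#'
#' @param response,predictor numeric vectors (length >= 3; the
#'   predictor must vary).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
linear_regression <- function(response, predictor) {
  stopifnot(length(response) == length(predictor))
  if (length(response) < 3) stop("at least 3 cycles are required")
  if (stats::var(predictor) == 0) stop("constant predictor: regression undefined")
  fit <- stats::lm(response ~ predictor)
  # exact agreement is a legitimate input (identity checks); silence
  # summary.lm's perfect-fit warning only
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  r2 <- if (stats::var(response) == 0) 0 else sm$r.squared
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    p_value = sm$coefficients["predictor", "Pr(>|t|)"],
    n = length(response)
  )
}

#' Average hourly count per month (diel activity profile)
#'
#' For each calendar month and genus, the counts falling in each hour
#' of the day are totalled over the month and divided by the number of
#' days of that month covered by the trial period, giving the average
#' hourly count the sensor registered — the quantity plotted as daily /
#' seasonal activity dynamics.
#'
#' @param events data frame with a `timestamp` (`POSIXct`) column and
#'   either a `genus` column or a class `label` column (mapped via
#'   [label_genus()]; non-target rows are dropped).
#' @param period_start,period_end bounds of the trial period; default to
#'   the range of the time stamps (flagged in the result).
#' @return data frame with `month` (`"YYYY-MM"`), `genus`, `hour`
#'   (0-23), `mean_count`, `days_covered`; empty input gives an empty
#'   profile. The attribute `period_inferred` records whether the
#'   period was taken from the data.
#' @export
compute_activity_profile <- function(events, period_start = NULL,
                                     period_end = NULL) {
  if (is.null(events$genus)) {
    stopifnot(!is.null(events$label))
    events$genus <- label_genus(events$label)
  }
  events <- events[!is.na(events$genus), , drop = FALSE]
  if (nrow(events) == 0) {
    out <- data.frame(month = character(), genus = character(),
                      hour = integer(), mean_count = numeric(),
                      days_covered = integer())
    attr(out, "period_inferred") <- is.null(period_start) || is.null(period_end)
    return(out)
  }
  inferred <- is.null(period_start) || is.null(period_end)
  if (is.null(period_start)) period_start <- min(events$timestamp)
  if (is.null(period_end)) period_end <- max(events$timestamp)
  stopifnot(all(events$timestamp >= period_start),
            all(events$timestamp <= period_end))

  days <- seq(as.Date(period_start), as.Date(period_end), by = "day")
  days_per_month <- table(format(days, "%Y-%m"))
  months <- names(days_per_month)
  genera <- sort(unique(events$genus))

  ev_month <- format(events$timestamp, "%Y-%m")
  ev_hour <- as.integer(format(events$timestamp, "%H"))
  grid <- expand.grid(month = months, genus = genera, hour = 0:23,
                      stringsAsFactors = FALSE)
  grid$mean_count <- mapply(function(m, g, h) {
    sum(ev_month == m & events$genus == g & ev_hour == h)
  }, grid$month, grid$genus, grid$hour) /
    as.integer(days_per_month[grid$month])
  grid$days_covered <- as.integer(days_per_month[grid$month])
  grid <- grid[order(grid$month, grid$genus, grid$hour), , drop = FALSE]
  row.names(grid) <- NULL
  attr(grid, "period_inferred") <- inferred
  grid
}
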