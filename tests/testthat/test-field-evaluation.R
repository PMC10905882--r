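test_that("count-based confusion follows the count-matching rule", {
  expect_equal(as.list(count_confusion(5, 5, 10))[1:4],
               list(tp = 5, fp = 0, fn = 0, tn = 10))
  expect_equal(as.list(count_confusion(8, 10, 20))[1:4],
               list(tp = 8, fp = 0, fn = 2, tn = 20))
  expect_equal(as.list(count_confusion(12, 10, 20))[1:4],
               list(tp = 12 - 2, fp = 2, fn = 0, tn = 18))
  expect_error(count_confusion(-1, 5, 5), "non-negative")
})

test_that("count confusion matches a best-case event-matching oracle", {
  # oracle: enumerate the TP count that maximises correct calls; the
  # remaining sensor excess must fall on negatives and the deficit on
  # missed positives
  oracle <- function(s, m, neg) {
    best <- NULL
    for (tp in 0:min(s, m)) {
      fp <- s - tp
      fn <- m - tp
      if (fp > neg) next
      cand <- list(tp = tp, fp = fp, fn = fn, tn = neg - fp)
      if (is.null(best) || (cand$tp + cand$tn) > (best$tp + best$tn)) {
        best <- cand
      }
    }
    best
  }
  withr::with_seed(1, {
    for (i in 1:500) {
      s <- rpois(1, 20); m <- rpois(1, 20); neg <- rpois(1, 40) + s
      got <- count_confusion(s, m, neg)
      want <- oracle(s, m, neg)
      expect_equal(as.list(got)[c("tp", "fp", "fn", "tn")], want)
    }
  })
})

test_that("confusion conservation laws hold for random count triples", {
  withr::with_seed(2, {
    s <- rpois(300, 15); m <- rpois(300, 15); neg <- rpois(300, 30)
    cc <- count_confusion(s, m, neg)
    expect_equal(cc$tp + cc$fn, m)
    expect_equal(cc$tp + cc$fp, s)
    ok <- !cc$tn_deficit
    expect_equal(cc$tn[ok] + cc$fp[ok], neg[ok])
    expect_true(all(cc$tn[!ok] == 0))
  })
})

test_that("balanced accuracy handles defined and undefined components", {
  ba <- balanced_accuracy(data.frame(tp = 5, fp = 0, fn = 0, tn = 10))
  expect_equal(ba$ba, 1)
  ba <- balanced_accuracy(data.frame(tp = 8, fp = 0, fn = 2, tn = 20))
  expect_equal(c(ba$se, ba$sp, ba$ba), c(0.8, 1.0, 0.9))
  ba <- balanced_accuracy(data.frame(tp = 10, fp = 2, fn = 0, tn = 18))
  expect_equal(c(ba$se, ba$sp, ba$ba), c(1.0, 0.9, 0.95))
  # no positives: BA falls back to the defined component, flagged
  ba <- balanced_accuracy(data.frame(tp = 0, fp = 1, fn = 0, tn = 9))
  expect_true(is.na(ba$se))
  expect_equal(ba$ba, 0.9)
  expect_true(ba$ba_partial)
  # nothing defined: BA undefined
  ba <- balanced_accuracy(data.frame(tp = 0, fp = 0, fn = 0, tn = 0))
  expect_true(is.na(ba$ba))
})

test_that("balanced accuracy is invariant to scaling all counts", {
  withr::with_seed(3, {
    for (i in 1:50) {
      cc <- data.frame(tp = rpois(1, 10) + 1, fp = rpois(1, 3),
                       fn = rpois(1, 3), tn = rpois(1, 20) + 1)
      k <- sample(2:7, 1)
      expect_equal(balanced_accuracy(cc)$ba, balanced_accuracy(cc * k)$ba)
    }
  })
})

test_that("per-cycle target detection summarises as designed", {
  # three cycles engineered to BAs of 90, 95 and 100
  cyc <- make_cycle_counts(
    sensor = rbind(c(8, 0, 0, 0), c(12, 0, 0, 0), c(10, 0, 0, 0)),
    manual = rbind(c(10, 0, 0, 0), c(10, 0, 0, 0), c(10, 0, 0, 0)),
    nontarget = c(20, 20, 20)
  )
  ev <- evaluate_target_detection(cyc)
  expect_equal(ev$per_cycle$ba, c(0.90, 0.95, 1.00))
  expect_equal(ev$summary$mean, 95)
  expect_equal(ev$summary$median, 95)

  perfect <- make_cycle_counts(
    sensor = matrix(5, 3, 4), manual = matrix(5, 3, 4), nontarget = c(9, 9, 9)
  )
  ev <- evaluate_target_detection(perfect)
  expect_equal(ev$summary$mean, 100)
  expect_equal(ev$summary$iqr, 0)

  excluded <- perfect
  excluded$excluded <- TRUE
  expect_error(evaluate_target_detection(excluded), "excluded")
})

test_that("excluded cycles are dropped before all statistics", {
  cyc <- make_cycle_counts(
    sensor = rbind(c(5, 5, 5, 5), c(0, 0, 0, 0)),
    manual = rbind(c(5, 5, 5, 5), c(9, 9, 9, 9)),
    nontarget = c(10, 10),
    excluded = c(FALSE, TRUE)
  )
  ev <- evaluate_target_detection(cyc)
  expect_equal(nrow(ev$per_cycle), 1)
  expect_equal(ev$summary$mean, 100)
})

test_that("a designed one-sided detector error surfaces as the expected BA", {
  # miss rate 10%, no false alarms: per-cycle count confusion gives
  # Se = 1 - miss in expectation and Sp = 1, so E[BA] = 95%
  sc <- default_field_scenario(intensity_scale = 0.5)
  sim <- simulate_field_trial(sc, detector_noise = list(miss = 0.1,
                                                        false_alarm = 0),
                              seed = 9)
  cyc <- merge(sim$truth, sim$sensor, by = "cycle_id", sort = FALSE)
  ev <- evaluate_target_detection(cyc)
  # Monte-Carlo bound: per-cycle BA averages over 44 cycles; with target
  # totals >= ~25 per cycle the standard error of the mean is < 1 point
  expect_lt(abs(ev$summary$mean - 95), 3)
})

test_that("genus and sex evaluation is exact for designed counts", {
  perfect <- make_cycle_counts(
    sensor = matrix(c(4, 2, 30, 2), 3, 4, byrow = TRUE),
    manual = matrix(c(4, 2, 30, 2), 3, 4, byrow = TRUE),
    nontarget = rep(50, 3)
  )
  ev <- evaluate_genus_sex(perfect)
  expect_true(all(ev$per_cycle$ba == 1))
  expect_equal(ev$overall$mean_ba, 100)

  # over-count one class by exactly its manual count in one cycle:
  # its Se stays 1, its Sp drops, the other classes' Se is untouched
  over <- perfect
  over$sensor_AeF[1] <- 2 * over$manual_AeF[1]
  ev2 <- evaluate_genus_sex(over)
  aef <- ev2$per_cycle[ev2$per_cycle$class == "AEDES_F", ]
  expect_equal(aef$se, rep(1, 3))
  # fp = 4 against negatives 2 + 30 + 2 = 34 -> Sp = 30/34
  expect_equal(aef$sp[1], 30 / 34)
  others <- ev2$per_cycle[ev2$per_cycle$class != "AEDES_F", ]
  expect_true(all(others$se == 1))
})

test_that("designed class confusion is recovered from aggregate counts", {
  conf <- diag(4) * 0.85
  conf[1, 3] <- 0.15; conf[2, 4] <- 0.15; conf[3, 1] <- 0.15; conf[4, 2] <- 0.15
  sc <- default_field_scenario(intensity_scale = 0.5)
  sim <- simulate_field_trial(
    sc, detector_noise = list(miss = 0, false_alarm = 0,
                              class_confusion = conf),
    seed = 10
  )
  cyc <- merge(sim$truth, sim$sensor, by = "cycle_id", sort = FALSE)
  ev <- evaluate_genus_sex(cyc)
  # independent oracle: replay the same count-based rules on a direct
  # multinomial simulation of the designed confusion, cycle by cycle at
  # the scenario's own seasonal intensities
  active <- sc$cycles[!sc$cycles$excluded, ]
  base <- sc$class_intensities[match(active$cycle_id, sc$cycles$cycle_id),
                               target_labels(), drop = FALSE]
  mult <- sc$seasonal_trend[as.integer(format(active$start, "%m"))]
  oracle <- replicate(50, {
    per_cycle <- vapply(seq_len(nrow(active)), function(cy) {
      manual <- rpois(4, base[cy, ] * mult[cy])
      called <- rowSums(vapply(1:4, function(i) {
        stats::rmultinom(1, manual[i], conf[i, ])[, 1]
      }, numeric(4)))
      vapply(1:4, function(i) {
        cc <- count_confusion(called[i], manual[i], sum(manual[-i]))
        balanced_accuracy(cc)$ba
      }, 0)
    }, numeric(4))
    rowMeans(per_cycle, na.rm = TRUE)
  })
  want <- rowMeans(oracle, na.rm = TRUE)
  got <- vapply(ev$per_class, function(s) s$mean / 100, 0)
  expect_true(all(abs(got - want) < 0.05))
})

test_that("Pearson correlation matches direct computation", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1)
  res <- pearson_correlation(c(1, 2, 3), c(2, 4, 5))
  expect_equal(res$r, 0.98198, tolerance = 1e-4)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")
  expect_error(pearson_correlation(1:2, 1:2), "3 cycles")
})

test_that("least-squares regression recovers exact and noisy lines", {
  res <- linear_regression(2 * (1:10) + 1, 1:10)
  expect_equal(c(res$slope, res$intercept, res$r_squared), c(2, 1, 1))
  res <- linear_regression(rep(3, 10), 1:10)
  expect_equal(c(res$slope, res$r_squared), c(0, 0))
  expect_error(linear_regression(1:10, rep(1, 10)), "constant")

  withr::with_seed(11, {
    x <- rpois(44, 50)
    sigma <- 5
    y <- 0.9 * x + rnorm(44, 0, sigma)
    fit <- linear_regression(y, x)
    # sampling-distribution oracle: the true slope lies in the 95% CI
    se <- sigma / sqrt(sum((x - mean(x))^2))
    expect_lt(abs(fit$slope - 0.9), qnorm(0.975) * 3 * se)
  })
})

test_that("aggregate and per-cycle confusion relate as designed", {
  withr::with_seed(12, {
    for (i in 1:30) {
      m <- rpois(6, 20)
      delta <- rpois(6, 4) * sample(c(-1, 1), 6, replace = TRUE)
      s <- pmax(m + delta, 0)
      per_cycle_tp <- sum(count_confusion(s, m, rep(100, 6))$tp)
      aggregate_tp <- count_confusion(sum(s), sum(m), 600)$tp
      if (all(delta >= 0) || all(delta <= 0)) {
        expect_equal(per_cycle_tp, aggregate_tp)
      } else {
        expect_lte(per_cycle_tp, aggregate_tp)
      }
    }
  })
})

test_that("activity profiles average counts over month days", {
  ts <- as.POSIXct(sprintf("2021-07-%02d 06:%02d:00", 1:30, 0:29), tz = "UTC")
  events <- data.frame(timestamp = ts, genus = "Aedes")
  prof <- compute_activity_profile(
    events,
    period_start = as.POSIXct("2021-07-01", tz = "UTC"),
    period_end = as.POSIXct("2021-07-30 23:59:59", tz = "UTC")
  )
  expect_equal(prof$mean_count[prof$hour == 6], 1.0)
  expect_true(all(prof$mean_count[prof$hour != 6] == 0))

  empty <- compute_activity_profile(data.frame(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    genus = character()
  ))
  expect_equal(nrow(empty), 0)
})

test_that("the designed bimodal Aedes diel profile is recovered", {
  sc <- default_field_scenario(intensity_scale = 1)
  sim <- simulate_field_trial(sc, seed = 13)
  ev <- sim$events[sim$events$true_label %in% c("AEDES_F", "AEDES_M"), ]
  prof <- compute_activity_profile(
    data.frame(timestamp = ev$timestamp, genus = "Aedes"),
    period_start = min(sc$cycles$start), period_end = max(sc$cycles$end)
  )
  hourly <- vapply(0:23, function(h) sum(prof$mean_count[prof$hour == h]), 0)
  top2 <- order(hourly, decreasing = TRUE)[1:2]
  expect_setequal(top2 - 1, c(6, 19))
})

test_that("per-cycle count tables round-trip through CSV", {
  cyc <- make_cycle_counts(
    sensor = matrix(rpois(8, 10), 2, 4), manual = matrix(rpois(8, 10), 2, 4),
    nontarget = c(30, 40)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_cycle_counts(cyc, path)
  back <- read_cycle_counts(path)
  expect_equal(back$sensor_target_total, cyc$sensor_target_total)
  expect_equal(back$manual_nontarget, cyc$manual_nontarget)
  bad <- cyc
  bad$manual_nontarget <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_cycle_counts(path2), "missing columns")
})
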