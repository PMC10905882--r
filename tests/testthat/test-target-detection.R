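test_that("identical rows give a degenerate mean with a ridge covariance", {
  x <- matrix(rep(c(1, 2, 3), each = 10), nrow = 10)
  m <- fit_density(x, ridge = 1e-6)
  expect_equal(unname(m$mean), c(1, 2, 3))
  expect_equal(m$covariance, diag(1e-6, 3), ignore_attr = TRUE)
  expect_error(fit_density(x[1, , drop = FALSE]), "2 rows")
})

test_that("fitted moments converge on a large standard-normal sample", {
  withr::with_seed(1, {
    n <- 1e5
    x <- matrix(rnorm(n), ncol = 1)
    m <- fit_density(x)
    expect_lt(abs(m$mean), 3 / sqrt(n))              # 3 standard errors
    expect_lt(abs(m$covariance[1, 1] - 1), 3 * sqrt(2 / n))
  })
})

test_that("the fitted 2-D density integrates to one", {
  withr::with_seed(2, {
    x <- cbind(rnorm(500, 1, 2), rnorm(500, -3, 0.5))
    m <- fit_density(x)
    sds <- sqrt(diag(m$covariance))
    g1 <- seq(m$mean[1] - 8 * sds[1], m$mean[1] + 8 * sds[1], length.out = 400)
    g2 <- seq(m$mean[2] - 8 * sds[2], m$mean[2] + 8 * sds[2], length.out = 400)
    dens <- exp(log_density(m, as.matrix(expand.grid(g1, g2))))
    integral <- sum(dens) * diff(g1[1:2]) * diff(g2[1:2])
    expect_lt(abs(integral - 1), 1e-3)
  })
})

test_that("log-density matches the closed forms and a dense-solve oracle", {
  # 1-D unit-variance sample at the mean: density 1/sqrt(2*pi)
  m1 <- fit_density(matrix(c(-1, 1) / sqrt(2), ncol = 1), ridge = 0)
  expect_equal(exp(log_density(m1, 0)), 1 / sqrt(2 * pi), tolerance = 1e-12)

  withr::with_seed(3, {
    # d-dimensional identity covariance at the mean: (2*pi)^(-d/2)
    for (d in c(2, 5)) {
      x <- matrix(rnorm(5000 * d), ncol = d)
      m <- list(
        mean = rep(0, d), covariance = diag(d), ridge = 0, chol = diag(d),
        log_norm_const = -0.5 * d * log(2 * pi)
      )
      class(m) <- "gaussian_density"
      expect_equal(exp(log_density(m, rep(0, d))), (2 * pi)^(-d / 2),
                   tolerance = 1e-12)
    }
    # random SPD covariance vs. direct dense evaluation of the formula
    for (i in 1:20) {
      d <- sample(2:6, 1)
      A <- matrix(rnorm(d * d), d)
      S <- A %*% t(A) + diag(d)
      mu <- rnorm(d)
      ch <- chol(S)
      m <- structure(
        list(mean = mu, covariance = S, ridge = 0, chol = ch,
             log_norm_const = -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))))),
        class = "gaussian_density"
      )
      x <- rnorm(d)
      direct <- -0.5 * (t(x - mu) %*% solve(S, x - mu) +
                        d * log(2 * pi) + determinant(S)$modulus)
      expect_equal(log_density(m, x), as.numeric(direct), tolerance = 1e-10)
    }
  })
  expect_error(log_density(m1, c(1, 2)), "dimension mismatch")
})

test_that("density decreases with Mahalanobis distance from the mean", {
  withr::with_seed(4, {
    A <- matrix(rnorm(9), 3)
    S <- A %*% t(A) + diag(3)
    x <- matrix(rnorm(300), ncol = 3)
    m <- fit_density(x %*% chol(S))
    for (i in 1:10) {
      dir <- rnorm(3)
      dists <- seq(0.5, 5, by = 0.5)
      ld <- vapply(dists, function(s) {
        log_density(m, m$mean + s * dir)
      }, 0)
      expect_true(all(diff(ld) < 0))
    }
  })
})

test_that("the gate calls TARGET at and above the threshold", {
  m <- fit_density(matrix(rnorm(100), ncol = 1), ridge = 0)
  peak <- log_density(m, m$mean)
  expect_equal(classify_target(m, detection_threshold(peak - 1), m$mean),
               "TARGET")
  # a point exactly at the threshold log-density is a target
  x0 <- m$mean + sqrt(m$covariance[1, 1])
  expect_equal(classify_target(m, detection_threshold(log_density(m, x0)), x0),
               "TARGET")
  # a threshold above the maximum makes everything non-target
  xs <- matrix(seq(-3, 3, 0.5), ncol = 1)
  expect_true(all(classify_target(m, detection_threshold(peak + 1), xs) ==
                  "NON_TARGET"))
})

test_that("raising the threshold never increases TARGET calls", {
  withr::with_seed(5, {
    m <- fit_density(matrix(rnorm(200), ncol = 2))
    xs <- matrix(rnorm(200, sd = 2), ncol = 2)
    ld <- log_density(m, xs)
    thresholds <- sort(c(-Inf, sample(ld, 10), Inf))
    n_calls <- vapply(thresholds, function(th) {
      sum(classify_target(m, detection_threshold(min(th, 1e300)), xs) == "TARGET")
    }, 0)
    expect_true(all(diff(n_calls) <= 0))
  })
})

test_that("threshold calibration maximises balanced accuracy exactly", {
  # brute-force oracle: evaluate BA at every midpoint between sorted
  # log-densities (plus outer sentinels)
  oracle_best_ba <- function(ld, is_target) {
    cuts <- sort(unique(ld))
    cands <- c(min(cuts) - 1, (utils::head(cuts, -1) + cuts[-1]) / 2, cuts,
               max(cuts) + 1)
    max(vapply(cands, function(th) {
      (mean(ld[is_target] >= th) + mean(ld[!is_target] < th)) / 2
    }, 0))
  }
  withr::with_seed(6, {
    m <- fit_density(matrix(rnorm(100), ncol = 1))
    for (i in 1:200) {
      n <- sample(6:25, 1)
      x <- matrix(rnorm(n, sd = 2), ncol = 1)
      is_target <- runif(n) < 0.5
      if (!any(is_target) || all(is_target)) next
      thr <- calibrate_threshold(m, x, is_target)
      ld <- log_density(m, x)
      expect_equal(thr$calibration_ba / 100, oracle_best_ba(ld, is_target),
                   tolerance = 1e-12)
      # the returned threshold actually achieves the reported BA
      achieved <- (mean(ld[is_target] >= thr$value) +
                   mean(ld[!is_target] < thr$value)) / 2
      expect_equal(achieved, thr$calibration_ba / 100, tolerance = 1e-12)
    }
  })
})

test_that("calibration hits 100% on separated and ~50% on identical inputs", {
  withr::with_seed(7, {
    m <- fit_density(matrix(rnorm(500), ncol = 1))
    x <- matrix(c(rnorm(100), rnorm(100, 40)), ncol = 1)
    thr <- calibrate_threshold(m, x, rep(c(TRUE, FALSE), each = 100))
    expect_equal(thr$calibration_ba, 100)

    same <- matrix(rnorm(2000), ncol = 1)
    thr2 <- calibrate_threshold(m, same, rep(c(TRUE, FALSE), 1000))
    expect_lt(abs(thr2$calibration_ba - 50), 5)
    expect_error(calibrate_threshold(m, same, rep(TRUE, 2000)), "both")
  })
})

test_that("distant non-target clusters are gated near-perfectly per cycle", {
  withr::with_seed(8, {
    d <- 4
    lab <- matrix(rnorm(400 * d), ncol = d)
    m <- fit_density(lab)
    n_cycles <- 5
    counts <- lapply(seq_len(n_cycles), function(i) {
      targ <- matrix(rnorm(40 * d), ncol = d)
      nont <- matrix(rnorm(40 * d), ncol = d)
      nont[, 1] <- nont[, 1] + 8 # >= 6 Mahalanobis units from the mean
      ld_all <- c(log_density(m, targ), log_density(m, nont))
      thr <- calibrate_threshold(m, rbind(targ, nont),
                                 rep(c(TRUE, FALSE), each = 40))
      sensor_pos <- sum(ld_all >= thr$value)
      data.frame(sensor = sensor_pos, manual = 40, neg = 40)
    })
    df <- do.call(rbind, counts)
    ba <- balanced_accuracy(count_confusion(df$sensor, df$manual, df$neg))$ba
    expect_true(all(ba >= 0.99))
  })
})

test_that("the detector reduces features and round-trips through disk", {
  feats <- separable_features()
  targets <- feats[feats$label %in% target_labels(), ]
  det <- fit_detection_model(targets, n_components = 8)
  expect_equal(det$n_components, 8)
  ld <- detection_log_density(det, targets)
  expect_length(ld, nrow(targets))
  dir <- withr::local_tempdir()
  thr <- detection_threshold(-40, calibration_ba = 99)
  save_detector(det, dir, threshold = thr)
  restored <- load_detector(dir)
  expect_equal(detection_log_density(restored, targets), ld, tolerance = 1e-8)
  expect_equal(restored$threshold$value, -40)
})
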