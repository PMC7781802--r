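# The agreement panel: bias, error metrics, ICC(A,2), box-plot statistics.

test_that("bias_stats matches a direct two-pass computation", {
  z <- bias_stats(rep(0, 100))
  expect_equal(unlist(z[c("bias", "sd", "se", "ci_low", "ci_high")]),
               c(bias = 0, sd = 0, se = 0, ci_low = 0, ci_high = 0))

  set.seed(12)
  d <- rnorm(50, 3, 7)
  b <- bias_stats(d)
  m <- sum(d) / 50
  s <- sqrt(sum((d - m)^2) / 49)
  expect_equal(b$bias, m, tolerance = 1e-12)
  expect_equal(b$sd, s, tolerance = 1e-12)
  expect_equal(b$se, s / sqrt(50), tolerance = 1e-12)
  expect_equal(b$ci_low, m - 1.96 * s / sqrt(50), tolerance = 1e-12)
  expect_error(bias_stats(1), class = "poseagree_insufficient_data_error")
})

test_that("error metrics match element-wise loop oracles and sMAPE is bounded", {
  e <- error_metrics(c(10, 20, 30), c(10, 20, 30))
  expect_equal(unlist(e), c(mae = 0, mad = 0, rmse = 0, smape = 0))

  # a single pair (10, 0) sits at the 200% sMAPE ceiling
  expect_equal(error_metrics(10, 0)$smape, 200)
  expect_equal(error_metrics(0, 0)$smape, 0)

  set.seed(13)
  cand <- runif(50, 0, 180); ref <- runif(50, 0, 180)
  e <- error_metrics(cand, ref)
  d <- cand - ref
  mae <- 0; rmse <- 0; sm <- 0
  for (i in 1:50) {
    mae <- mae + abs(d[i]) / 50
    rmse <- rmse + d[i]^2 / 50
    sm <- sm + 100 * abs(cand[i] - ref[i]) /
      ((abs(cand[i]) + abs(ref[i])) / 2) / 50
  }
  expect_equal(e$mae, mae, tolerance = 1e-12)
  expect_equal(e$rmse, sqrt(rmse), tolerance = 1e-12)
  expect_equal(e$smape, sm, tolerance = 1e-12)
  expect_equal(e$mad, median(abs(d - median(d))), tolerance = 1e-12)
  expect_equal(error_metrics(cand, ref, mad_type = "mean")$mad,
               mean(abs(d - mean(d))), tolerance = 1e-12)
  expect_true(e$smape >= 0 && e$smape <= 200)
})

test_that("rmse_from_moments reproduces the RMSE of the underlying differences", {
  set.seed(14)
  d <- rnorm(200, 1, 4)
  b <- bias_stats(d)
  expect_equal(rmse_from_moments(b$bias, b$sd, b$n), sqrt(mean(d^2)),
               tolerance = 1e-12)
  # zero-bias large-n limit is the SD itself
  expect_equal(rmse_from_moments(0, 5, 1e9), 5, tolerance = 1e-8)
})

test_that("icc_a2 equals the aov oracle and the frozen cross-implementation values", {
  # perfect agreement on a non-constant series
  set.seed(15)
  r <- rnorm(30, 90, 10)
  perfect <- icc_a2(r, r)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$icc_ci_low, 1)

  # fixed 6x2 matrix; expected values frozen from an independent
  # implementation (pingouin ICC2k: 0.9896711650451595, CI [0.93, 1.00])
  m1 <- matrix(c(82.1, 75.3, 90.4, 68.2, 77.7, 85.0,
                 80.9, 74.1, 92.2, 70.5, 76.3, 83.8), ncol = 2)
  r1 <- icc_a2(m1[, 1], m1[, 2])
  expect_equal(r1$icc, 0.9896711650451595, tolerance = 1e-12)
  expect_equal(round(r1$icc_ci_low, 2), 0.93)
  expect_equal(round(r1$icc_ci_high, 2), 1.00)
  expect_equal(icc_oracle_aov(m1[, 1], m1[, 2]), r1$icc, tolerance = 1e-10)

  expect_error(icc_a2(rep(5, 10), rep(5, 10)),
               class = "poseagree_degenerate_error")
  expect_error(icc_a2(1:2, 2:1), class = "poseagree_insufficient_data_error")
})

test_that("a constant candidate offset shifts bias exactly and strictly lowers ICC(A,2)", {
  set.seed(16)
  ref <- rnorm(300, 100, 12)
  cand <- ref + rnorm(300, 0, 3)
  base_icc <- icc_a2(cand, ref)$icc
  b0 <- bias_stats(cand - ref)
  for (offset in c(1.5, -4)) {
    b1 <- bias_stats(cand + offset - ref)
    expect_equal(b1$bias - b0$bias, offset, tolerance = 1e-12)
    expect_equal(b1$sd, b0$sd, tolerance = 1e-12)
    expect_lt(icc_a2(cand + offset, ref)$icc, base_icc)
  }
})

test_that("ICC decreases monotonically with noise and small noise is excellent", {
  set.seed(17)
  ref <- rnorm(400, 90, 12)
  grid <- c(0.5, 2, 5, 10)
  mean_icc <- sapply(grid, function(s) {
    mean(replicate(50, icc_a2(ref + rnorm(400, 0, s), ref)$icc))
  })
  expect_true(all(diff(mean_icc) < 0))
  expect_gt(mean_icc[1], 0.95)
  expect_identical(classify_icc(mean_icc[1]), "excellent")
})

test_that("classify_icc follows the Fleiss bands including boundaries", {
  expect_identical(classify_icc(c(0.951, 0.39, 0.5, 0.40, 0.75, -0.2)),
                   c("excellent", "poor", "fair-to-good", "fair-to-good",
                     "excellent", "poor"))
})

test_that("boxplot_stats matches the sort-based quantile oracle and isolates outliers", {
  b <- boxplot_stats(as.numeric(1:100))
  expect_equal(b$median, 50.5)
  expect_equal(length(b$outliers[[1]]), 0)

  b2 <- boxplot_stats(c(1:100, 1000))
  expect_identical(b2$outliers[[1]], 1000)
  expect_equal(b2$whisker_high, 100)

  set.seed(18)
  x <- rnorm(173, 2, 9)
  b3 <- boxplot_stats(x)
  expect_equal(b3$q1, quantile_oracle(x, 0.25), tolerance = 1e-12)
  expect_equal(b3$median, quantile_oracle(x, 0.5), tolerance = 1e-12)
  expect_equal(b3$q3, quantile_oracle(x, 0.75), tolerance = 1e-12)
  expect_true(all(b3$outliers[[1]] < b3$whisker_low |
                    b3$outliers[[1]] > b3$whisker_high))
})

test_that("per_video_icc flags exactly the degraded video and tolerates failures", {
  set.seed(19)
  mk <- function(v, noise_sd) {
    ref <- rnorm(200, 90, 10)
    tibble::tibble(video_id = v, joint = "right_knee", time = (0:199) / 30,
                   candidate = ref + rnorm(200, 0, noise_sd), reference = ref)
  }
  paired <- dplyr::bind_rows(c(
    lapply(paste0("v", 1:6), mk, noise_sd = 1),
    list(mk("v7", 30)),
    lapply(paste0("v", 8:10), mk, noise_sd = 1)
  ))
  pv <- per_video_icc(paired)
  expect_equal(nrow(pv), 10)
  expect_identical(pv$video_id[pv$flag_low], "v7")

  # ten identical-pair videos -> ten exact 1.0 values
  ident <- dplyr::bind_rows(lapply(paste0("w", 1:10), function(v) {
    r <- rnorm(50, 80, 8)
    tibble::tibble(video_id = v, joint = "neck", time = (0:49) / 30,
                   candidate = r, reference = r)
  }))
  expect_equal(per_video_icc(ident)$icc, rep(1, 10))

  # a degenerate group reports its error without aborting the others
  degen <- mk("v1", 1)
  degen2 <- degen
  degen2$video_id <- "v2"
  degen2$candidate <- 5
  degen2$reference <- 5
  pv2 <- per_video_icc(dplyr::bind_rows(degen, degen2))
  expect_false(is.na(pv2$error[pv2$video_id == "v2"]))
  expect_true(is.na(pv2$error[pv2$video_id == "v1"]))
})

test_that("agreement_stats satisfies the panel identities on study output", {
  fit <- run_synthetic_study(
    motion_spec(n_videos = 2, duration_s = 20, seed = 23),
    noise_spec(), adf_series = NULL, per_video = FALSE
  )
  a <- tidy(fit)
  expect_true(all(is.na(a$error)))
  expect_equal(rmse_from_moments(a$bias, a$sd, a$n), a$rmse, tolerance = 1e-9)
  expect_true(all(a$mae <= a$rmse))
  expect_true(all(a$rmse >= abs(a$bias)))
  expect_true(all(a$ci_low <= a$bias & a$bias <= a$ci_high))
  expect_true(all(a$smape >= 0 & a$smape <= 200))
  expect_true(all(a$icc >= -1 & a$icc <= 1))
  expect_true(all(a$icc_ci_low <= a$icc & a$icc <= a$icc_ci_high))
})
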