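# Bartlett smoothing, moving-average imputation, frame alignment.

test_that("bartlett smoothing preserves constants, linear trends, and the missing mask", {
  const <- angles_from_values(rep(42, 30))
  out <- bartlett_smooth(const, 11)
  expect_equal(out$angle, rep(42, 30), tolerance = 1e-12)

  ramp <- angles_from_values(as.numeric(1:50))
  out <- bartlett_smooth(ramp, 11)
  expect_equal(out$angle[6:45], as.numeric(6:45), tolerance = 1e-9)

  with_na <- angles_from_values(c(rep(10, 10), NA, rep(10, 10)))
  out <- bartlett_smooth(with_na, 5)
  expect_identical(is.na(out$angle), with_na$missing)
  expect_equal(out$angle[!out$missing], rep(10, 20), tolerance = 1e-12)
})

test_that("smoothing equals convolution with the hand-computed triangular weights", {
  w <- bartlett_weights_oracle(11)
  expect_equal(sum(w), 1)
  expect_equal(w[6], 0.2) # normalized peak of the length-11 window

  imp <- angles_from_values(c(rep(0, 10), 1, rep(0, 10)))
  out <- bartlett_smooth(imp, 11)
  expect_equal(out$angle[11], w[6])
  # full interior response equals the impulse reading off the weights
  expect_equal(out$angle[6:16], w, tolerance = 1e-12)

  set.seed(21)
  v <- runif(40, 0, 180)
  out <- bartlett_smooth(angles_from_values(v), 11)$angle
  manual <- sapply(6:35, function(i) sum(w * v[(i - 5):(i + 5)]))
  expect_equal(out[6:35], manual, tolerance = 1e-12)
})

test_that("smoothing window validation", {
  a <- angles_from_values(runif(20, 0, 180))
  expect_error(bartlett_smooth(a, 4), class = "poseagree_parameter_error")
  expect_error(bartlett_smooth(a, 1), class = "poseagree_parameter_error")
  expect_error(bartlett_smooth(a, 21), class = "poseagree_parameter_error")
})

test_that("imputation fills gaps as documented and never alters observed values", {
  out <- impute_moving_average(angles_from_values(c(10, NA, 20)), 3)
  expect_equal(out$angle, c(10, 15, 20))
  expect_false(any(out$missing))

  complete <- angles_from_values(runif(30, 0, 180))
  expect_equal(impute_moving_average(complete, 5)$angle, complete$angle)

  # gap longer than the window: linear interpolation between neighbours
  v <- c(1, 2, 3, rep(NA, 7), 11, 12)
  out <- impute_moving_average(angles_from_values(v), 5)
  expect_equal(out$angle[6:8], c(6, 7, 8)) # interior of the long run
  # leading gap takes the nearest valid value
  v2 <- c(NA, NA, NA, NA, 5, 6, 7, 8, 9, 10)
  expect_equal(impute_moving_average(angles_from_values(v2), 5)$angle[1], 5)

  expect_error(impute_moving_average(angles_from_values(rep(NA_real_, 10)), 5),
               class = "poseagree_imputation_error")

  set.seed(31)
  v3 <- 90 + 30 * sin(2 * pi * 0.2 * (0:299) / 30)
  mask <- runif(300) < 0.05
  v3m <- replace(v3, mask, NA)
  out <- impute_moving_average(angles_from_values(v3m), 5)
  expect_equal(out$angle[!mask], v3[!mask]) # observed untouched
  max_window_var <- max(sapply(1:296, function(i) diff(range(v3[i:(i + 4)]))))
  expect_lt(max(abs(out$angle[mask] - v3[mask])), max_window_var)
})

test_that("pairing matches equal-rate frames and resamples across rates", {
  v <- 90 + 20 * sin(2 * pi * 0.3 * (0:99) / 30)
  p <- pair_angles(angles_from_values(v), angles_from_values(v))
  expect_equal(nrow(p), 100)
  expect_true(all(p$candidate - p$reference == 0))

  # 30 fps candidate vs 25 fps reference over 10 s -> 250 pairs at the
  # reference timestamps
  f <- 0.4; amp <- 25
  cand <- angles_from_values(90 + amp * sin(2 * pi * f * (0:299) / 30), fps = 30)
  ref <- angles_from_values(90 + amp * sin(2 * pi * f * (0:249) / 25), fps = 25)
  p <- pair_angles(cand, ref)
  expect_equal(nrow(p), 250)
  expect_equal(p$time, (0:249) / 25)
  expect_equal(p$reference, ref$angle)
  # linear-interpolation error bound for a sinusoid: |f''| dt^2 / 8
  bound <- amp * (2 * pi * f)^2 * (1 / 30)^2 / 8
  expect_lt(max(abs(p$candidate - p$reference)), bound + 1e-12)

  far <- angles_from_values(v, fps = 30)
  far$frame <- far$frame + 10000L
  expect_error(pair_angles(cand, far), class = "poseagree_pairing_error")
  expect_error(pair_angles(angles_from_values(c(1, NA, 3)), ref),
               class = "poseagree_pairing_error")
})

test_that("smoothing commutes with equal-rate pairing", {
  set.seed(41)
  vc <- 90 + 15 * sin(2 * pi * 0.2 * (0:199) / 30) + rnorm(200)
  vr <- 90 + 15 * sin(2 * pi * 0.2 * (0:199) / 30) + rnorm(200)
  sm_then_pair <- pair_angles(
    bartlett_smooth(angles_from_values(vc), 11),
    bartlett_smooth(angles_from_values(vr), 11)
  )
  paired <- pair_angles(angles_from_values(vc), angles_from_values(vr))
  pair_then_sm <- list(
    candidate = bartlett_smooth(angles_from_values(paired$candidate), 11)$angle,
    reference = bartlett_smooth(angles_from_values(paired$reference), 11)$angle
  )
  expect_equal(sm_then_pair$candidate, pair_then_sm$candidate, tolerance = 1e-9)
  expect_equal(sm_then_pair$reference, pair_then_sm$reference, tolerance = 1e-9)
})
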