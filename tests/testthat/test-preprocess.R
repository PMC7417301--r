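test_that("trimming slices inclusively and validates its range", {
  tr <- sine_trial(240)
  expect_identical(trim_trial(tr, NULL), tr)
  cut <- trim_trial(tr, c(10, 109))
  expect_equal(cut$frames, 100)
  expect_equal(cut$positions[1, ], tr$positions[10, ])
  expect_error(trim_trial(tr, c(100, 100)), "range")
  expect_error(trim_trial(tr, c(0, 50)), "range")
  expect_error(trim_trial(tr, c(10, 500)), "range")
})

test_that("the zero-phase low-pass filter has the expected response", {
  cfg <- preprocess_config()
  # DC passes exactly
  tr <- sine_trial(200)
  tr$lin_vel[] <- 7.25
  out <- lowpass_filter(tr, cfg)
  expect_lt(max(abs(out$lin_vel - 7.25)), 1e-9)
  # a 30 Hz tone at 120 Hz sampling is attenuated below 5% (measured away
  # from the reflection-padded edges, where any dual-pass filter leaves a
  # transient)
  t <- (0:299) / 120
  tone <- sine_trial(300)
  tone$lin_vel[] <- sin(2 * pi * 30 * t)
  f <- lowpass_filter(tone, cfg)
  expect_lt(max(abs(f$lin_vel[20:280, ])), 0.05)
  # white noise loses variance
  set.seed(1)
  wn <- sine_trial(400)
  wn$ang_vel[] <- rnorm(length(wn$ang_vel))
  fw <- lowpass_filter(wn, cfg)
  expect_lt(var(as.vector(fw$ang_vel)), var(as.vector(wn$ang_vel)))
  # frame count unchanged
  expect_equal(f$frames, 300)
})

test_that("filtering rejects trials shorter than the padding needs", {
  tr <- sine_trial(20)
  expect_error(lowpass_filter(tr, preprocess_config()), "too short")
})

test_that("height normalization is a pure scalar division", {
  tr <- sine_trial(100)
  expect_equal(normalize_by_height(tr, 1)$positions, tr$positions)
  out <- normalize_by_height(tr, 2)
  expect_equal(out$positions, tr$positions / 2)
  expect_equal(out$lin_vel, tr$lin_vel / 2)
  # scaling trial and height together leaves the output invariant
  tr2 <- omat:::.map_families(tr, function(m) m * 1.6)
  expect_equal(normalize_by_height(tr2, 1.6 * 1.8)$positions,
               normalize_by_height(tr, 1.8)$positions, tolerance = 1e-12)
  expect_error(normalize_by_height(tr, 0), "height")
})

test_that("trunk alignment zeroes the hip midpoint and is idempotent", {
  co <- small_cohort(1, 0)
  tr <- co$trials[[1]]
  al <- align_to_trunk(tr)
  hip <- (al$positions[1, omat:::.chan_cols("hip_L")] +
            al$positions[1, omat:::.chan_cols("hip_R")]) / 2
  expect_equal(unname(hip), c(0, 0, 0))
  again <- align_to_trunk(al)
  expect_lt(max(abs(again$positions - al$positions)), 1e-9)
})

test_that("trunk alignment is invariant to a global rotation of the lab", {
  co <- small_cohort(1, 0)
  tr <- co$trials[[1]]
  ref <- align_to_trunk(tr)$positions
  set.seed(42)
  for (i in 1:5) {
    rot <- rotate_trial(tr, random_rotation())
    expect_lt(max(abs(align_to_trunk(rot)$positions - ref)), 1e-6)
  }
})

test_that("degenerate trunk landmarks raise a geometry error", {
  tr <- sine_trial(50)
  tr$positions[, omat:::.chan_cols("sternum")] <-
    (tr$positions[, omat:::.chan_cols("T2")] +
       tr$positions[, omat:::.chan_cols("T8")]) / 2
  expect_error(align_to_trunk(tr), "geometry")
})

test_that("time normalization is shape preserving", {
  tr <- sine_trial(137)
  out <- time_normalize(tr, 50)
  expect_equal(out$frames, 50)
  expect_equal(out$positions[1, ], tr$positions[1, ])
  expect_equal(out$positions[50, ], tr$positions[137, ])
  # linear ramps are reproduced
  ramp <- sine_trial(100)
  ramp$lin_vel[] <- seq(0, 1, length.out = 100)
  rout <- time_normalize(ramp, 37)
  expect_lt(max(abs(rout$lin_vel - seq(0, 1, length.out = 37))), 1e-12)
  # monotone channels stay monotone
  mono <- sine_trial(60)
  mono$ang_vel[, 1] <- cumsum(abs(rnorm(60)))
  mout <- time_normalize(mono, 200)
  expect_true(all(diff(mout$ang_vel[, 1]) >= 0))
})

test_that("the uniform-grid PCHIP agrees with the reference implementation", {
  set.seed(8)
  for (i in 1:5) {
    n <- sample(10:80, 1)
    y <- cumsum(rnorm(n))
    xi <- seq(0, 1, length.out = n)
    xq <- seq(0, 1, length.out = 61)
    mine <- omat:::.pchip_uniform(matrix(y, ncol = 1), 61)[, 1]
    expect_lt(max(abs(mine - pracma::pchip(xi, y, xq))), 1e-12)
  }
})

test_that("the optical matrix assembles in canonical order", {
  co <- small_cohort(3, 0, duration_range = c(1, 1.5))
  cfg <- preprocess_config(target_frames = 500)
  heights <- setNames(co$athletes$height, co$athletes$athlete_id)
  pre <- lapply(co$trials, function(tr)
    preprocess_trial(tr, heights[[tr$athlete_id]], cfg, "OPT"))
  fm <- build_opt_matrix(pre, co$athletes)
  expect_equal(dim(fm$values), c(3, 39000))
  expect_equal(colnames(fm$values)[1], "wrist_L.position.x.t000")
  # flattening: channel-major, axis next, time fastest
  expect_equal(unname(fm$values[1, 1:500]),
               unname(pre[[1]]$positions[, "wrist_L.x"]))

  cfg2 <- preprocess_config(target_frames = 100)
  pre2 <- lapply(co$trials, function(tr)
    preprocess_trial(tr, heights[[tr$athlete_id]], cfg2, "OPT"))
  expect_equal(ncol(build_opt_matrix(pre2)$values), 7800)
  expect_error(build_opt_matrix(list()), "empty cohort")
})

test_that("preprocessing never introduces NaN or changes channel counts", {
  co <- small_cohort(2, 2)
  heights <- setNames(co$athletes$height, co$athletes$athlete_id)
  for (tr in co$trials) {
    out <- preprocess_trial(tr, heights[[tr$athlete_id]],
                            preprocess_config(target_frames = 40), "OPT")
    expect_false(anyNA(out$positions))
    expect_equal(ncol(out$positions), 78)
    expect_equal(ncol(out$lin_vel), 39)
  }
})
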