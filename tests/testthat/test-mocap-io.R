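test_that("TRC files round-trip exactly", {
  tr <- sine_trial(120)
  f <- withr::local_tempfile(fileext = ".trc")
  write_trial(tr, f, "trc")
  back <- read_trial(f, "trc", athlete_id = tr$athlete_id, task = tr$task)
  expect_equal(back$frames, tr$frames)
  expect_equal(back$sample_rate, tr$sample_rate)
  expect_lt(max(abs(back$positions - tr$positions)), 1e-9)
})

test_that("segment CSV files round-trip and validate channels", {
  tr <- sine_trial(100)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, f, "csv")
  back <- read_trial(f, "csv", athlete_id = tr$athlete_id, task = tr$task)
  expect_lt(max(abs(back$lin_vel - tr$lin_vel)), 1e-9)
  expect_lt(max(abs(back$ang_vel - tr$ang_vel)), 1e-9)

  # drop the left-thigh angular-velocity columns -> error naming them
  df <- utils::read.csv(f, check.names = FALSE)
  df <- df[, !grepl("^thigh_L\\.angular_velocity", names(df))]
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE, quote = FALSE)
  expect_error(read_trial(f2, "csv"), "thigh_L.angular_velocity")
})

test_that("units declared in the channel map are coerced to SI", {
  tr <- sine_trial(60)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, f, "csv")
  cm <- channel_map(units = c(velocity = "mm/s", angular = "deg/s"))
  back <- read_trial(f, "csv", channel_map = cm)
  expect_equal(back$lin_vel[5, 3], tr$lin_vel[5, 3] * 1e-3)
  expect_equal(back$ang_vel[5, 3], tr$ang_vel[5, 3] * pi / 180,
               tolerance = 1e-12)
})

test_that("C3D files carry frame count, rate and positions", {
  tr <- sine_trial(240)
  f <- withr::local_tempfile(fileext = ".c3d")
  write_trial(tr, f, "c3d")
  back <- read_trial(f, "c3d", athlete_id = tr$athlete_id, task = tr$task)
  expect_equal(back$frames, 240)
  expect_equal(back$sample_rate, 120)
  # point data is stored as 32-bit floats
  expect_lt(max(abs(back$positions - tr$positions)), 1e-6)
})

test_that("feature matrices round-trip with labels and schema", {
  set.seed(4)
  vals <- matrix(rnorm(5 * 13 * 2 * 10), 5,
                 dimnames = list(sprintf("ath%02d", 1:5), NULL))
  fm <- feature_matrix(vals, "sIMU", 10)
  expect_equal(colnames(fm$values)[1], "head.linear_acceleration_norm.t000")
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix(fm, f)
  back <- read_matrix(f)
  expect_identical(back$variant, "sIMU")
  expect_identical(rownames(back$values), rownames(fm$values))
  expect_lt(max(abs(back$values - fm$values)), 1e-12)
})

test_that("matrix widths are enforced per variant", {
  ok <- matrix(0, 2, 39000, dimnames = list(c("a", "b"), NULL))
  expect_s3_class(feature_matrix(ok, "OPT", 500), "feature_matrix")
  bad <- matrix(0, 2, 38999, dimnames = list(c("a", "b"), NULL))
  expect_error(feature_matrix(bad, "OPT", 500), "39000")
  expect_error(feature_matrix(ok, "sIMU", 500), "13000")
})

test_that("duplicate athlete rows are rejected", {
  vals <- matrix(0, 2, 1300, dimnames = list(c("a", "a"), NULL))
  expect_error(feature_matrix(vals, "sIMU", 50), "duplicate")
})

test_that("cohorts written to disk read back equal", {
  co <- small_cohort(2, 1, duration_range = c(1, 1.2))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_setequal(back$athletes$athlete_id, co$athletes$athlete_id)
  key <- names(co$trials)[1]
  expect_lt(max(abs(back$trials[[key]]$lin_vel - co$trials[[key]]$lin_vel)),
            1e-9)
  expect_lt(max(abs(back$trials[[key]]$positions -
                      co$trials[[key]]$positions)), 1e-9)
})

test_that("channel maps reject duplicates and unknown names", {
  expect_error(channel_map(positions = c(bogus = "X")), "bogus")
  expect_error(channel_map(positions = c(wrist_L = "M1", wrist_R = "M1")),
               "duplicate")
  expect_error(channel_map(units = c(position = "furlong")), "furlong")
})
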