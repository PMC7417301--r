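test_that("differentiation is exact on polynomials of degree <= 1", {
  t <- (0:99) / 120
  expect_lt(max(abs(differentiate(3.2 * t, 120)[2:99] - 3.2)), 1e-10)
  expect_equal(differentiate(rep(5, 50), 120), rep(0, 50))
  expect_error(differentiate(c(1, 2), 120), "3 frames")
})

test_that("central differences track a sinusoid within its error bound", {
  t <- (0:239) / 120
  v <- sin(2 * pi * t)
  d <- differentiate(v, 120)
  truth <- 2 * pi * cos(2 * pi * t)
  interior <- 2:239
  expect_lt(max(abs(d[interior] - truth[interior])) / (2 * pi), 0.005)
})

test_that("the Euclidean norm is correct and rotation invariant", {
  expect_equal(euclidean_norm(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(euclidean_norm(matrix(0, 4, 3)), rep(0, 4))
  set.seed(5)
  xyz <- matrix(rnorm(300), 100, 3)
  for (i in 1:5) {
    R <- random_rotation()
    expect_lt(max(abs(euclidean_norm(xyz %*% t(R)) - euclidean_norm(xyz))),
              1e-9)
  }
})

test_that("the sIMU matrix has the contracted width and ordering", {
  co <- small_cohort(2, 0, duration_range = c(1, 1.2))
  heights <- setNames(co$athletes$height, co$athletes$athlete_id)
  pre <- lapply(co$trials, function(tr)
    preprocess_trial(tr, heights[[tr$athlete_id]],
                     preprocess_config(target_frames = 500), "sIMU"))
  fm <- build_simu_matrix(pre, co$athletes,
                          preprocess_config(target_frames = 500))
  expect_equal(dim(fm$values), c(2, 13000))
  fm2 <- build_simu_matrix(pre, co$athletes,
                           preprocess_config(target_frames = 50))
  expect_equal(ncol(fm2$values), 1300)
  # zero angular velocity -> its 6,500 columns are zero
  z <- lapply(pre, function(tr) { tr$ang_vel[] <- 0; tr })
  fz <- build_simu_matrix(z, co$athletes,
                          preprocess_config(target_frames = 500))
  ang_cols <- grepl("angular_velocity_norm", colnames(fz$values))
  expect_equal(sum(ang_cols), 6500)
  expect_true(all(fz$values[, ang_cols] == 0))
  expect_true(all(fz$values[, !ang_cols] == fm$values[, !ang_cols]))
})

test_that("the sIMU matrix is invariant to per-athlete sensor rotations", {
  co <- small_cohort(3, 3, duration_range = c(1, 1.5))
  cfg <- preprocess_config(target_frames = 50)
  ref <- task_matrices(co, "drop_jump", cfg, "sIMU")
  set.seed(13)
  rot <- co
  rot$trials <- lapply(rot$trials, function(tr)
    rotate_trial(tr, random_rotation()))
  out <- task_matrices(rot, "drop_jump", cfg, "sIMU")
  rel <- norm(out$values - ref$values, "F") / norm(ref$values, "F")
  expect_lt(rel, 1e-6)
})

test_that("robust scaling matches hand-computed quartiles", {
  m <- matrix(c(0, 1, 2, 3, 4), 5, 1)
  st <- robust_scale_fit(m)
  expect_equal(st$median, 2)
  expect_equal(st$iqr, 2)
  expect_equal(robust_scale_apply(m, st)[, 1], c(-1, -0.5, 0, 0.5, 1))
})

test_that("column quartiles equal the type-7 reference", {
  set.seed(6)
  X <- matrix(rnorm(37 * 20), 37, 20)
  qs <- omat:::.col_quartiles(X)
  ref <- apply(X, 2, quantile, probs = c(0.25, 0.5, 0.75), type = 7)
  expect_equal(qs$q1, unname(ref[1, ]))
  expect_equal(qs$med, unname(ref[2, ]))
  expect_equal(qs$q3, unname(ref[3, ]))
})

test_that("degenerate (constant) features are centred only", {
  X <- cbind(rep(3, 6), 1:6)
  st <- robust_scale_fit(X)
  out <- robust_scale_apply(X, st)
  expect_true(all(out[, 1] == 0))
})

test_that("robust scaling is an invertible affine map for IQR > 0", {
  set.seed(7)
  X <- matrix(rnorm(60), 12, 5)
  st <- robust_scale_fit(X)
  sc <- robust_scale_apply(X, st)
  back <- sweep(sweep(sc, 2, st$iqr, "*"), 2, st$median, "+")
  expect_lt(max(abs(back - X)), 1e-12)
})

test_that("fit and apply are separable (train stats on held-out rows)", {
  set.seed(9)
  X <- matrix(rnorm(50), 10, 5)
  st <- robust_scale_fit(X[1:9, ])
  held <- robust_scale_apply(X[10, , drop = FALSE], st)
  expect_equal(held[1, 3], (X[10, 3] - st$median[3]) / st$iqr[3])
  expect_error(robust_scale_apply(X[, 1:3], st), "width mismatch")
})
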