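test_that("cohort configuration validates fields by name", {
  expect_error(cohort_config(-1, 5), "n_elite")
  expect_error(cohort_config(5, 2.5), "n_novice")
  expect_error(cohort_config(2, 2, tasks = "pirouette"), "tasks")
  expect_error(cohort_config(2, 2, sample_rate = 0), "sample_rate")
  expect_error(cohort_config(2, 2, duration_range = c(3, 1)),
               "duration_range")
  expect_error(cohort_config(2, 2, smoothness_gap = -1), "smoothness_gap")
  expect_error(cohort_config(2, 2, height_sd = 0), "height_sd")
})

test_that("empty cohort yields no athletes and no trials", {
  co <- generate_cohort(cohort_config(0, 0, tasks = "lunge_left"))
  expect_equal(nrow(co$athletes), 0)
  expect_length(co$trials, 0)
})

test_that("generation is deterministic under the same seed", {
  cfg <- cohort_config(3, 2, tasks = c("drop_jump", "t_balance_left"),
                       seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("fixed duration gives the expected frame count", {
  cfg <- cohort_config(1, 0, tasks = "drop_jump",
                       duration_range = c(2, 2), sample_rate = 120)
  tr <- generate_cohort(cfg)$trials[[1]]
  expect_equal(tr$frames, 240)
})

test_that("emitted CoG velocity is the analytic derivative of position", {
  co <- small_cohort(1, 0, duration_range = c(2, 2))
  tr <- co$trials[[1]]
  # trunk CoG position is emitted alongside its velocity; a central
  # difference of the position must agree with the analytic velocity to
  # the O(h^2) truncation error of the difference itself
  pos <- tr$positions[, omat:::.chan_cols("trunk_cog")[1]]
  vel <- tr$lin_vel[, which(colnames(tr$lin_vel) ==
                              "trunk.linear_velocity.x")]
  fd <- differentiate(pos, tr$sample_rate)
  interior <- 5:(tr$frames - 5)
  expect_lt(max(abs(fd[interior] - vel[interior])),
            0.005 * max(abs(vel)) + 1e-9)
})

test_that("athletes differing only in id get distinct trials", {
  cfg <- cohort_config(2, 0, tasks = "drop_jump", seed = 3)
  co <- generate_cohort(cfg)
  a <- co$athletes
  t1 <- generate_trial(a[1, ], "drop_jump", cfg)
  t2 <- generate_trial(a[2, ], "drop_jump", cfg)
  expect_false(isTRUE(all.equal(t1$positions, t2$positions)))
})

test_that("unknown task errors and lists valid tasks", {
  cfg <- cohort_config(1, 0, tasks = "drop_jump")
  co <- generate_cohort(cfg)
  expect_error(generate_trial(co$athletes[1, ], "lunge_left", cfg),
               "drop_jump")
})

test_that("elite athletes are taller on average when configured so", {
  co <- small_cohort(40, 40, seed = 11)
  h <- tapply(co$athletes$height, co$athletes$skill, mean)
  expect_gt(h[["elite"]], h[["novice"]])
})

test_that("a large smoothness gap separates high-pass acceleration power", {
  co <- fixture("gap2_n30", function() small_cohort(15, 15, seed = 2))
  bf <- signal::butter(2, 6 / 60, type = "high")
  heights <- setNames(co$athletes$height, co$athletes$athlete_id)
  pow <- vapply(co$trials, function(tr) {
    acc <- differentiate(tr$lin_vel, tr$sample_rate) /
      heights[[tr$athlete_id]]
    hp <- omat:::.filtfilt(acc, bf$b, bf$a, 9L)
    mean(hp^2)
  }, numeric(1))
  skill <- setNames(co$athletes$skill, co$athletes$athlete_id)
  g <- skill[vapply(co$trials, `[[`, character(1), "athlete_id")]
  d <- abs(mean(pow[g == "novice"]) - mean(pow[g == "elite"])) /
    sqrt((var(pow[g == "novice"]) + var(pow[g == "elite"])) / 2)
  expect_gt(d, 1)
})

test_that("a null generator shows no class difference in trial jerk", {
  # heights are held equal so body size cannot masquerade as a smoothness
  # difference in the raw (un-normalized) jerk
  flags <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(
      50, 50, tasks = "drop_jump", smoothness_gap = 0, amplitude_gap = 0,
      height_mean_elite = 1.77, height_mean_novice = 1.77,
      duration_range = c(1, 1.5), seed = s))
    jerk <- vapply(co$trials, function(tr) {
      j <- differentiate(differentiate(tr$lin_vel, tr$sample_rate),
                         tr$sample_rate)
      mean(sqrt(rowSums(j^2)))
    }, numeric(1))
    skill <- setNames(co$athletes$skill, co$athletes$athlete_id)
    g <- skill[vapply(co$trials, `[[`, character(1), "athlete_id")]
    t.test(jerk[g == "elite"], jerk[g == "novice"])$p.value > 0.05
  }, logical(1))
  expect_gte(sum(flags), 18)
})
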