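# Shared fixture builders. Heavy cohorts are built lazily and memoised for
# the duration of the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_cohort <- function(n_elite = 4, n_novice = 4, tasks = "drop_jump",
                         smoothness_gap = 2, amplitude_gap = 0.5,
                         seed = 1, duration_range = c(1, 2), ...) {
  generate_cohort(cohort_config(
    n_elite = n_elite, n_novice = n_novice, tasks = tasks,
    smoothness_gap = smoothness_gap, amplitude_gap = amplitude_gap,
    duration_range = duration_range, seed = seed, ...))
}

cohort_labels <- function(cohort, fm) {
  setNames(cohort$athletes$skill,
           cohort$athletes$athlete_id)[rownames(fm$values)]
}

# a deterministic sinusoidal trial with all channel families, built without
# the generator (for io / preprocessing tests)
sine_trial <- function(frames = 240, rate = 120, athlete_id = "athX",
                       task = "drop_jump") {
  t <- (seq_len(frames) - 1) / rate
  mk <- function(ncol, names, f0 = 0.5, a0 = 0.3) {
    m <- sapply(seq_len(ncol), function(j)
      a0 * sin(2 * pi * (f0 + 0.01 * j) * t + j) + 0.001 * j)
    colnames(m) <- names
    m
  }
  motion_trial(athlete_id, task, rate,
               positions = mk(78, omat:::.pos_colnames()),
               lin_vel = mk(39, omat:::.vel_colnames("linear_velocity")),
               ang_vel = mk(39, omat:::.vel_colnames("angular_velocity")))
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
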