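# Synthetic athlete cohorts.
#
# Movement is modelled as smooth low-frequency (<= 2 Hz) sinusoidal
# excursions about a standing posture, with every amplitude proportional to
# athlete height so that body size acts as a pure global scale (the inverse
# of the pipeline's height normalization). Skill enters through two latent
# class effects applied to novices:
#   * smoothness: extra 4-8 Hz "jitter" harmonics whose amplitude
#     multiplier is shifted by smoothness_gap effect-size units,
#   * amplitude: a multiplier on movement amplitude shifted by
#     amplitude_gap effect-size units.
# Both multipliers are truncated-Gaussian with the same within-class
# variance in the two classes, so the class signal is a pure location
# shift: linear discriminants are then the Bayes rule on the latent, which
# is the structure the pipeline's study conditions assume (classes
# separable by a linear plane). The jitter multiplier decomposes into an
# athlete-level trait and a per-channel component, so the class signal is
# partly shared and partly independent across channels; aggregating over
# channels therefore yields a larger effect size than any single channel
# carries.

# latent-effect scales (multiplier units); chosen once, see the methods
# vignette
.SIG_SMOOTH_ATHLETE <- 0.15
.SIG_SMOOTH_CHANNEL <- 0.34
.SIG_AMP            <- 0.30
.BASE_AMP_FRAC      <- 0.04   # per-harmonic movement amplitude, x height
.JITTER_AMP_FRAC    <- 0.005  # per-harmonic jitter amplitude, x height
.ANGVEL_AMP         <- 0.8    # per-harmonic angular velocity, rad/s x height
.ANGVEL_JITTER      <- 0.25

#' Configuration for a synthetic athlete cohort
#'
#' @param n_elite,n_novice Class sizes (non-negative integers).
#' @param tasks Task names, a subset of [omat_tasks()].
#' @param sample_rate Sampling rate in Hz (120 by default, the usual optical
#'   capture rate for screening batteries).
#' @param duration_range Length-2 numeric, min/max raw trial duration in
#'   seconds; each trial's duration is drawn uniformly from this range.
#' @param smoothness_gap Effect size (Cohen's d, log-scale) separating the
#'   classes in high-frequency (4-8 Hz) movement jitter amplitude; 0 means
#'   no smoothness difference.
#' @param amplitude_gap Effect size separating the classes in overall
#'   movement amplitude; 0 means none.
#' @param height_mean_elite,height_mean_novice,height_sd Heights in metres;
#'   elite athletes are systematically taller by default.
#' @param male_fraction Probability an athlete is male (metadata only; skill
#'   classification never uses sex).
#' @param seed Integer seed governing the whole cohort through per-athlete,
#'   per-task substreams.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_elite, n_novice,
                          tasks = omat_tasks(),
                          sample_rate = 120,
                          duration_range = c(1, 4),
                          smoothness_gap = 2,
                          amplitude_gap = 0.5,
                          height_mean_elite = 1.82,
                          height_mean_novice = 1.72,
                          height_sd = 0.085,
                          male_fraction = 0.85,
                          seed = 1L) {
  bad <- function(field, why) stop("invalid cohort configuration: `", field,
                                   "` ", why, call. = FALSE)
  is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= 0 && x == floor(x)
  if (!is_count(n_elite)) bad("n_elite", "must be a non-negative integer")
  if (!is_count(n_novice)) bad("n_novice", "must be a non-negative integer")
  if (!is.character(tasks) || anyDuplicated(tasks) ||
      !all(tasks %in% omat_tasks()))
    bad("tasks", paste0("must be distinct names from: ",
                        paste(omat_tasks(), collapse = ", ")))
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    bad("sample_rate", "must be > 0")
  if (!is.numeric(duration_range) || length(duration_range) != 2L ||
      any(duration_range <= 0) || duration_range[1] > duration_range[2])
    bad("duration_range", "must be 0 < min <= max seconds")
  if (!is.numeric(smoothness_gap) || smoothness_gap < 0)
    bad("smoothness_gap", "must be >= 0")
  if (!is.numeric(amplitude_gap) || amplitude_gap < 0)
    bad("amplitude_gap", "must be >= 0")
  for (f in c("height_mean_elite", "height_mean_novice", "height_sd")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || v <= 0) bad(f, "must be > 0")
  }
  if (!is.numeric(male_fraction) || male_fraction < 0 || male_fraction > 1)
    bad("male_fraction", "must be in [0, 1]")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    bad("seed", "must be an integer")
  structure(list(n_elite = as.integer(n_elite),
                 n_novice = as.integer(n_novice),
                 tasks = tasks, sample_rate = sample_rate,
                 duration_range = duration_range,
                 smoothness_gap = smoothness_gap,
                 amplitude_gap = amplitude_gap,
                 height_mean_elite = height_mean_elite,
                 height_mean_novice = height_mean_novice,
                 height_sd = height_sd, male_fraction = male_fraction,
                 seed = as.integer(seed %% 2147483647)),
            class = "cohort_config")
}

# counter-based substream: map (seed, a, b) to a seed in [1, 2^31 - 2].
# All products stay below 2^53 so the arithmetic is exact in doubles.
.substream <- function(seed, a, b) {
  m <- 2147483647
  h <- (as.numeric(seed) %% m) + 1
  h <- (h * 48271) %% m
  h <- (h + (as.numeric(a) %% m) * 7919 + (as.numeric(b) %% m) * 104729) %% m
  h <- (h * 48271) %% m
  as.integer(h) + 1L
}

# polynomial rolling hash over the id bytes, dispersed across the full
# 31-bit range so distinct athlete ids get distinct RNG substreams
.id_hash <- function(id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 131 + ch) %% 2147483647
  h
}

# Per-athlete latent traits, reproducible from (config$seed, athlete_id).
# Draw order is fixed: height z-score, sex, amplitude trait, smoothness trait.
.athlete_traits <- function(athlete_id, skill, config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.substream(config$seed, .id_hash(athlete_id), 0))
  z_height <- rnorm(1)
  u_sex <- runif(1)
  e_amp <- rnorm(1, 0, .SIG_AMP)
  e_smooth <- rnorm(1, 0, .SIG_SMOOTH_ATHLETE)
  novice <- identical(skill, "novice")
  hmean <- if (novice) config$height_mean_novice else config$height_mean_elite
  sig_tot <- sqrt(.SIG_SMOOTH_ATHLETE^2 + .SIG_SMOOTH_CHANNEL^2)
  list(height = max(1.3, hmean + config$height_sd * z_height),
       sex = if (u_sex < config$male_fraction) "M" else "F",
       amp_mult = max(0.2, 1 + e_amp +
                        if (novice) config$amplitude_gap * .SIG_AMP else 0),
       smooth_base = 1 + e_smooth +
         if (novice) config$smoothness_gap * sig_tot else 0)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# sum of sinusoids and its analytic time derivative
.sum_sines <- function(t, f, A, phi) {
  arg <- outer(2 * pi * f, t) + phi
  list(pos = as.vector(A %*% sin(arg)),
       vel = as.vector((A * 2 * pi * f) %*% cos(arg)))
}

# CoG posture offsets (fractions of height) for the 10 segments that are not
# already optical channels; trunk/head/pelvis CoGs are shared with them.
.segment_offsets <- function() {
  shared <- .posture_offsets()[c("head_cog", "trunk_cog", "pelvis_cog"), ]
  rownames(shared) <- c("head", "trunk", "pelvis")
  extra <- rbind(
    upper_arm_L = c(-0.13, 0.00, 0.76), upper_arm_R = c(0.13, 0.00, 0.76),
    forearm_L   = c(-0.19, 0.03, 0.59), forearm_R   = c(0.19, 0.03, 0.59),
    thigh_L     = c(-0.08, 0.00, 0.40), thigh_R     = c(0.08, 0.00, 0.40),
    shank_L     = c(-0.065, 0.00, 0.16), shank_R    = c(0.065, 0.00, 0.16),
    foot_L      = c(-0.06, 0.04, 0.03), foot_R      = c(0.06, 0.04, 0.03))
  colnames(extra) <- .axes
  rbind(shared, extra)[simu_segments(), , drop = FALSE]
}

#' Generate one synthetic trial
#'
#' Draws the trial's duration and all sinusoidal movement parameters from a
#' substream keyed by (seed, athlete, task), so trials are reproducible and
#' independent of generation order. Segment CoG linear velocities are the
#' analytic time derivatives of generated CoG position paths; for the trunk,
#' head and pelvis the same path underlies both the emitted position channel
#' and the emitted velocity.
#'
#' @param athlete A one-row data frame (or list) with `athlete_id`, `skill`
#'   (`"elite"` or `"novice"`) and `height` in metres.
#' @param task A task name present in `config$tasks`.
#' @param config A [cohort_config()].
#'
#' @return A [motion_trial()] carrying positions, segment linear velocities
#'   and segment angular velocities.
#' @export
generate_trial <- function(athlete, task, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!task %in% config$tasks)
    stop("unknown task '", task, "'; valid tasks: ",
         paste(config$tasks, collapse = ", "))
  athlete <- as.list(athlete)
  traits <- .athlete_traits(athlete$athlete_id, as.character(athlete$skill),
                            config)
  height <- if (!is.null(athlete$height)) athlete$height else traits$height

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  task_idx <- match(task, omat_tasks())
  set.seed(.substream(config$seed, .id_hash(athlete$athlete_id), task_idx))

  dur <- runif(1, config$duration_range[1], config$duration_range[2])
  frames <- max(2L, as.integer(round(dur * config$sample_rate)))
  t <- (seq_len(frames) - 1) / config$sample_rate
  amp_mult <- traits$amp_mult

  draw_path <- function(offset, base_scale, jitter_scale) {
    nh <- sample(3:5, 1)
    f <- runif(nh, 0.3, 2)
    A <- base_scale * amp_mult * abs(rnorm(nh, 1, 0.3))
    phi <- runif(nh, 0, 2 * pi)
    jf <- max(0.05, traits$smooth_base + rnorm(1, 0, .SIG_SMOOTH_CHANNEL))
    fj <- runif(2, 4, 8)
    Aj <- jitter_scale * jf * abs(rnorm(2, 1, 0.3))
    phij <- runif(2, 0, 2 * pi)
    s <- .sum_sines(t, c(f, fj), c(A, Aj), c(phi, phij))
    list(pos = offset + s$pos, vel = s$vel)
  }

  # 26 optical channels + 10 extra segment CoG paths, x/y/z each
  pos_off <- .posture_offsets() * height
  seg_off <- .segment_offsets() * height
  paths <- vector("list", 36L)
  names(paths) <- c(opt_channels(),
                    setdiff(simu_segments(), c("head", "trunk", "pelvis")))
  for (nm in names(paths)) {
    off <- if (nm %in% opt_channels()) pos_off[nm, ] else seg_off[nm, ]
    paths[[nm]] <- lapply(seq_len(3L), function(a)
      draw_path(off[a], .BASE_AMP_FRAC * height, .JITTER_AMP_FRAC * height))
  }

  positions <- matrix(0, frames, 78L, dimnames = list(NULL, .pos_colnames()))
  for (j in seq_along(opt_channels())) for (a in 1:3)
    positions[, 3L * (j - 1L) + a] <- paths[[opt_channels()[j]]][[a]]$pos

  seg_path_name <- function(seg) {
    if (seg %in% c("head", "trunk", "pelvis")) paste0(seg, "_cog") else seg
  }
  lin_vel <- matrix(0, frames, 39L,
                    dimnames = list(NULL, .vel_colnames("linear_velocity")))
  for (j in seq_along(simu_segments())) for (a in 1:3)
    lin_vel[, 3L * (j - 1L) + a] <-
      paths[[seg_path_name(simu_segments()[j])]][[a]]$vel

  ang_vel <- matrix(0, frames, 39L,
                    dimnames = list(NULL, .vel_colnames("angular_velocity")))
  for (j in seq_along(simu_segments())) for (a in 1:3) {
    p <- draw_path(0, .ANGVEL_AMP * height, .ANGVEL_JITTER * height)
    ang_vel[, 3L * (j - 1L) + a] <- p$pos  # generated directly on the
                                           # velocity scale
  }

  motion_trial(athlete$athlete_id, task, config$sample_rate,
               positions = positions, lin_vel = lin_vel, ang_vel = ang_vel)
}

#' Generate a synthetic athlete cohort
#'
#' @param config A [cohort_config()].
#'
#' @return A list with `athletes` (data frame: `athlete_id`, `skill`, `sex`,
#'   `height`) and `trials` (list of [motion_trial()], one per athlete per
#'   task, named `<athlete_id>.<task>`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_elite + config$n_novice
  skill <- rep(c("elite", "novice"), c(config$n_elite, config$n_novice))
  ids <- sprintf("ath%04d", seq_len(n))
  athletes <- data.frame(athlete_id = character(0), skill = character(0),
                         sex = character(0), height = numeric(0),
                         stringsAsFactors = FALSE)
  if (n > 0) {
    tr <- lapply(seq_len(n),
                 function(i) .athlete_traits(ids[i], skill[i], config))
    athletes <- data.frame(
      athlete_id = ids, skill = skill,
      sex = vapply(tr, `[[`, character(1), "sex"),
      height = vapply(tr, `[[`, numeric(1), "height"),
      stringsAsFactors = FALSE)
  }
  trials <- list()
  for (i in seq_len(n)) for (task in config$tasks) {
    trials[[paste(ids[i], task, sep = ".")]] <-
      generate_trial(athletes[i, ], task, config)
  }
  list(athletes = athletes, trials = trials)
}
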