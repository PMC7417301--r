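#' Construct a motion trial
#'
#' One athlete performing one task: a set of uniformly sampled kinematic
#' channel families. Any family may be absent (`NULL`), but all present
#' families must share the frame count. Units are metres, m/s and rad/s.
#'
#' @param athlete_id Athlete identifier (scalar character).
#' @param task Task name (scalar character).
#' @param sample_rate Sampling rate in Hz.
#' @param positions `frames x 78` matrix of the 26 optical channels
#'   (columns `<channel>.<axis>` in canonical order), or `NULL`.
#' @param lin_vel `frames x 39` matrix of segment CoG linear velocities
#'   (columns `<segment>.linear_velocity.<axis>`), or `NULL`.
#' @param ang_vel `frames x 39` matrix of segment angular velocities
#'   (columns `<segment>.angular_velocity.<axis>`), or `NULL`.
#'
#' @return An object of class `motion_trial`.
#' @export
motion_trial <- function(athlete_id, task, sample_rate,
                         positions = NULL, lin_vel = NULL, ang_vel = NULL) {
  if (!is.character(athlete_id) || length(athlete_id) != 1L)
    stop("athlete_id must be a scalar character")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0")
  fams <- Filter(Negate(is.null), list(positions = positions,
                                       lin_vel = lin_vel, ang_vel = ang_vel))
  if (length(fams) == 0L) stop("trial must carry at least one channel family")
  frames <- unique(vapply(fams, nrow, integer(1)))
  if (length(frames) != 1L)
    stop("all channel families must share the frame count")
  if (frames < 2L) stop("trial must have at least 2 frames")
  for (nm in names(fams)) {
    if (anyNA(fams[[nm]]))
      stop("NaN/NA samples in ", nm,
           "; gap-fill upstream before constructing trials")
  }
  chk <- function(m, want, what) {
    if (is.null(m)) return(invisible())
    if (!identical(colnames(m), want))
      stop(what, " columns must be the canonical set in canonical order")
  }
  chk(positions, .pos_colnames(), "positions")
  chk(lin_vel, .vel_colnames("linear_velocity"), "lin_vel")
  chk(ang_vel, .vel_colnames("angular_velocity"), "ang_vel")
  structure(list(athlete_id = athlete_id, task = task,
                 sample_rate = sample_rate, frames = as.integer(frames),
                 positions = positions, lin_vel = lin_vel, ang_vel = ang_vel),
            class = "motion_trial")
}

#' @exportS3Method base::print
print.motion_trial <- function(x, ...) {
  fams <- c(positions = !is.null(x$positions), lin_vel = !is.null(x$lin_vel),
            ang_vel = !is.null(x$ang_vel))
  cat(sprintf("<motion_trial> %s / %s: %d frames @ %g Hz [%s]\n",
              x$athlete_id, x$task, x$frames, x$sample_rate,
              paste(names(fams)[fams], collapse = ", ")))
  invisible(x)
}

# apply f (matrix -> matrix, same shape) to every present channel family
.map_families <- function(trial, f) {
  frames <- trial$frames
  for (nm in c("positions", "lin_vel", "ang_vel")) {
    if (!is.null(trial[[nm]])) {
      out <- f(trial[[nm]])
      dimnames(out) <- dimnames(trial[[nm]])
      trial[[nm]] <- out
      frames <- nrow(out)
    }
  }
  trial$frames <- as.integer(frames)
  trial
}

#' Rotate all 3-D channels of a trial
#'
#' Applies one rigid rotation to every (x, y, z) triplet of every channel
#' family. Used for orientation-invariance checks of the simulated-IMU
#' pipeline and internally by trunk alignment.
#'
#' @param trial A [motion_trial()].
#' @param rotation A 3x3 rotation matrix (applied as `v -> R v`).
#' @return The rotated trial.
#' @export
rotate_trial <- function(trial, rotation) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)))
  .map_families(trial, function(m) {
    out <- m
    for (j in seq_len(ncol(m) / 3L)) {
      idx <- (3L * (j - 1L) + 1L):(3L * j)
      out[, idx] <- m[, idx, drop = FALSE] %*% t(rotation)
    }
    out
  })
}
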