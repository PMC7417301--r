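# Shared signal conditioning and the optical-variant matrix construction.
# The stage order is fixed: trim -> filter -> height-normalize ->
# (trunk-align, OPT only) -> time-normalize -> assemble.

#' Preprocessing configuration
#'
#' @param cutoff_hz Low-pass cutoff in Hz (15 by default, the biomechanics
#'   convention for whole-body screening kinematics).
#' @param filter_order Butterworth order per pass (2 by default; the dual
#'   pass makes it effectively 4th order, zero phase).
#' @param target_frames Length of the normalized time base (500 by default).
#' @param trim_rule `"full_trial"` (no trimming) or `"config_events"`
#'   (per-task start/end frames supplied in `trim_events`).
#' @param trim_events Named list, `task = c(start_frame, end_frame)`
#'   (1-based, inclusive), used when `trim_rule = "config_events"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(cutoff_hz = 15, filter_order = 2,
                              target_frames = 500,
                              trim_rule = c("full_trial", "config_events"),
                              trim_events = list()) {
  trim_rule <- match.arg(trim_rule)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0)
    stop("cutoff_hz must be > 0")
  if (filter_order < 1 || filter_order != floor(filter_order))
    stop("filter_order must be a positive integer")
  if (target_frames < 2) stop("target_frames must be >= 2")
  structure(list(cutoff_hz = cutoff_hz,
                 filter_order = as.integer(filter_order),
                 target_frames = as.integer(target_frames),
                 trim_rule = trim_rule, trim_events = trim_events),
            class = "preprocess_config")
}

#' Trim a trial to start/end frames
#'
#' @param trial A [motion_trial()].
#' @param events `NULL` (keep the full trial) or `c(start, end)` frames,
#'   1-based inclusive.
#' @return The trimmed trial.
#' @export
trim_trial <- function(trial, events = NULL) {
  if (is.null(events)) return(trial)
  if (length(events) != 2L || any(events != floor(events)))
    stop("events must be two integer frames c(start, end)")
  start <- events[1]; end <- events[2]
  if (start >= end)
    stop("trim range error: start (", start, ") must be < end (", end, ")")
  if (start < 1L || end > trial$frames)
    stop("trim range error: events (", start, ", ", end,
         ") outside trial of ", trial$frames, " frames")
  .map_families(trial, function(m) m[start:end, , drop = FALSE])
}

# forward-backward IIR with odd-reflection padding, vectorized over
# channels (columns); the signal level is removed before each pass so that
# DC passes exactly (unit DC gain of the low-pass design).
.one_pass <- function(Z, b, a) {
  lvl <- Z[1L, ]
  Z <- sweep(Z, 2L, lvl)
  nb <- length(b)
  zma <- stats::filter(Z, b, method = "convolution", sides = 1)
  for (t in seq_len(nb - 1L))  # head rows the convolution leaves NA
    zma[t, ] <- crossprod(b[seq_len(t)], Z[t:1, , drop = FALSE])
  y <- stats::filter(zma, -a[-1], method = "recursive")
  sweep(matrix(as.numeric(y), nrow(Z)), 2L, lvl, "+")
}

.filtfilt <- function(X, b, a, padlen) {
  one_col <- is.null(dim(X))
  if (one_col) X <- matrix(X, ncol = 1L)
  n <- nrow(X)
  padlen <- min(padlen, n - 1L)
  front <- 2 * rep(X[1L, ], each = padlen) - X[(padlen + 1L):2L, ,
                                               drop = FALSE]
  back <- 2 * rep(X[n, ], each = padlen) - X[(n - 1L):(n - padlen), ,
                                             drop = FALSE]
  Xp <- rbind(front, X, back)
  y <- .one_pass(Xp, b, a)
  y <- .one_pass(y[nrow(y):1L, , drop = FALSE], b, a)[nrow(y):1L, ,
                                                      drop = FALSE]
  out <- y[(padlen + 1L):(padlen + n), , drop = FALSE]
  if (one_col) out[, 1L] else out
}

#' Zero-phase low-pass Butterworth filter
#'
#' Dual-pass (forward and backward) low-pass Butterworth applied to every
#' channel of every family; the frame count is unchanged and no phase lag is
#' introduced. Edges are handled by odd-reflection padding.
#'
#' @param trial A [motion_trial()].
#' @param config A [preprocess_config()] (or `NULL` for defaults).
#' @return The filtered trial.
#' @export
lowpass_filter <- function(trial, config = NULL) {
  if (is.null(config)) config <- preprocess_config()
  fs <- trial$sample_rate
  if (config$cutoff_hz >= fs / 2)
    stop("cutoff_hz (", config$cutoff_hz,
         ") must be below the Nyquist frequency (", fs / 2, ")")
  bf <- signal::butter(config$filter_order, config$cutoff_hz / (fs / 2),
                       type = "low")
  padlen <- 3L * (config$filter_order + 1L)
  if (trial$frames <= 3L * padlen)
    stop("trial too short to filter (", trial$frames, " frames, need > ",
         3L * padlen, "); use a longer trim window")
  .map_families(trial, function(m) .filtfilt(m, bf$b, bf$a, padlen))
}

#' Normalize a trial by athlete height
#'
#' Divides every sample of every channel family (positions, linear
#' velocities and angular velocities alike) by the athlete's height, so that
#' between-class differences cannot be driven by body size alone.
#'
#' @param trial A [motion_trial()].
#' @param height Athlete height in metres (> 0).
#' @return The height-normalized trial.
#' @export
normalize_by_height <- function(trial, height) {
  if (!is.numeric(height) || length(height) != 1L || is.na(height) ||
      height <= 0)
    stop("height must be a positive scalar (metres)")
  .map_families(trial, function(m) m / height)
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.chan_cols <- function(ch) {
  j <- match(ch, opt_channels())
  (3L * (j - 1L) + 1L):(3L * j)
}

#' Align a trial to the trunk coordinate system
#'
#' Computes an anatomical trunk frame from the first frame of data
#' (superior axis T8 to T2; anterior axis from the mid-spine toward the
#' sternum, orthogonalized; lateral axis their cross product) and applies
#' that single rigid rotation to all frames of all position channels, so the
#' trunk's local frame coincides with the global frame. All frames are then
#' translated so that the first frame's hip midpoint sits at the origin.
#' Using one frame-0 rotation (rather than a per-frame rotation) preserves
#' inter-frame dynamics.
#'
#' @param trial A [motion_trial()] carrying position channels.
#' @return The aligned trial.
#' @export
align_to_trunk <- function(trial) {
  if (is.null(trial$positions))
    stop("trunk alignment requires position channels")
  p0 <- trial$positions[1L, ]
  at <- function(ch) p0[.chan_cols(ch)]
  t2 <- at("T2"); t8 <- at("T8"); stern <- at("sternum")
  sup <- t2 - t8
  if (sqrt(sum(sup^2)) < 1e-12)
    stop("geometry error: T2 and T8 coincide; cannot build trunk axes")
  sup <- sup / sqrt(sum(sup^2))
  mid <- (t2 + t8) / 2
  ant <- stern - mid
  ant <- ant - sum(ant * sup) * sup
  if (sqrt(sum(ant^2)) < 1e-10)
    stop("geometry error: trunk landmarks are collinear; ",
         "cannot build trunk axes")
  ant <- ant / sqrt(sum(ant^2))
  lat <- .cross3(ant, sup)
  R <- cbind(lat, ant, sup)  # columns: trunk axes in global coordinates

  out <- trial
  pos <- trial$positions
  for (j in seq_len(ncol(pos) / 3L)) {
    idx <- (3L * (j - 1L) + 1L):(3L * j)
    pos[, idx] <- pos[, idx, drop = FALSE] %*% R  # v_local = R^T v
  }
  hip_mid <- (pos[1L, .chan_cols("hip_L")] + pos[1L, .chan_cols("hip_R")]) / 2
  for (j in seq_len(ncol(pos) / 3L)) {
    idx <- (3L * (j - 1L) + 1L):(3L * j)
    pos[, idx] <- sweep(pos[, idx, drop = FALSE], 2L, hip_mid)
  }
  out$positions <- pos
  out
}

# Shape-preserving piecewise cubic Hermite interpolation on a uniform grid,
# vectorized over channels. Slopes follow the Fritsch-Carlson construction
# (weighted harmonic mean at interior knots, clipped three-point formula at
# the ends), the same scheme as MATLAB/SciPy pchip, so monotone segments
# stay monotone and there is no overshoot beyond the data range.
.pchip_uniform <- function(Y, target_frames) {
  n <- nrow(Y); p <- ncol(Y)
  if (n == 2L) {
    w <- seq(0, 1, length.out = target_frames)
    return(outer(1 - w, Y[1L, ]) + outer(w, Y[2L, ]))
  }
  h <- 1 / (n - 1)
  delta <- diff(Y) / h                              # (n-1) x p
  d <- matrix(0, n, p)
  # interior: harmonic mean when the neighbouring secants share a sign
  d0 <- delta[-(n - 1L), , drop = FALSE]            # delta_{k-1}
  d1 <- delta[-1L, , drop = FALSE]                  # delta_k
  same <- (d0 * d1) > 0
  hm <- 2 * d0 * d1 / (d0 + d1)                     # equal spacing: w1 = w2
  hm[!same] <- 0
  d[2:(n - 1L), ] <- hm
  # ends: non-centred three-point formula with monotonicity clipping
  endslope <- function(del1, del2) {
    dd <- (3 * del1 - del2) / 2
    dd[dd * del1 <= 0] <- 0
    clip <- (del1 * del2 < 0) & (abs(dd) > 3 * abs(del1))
    dd[clip] <- 3 * del1[clip]
    dd
  }
  d[1L, ] <- endslope(delta[1L, ], delta[2L, ])
  d[n, ] <- endslope(delta[n - 1L, ], delta[n - 2L, ])

  xq <- seq(0, 1, length.out = target_frames)
  k <- pmin(pmax(floor(xq * (n - 1)) + 1L, 1L), n - 1L)
  s <- xq - (k - 1) * h
  dk <- d[k, , drop = FALSE]; dk1 <- d[k + 1L, , drop = FALSE]
  yk <- Y[k, , drop = FALSE]
  delk <- delta[k, , drop = FALSE]
  c2 <- (3 * delk - 2 * dk - dk1) / h
  c3 <- (dk + dk1 - 2 * delk) / h^2
  yk + s * (dk + s * (c2 + s * c3))
}

#' Time-normalize a trial to a fixed number of frames
#'
#' Resamples every channel onto `target_frames` points spanning normalized
#' time 0 to 1 (both ends included) with shape-preserving piecewise cubic
#' Hermite (PCHIP) interpolation: endpoints are reproduced exactly,
#' monotone segments stay monotone, and there is no overshoot beyond the
#' data range.
#'
#' @param trial A [motion_trial()].
#' @param target_frames Number of output frames (>= 2).
#' @return The resampled trial (the `sample_rate` field is kept as the raw
#'   acquisition rate; the time base is now normalized).
#' @export
time_normalize <- function(trial, target_frames = 500L) {
  if (target_frames < 2L) stop("target_frames must be >= 2")
  if (trial$frames < 2L) stop("trial must have at least 2 frames")
  .map_families(trial, function(m) .pchip_uniform(m, target_frames))
}

#' Build the optical-variant feature matrix
#'
#' Assembles one row per athlete from fully preprocessed trials (trimmed,
#' filtered, height-normalized, trunk-aligned, time-normalized), flattened
#' in canonical order: channel (enumeration order), axis (x, y, z), time
#' index fastest-varying. At 500 frames the width is
#' 26 x 3 x 500 = 39,000.
#'
#' @param trials List of preprocessed [motion_trial()]s, all of one task.
#' @param athletes Optional athlete data frame; when given, rows are
#'   restricted to and ordered by `athletes$athlete_id` (athletes lacking
#'   the task are omitted).
#' @return A [feature_matrix()] with `variant = "OPT"`.
#' @export
build_opt_matrix <- function(trials, athletes = NULL) {
  if (length(trials) == 0L) stop("empty cohort: no trials to assemble")
  tasks <- unique(vapply(trials, `[[`, character(1), "task"))
  if (length(tasks) != 1L)
    stop("all trials must be of the same task; got: ",
         paste(tasks, collapse = ", "))
  frames <- unique(vapply(trials, `[[`, integer(1), "frames"))
  if (length(frames) != 1L)
    stop("trials differ in frame count; time-normalize before assembling")
  ids <- vapply(trials, `[[`, character(1), "athlete_id")
  if (anyDuplicated(ids))
    stop("duplicate athlete_id rows: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(athletes)) {
    keep <- ids %in% athletes$athlete_id
    trials <- trials[keep][order(match(ids[keep], athletes$athlete_id))]
    ids <- ids[keep][order(match(ids[keep], athletes$athlete_id))]
    if (length(trials) == 0L) stop("empty cohort: no athletes carry task")
  }
  rows <- t(vapply(trials, function(tr) {
    if (is.null(tr$positions)) stop("trial lacks position channels")
    as.vector(tr$positions)
  }, numeric(frames * 78L)))
  rownames(rows) <- ids
  feature_matrix(rows, "OPT", frames)
}

#' Preprocess one trial for a pipeline variant
#'
#' Applies the fixed stage order. For `"OPT"`:
#' trim, filter, height-normalize, trunk-align, time-normalize. For
#' `"sIMU"`: trim, filter, height-normalize (differentiation, time
#' normalization and norms happen in [build_simu_matrix()]).
#'
#' @param trial A raw [motion_trial()].
#' @param height Athlete height in metres.
#' @param config A [preprocess_config()].
#' @param variant `"OPT"` or `"sIMU"`.
#' @return The preprocessed trial.
#' @export
preprocess_trial <- function(trial, height, config = preprocess_config(),
                             variant = c("OPT", "sIMU")) {
  variant <- match.arg(variant)
  events <- if (config$trim_rule == "config_events")
    config$trim_events[[trial$task]] else NULL
  tr <- trim_trial(trial, events)
  tr <- lowpass_filter(tr, config)
  tr <- normalize_by_height(tr, height)
  if (variant == "OPT") {
    tr <- align_to_trunk(tr)
    tr <- time_normalize(tr, config$target_frames)
  }
  tr
}
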