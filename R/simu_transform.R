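# Simulated-IMU features: segment linear accelerations obtained by
# differentiating CoG linear velocities, segment angular velocities,
# per-frame Euclidean norms, and robust (median/IQR) feature scaling.

#' Differentiate a uniformly sampled time series
#'
#' Central differences in the interior, one-sided differences at the two
#' ends; output length equals input length. Used to turn segment CoG linear
#' velocities into the linear accelerations an accelerometer would report.
#'
#' @param x Numeric vector or matrix (columns are channels).
#' @param sample_rate Sampling rate in Hz.
#' @return Derivative of `x`, same shape.
#' @export
differentiate <- function(x, sample_rate) {
  v <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  n <- nrow(v)
  if (n < 3L) stop("differentiate requires at least 3 frames")
  h <- 1 / sample_rate
  d <- v
  d[2:(n - 1L), ] <- (v[3:n, , drop = FALSE] -
                        v[1:(n - 2L), , drop = FALSE]) / (2 * h)
  d[1L, ] <- (v[2L, ] - v[1L, ]) / h
  d[n, ] <- (v[n, ] - v[n - 1L, ]) / h
  if (is.matrix(x)) d else d[, 1L]
}

#' Per-frame Euclidean norm of a 3-axis signal
#'
#' `sqrt(x^2 + y^2 + z^2)` per frame. The norm is invariant under any
#' rotation of the sensor axes, which is exactly why it is used: it removes
#' the dependence on sensor orientation (and brand axis conventions).
#'
#' @param xyz `frames x 3` matrix (or three aligned vectors via `cbind`).
#' @return Non-negative numeric vector of length `frames`.
#' @export
euclidean_norm <- function(xyz) {
  if (!is.matrix(xyz) || ncol(xyz) != 3L)
    stop("xyz must be a frames x 3 matrix")
  sqrt(rowSums(xyz^2))
}

#' Build the simulated-IMU feature matrix
#'
#' For each preprocessed trial (trimmed, filtered, height-normalized):
#' differentiate the 13 segment CoG linear velocities into accelerations,
#' take per-frame Euclidean norms, time-normalize the norm traces to
#' `target_frames` with the same PCHIP resampling as the optical variant,
#' and flatten segment-major, feature next (acceleration norm, then
#' angular-velocity norm), time fastest. At 500 frames the width is
#' 13 x 2 x 500 = 13,000. Norms are taken before resampling: the Euclidean
#' norm is exactly rotation invariant, and resampling the scalar norm trace
#' keeps the whole feature matrix independent of sensor axis orientation
#' (shape-preserving resampling of individual axes would not commute with
#' rotation).
#'
#' @param trials List of preprocessed [motion_trial()]s of one task,
#'   carrying `lin_vel` and `ang_vel`.
#' @param athletes Optional athlete data frame (restricts and orders rows).
#' @param config A [preprocess_config()] (supplies `target_frames`).
#' @return A [feature_matrix()] with `variant = "sIMU"`.
#' @export
build_simu_matrix <- function(trials, athletes = NULL,
                              config = preprocess_config()) {
  if (length(trials) == 0L) stop("empty cohort: no trials to assemble")
  tasks <- unique(vapply(trials, `[[`, character(1), "task"))
  if (length(tasks) != 1L)
    stop("all trials must be of the same task; got: ",
         paste(tasks, collapse = ", "))
  ids <- vapply(trials, `[[`, character(1), "athlete_id")
  if (anyDuplicated(ids))
    stop("duplicate athlete_id rows: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(athletes)) {
    keep <- ids %in% athletes$athlete_id
    ord <- order(match(ids[keep], athletes$athlete_id))
    trials <- trials[keep][ord]
    ids <- ids[keep][ord]
    if (length(trials) == 0L) stop("empty cohort: no athletes carry task")
  }
  tf <- config$target_frames
  segs <- simu_segments()
  rows <- t(vapply(trials, function(tr) {
    if (is.null(tr$lin_vel) || is.null(tr$ang_vel))
      stop("trial for ", tr$athlete_id,
           " lacks segment channels (lin_vel/ang_vel)")
    acc <- differentiate(tr$lin_vel, tr$sample_rate)
    norms <- matrix(0, nrow(acc), 2L * length(segs))
    for (j in seq_along(segs)) {
      cols <- (3L * (j - 1L) + 1L):(3L * j)
      norms[, 2L * j - 1L] <- euclidean_norm(acc[, cols, drop = FALSE])
      norms[, 2L * j] <- euclidean_norm(tr$ang_vel[, cols, drop = FALSE])
    }
    as.vector(.pchip_uniform(norms, tf))
  }, numeric(13L * 2L * tf)))
  rownames(rows) <- ids
  feature_matrix(rows, "sIMU", tf)
}

## ---- robust scaling --------------------------------------------------------

# type-7 (linear interpolation between order statistics) column quartiles,
# computed with one global order() call over (column, value) so the cost is
# a single O(N log N) sort rather than p separate R-level calls; matches
# the common robust-scaler default so ports can agree bit-for-bit
.col_quartiles <- function(X) {
  n <- nrow(X)
  S <- matrix(X[order(col(X), X)], n, ncol(X))
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    S[lo, ] + (h - lo) * (S[hi, ] - S[lo, ])
  }
  list(q1 = q(0.25), med = q(0.5), q3 = q(0.75))
}

#' Fit / apply robust feature scaling
#'
#' `robust_scale_fit` estimates the per-feature median and interquartile
#' range (Q3 - Q1, linear-interpolation quartiles); `robust_scale_apply`
#' computes `(x - median) / IQR` per feature. Features with zero IQR are
#' centred only (divisor 1). Fit and apply are separate so the transform
#' can be estimated on training folds and applied to held-out rows, and the
#' affine map is invertible for non-degenerate features.
#'
#' @param matrix A [feature_matrix()] or plain numeric matrix (>= 2 rows
#'   for fitting).
#' @return `robust_scale_fit`: an object of class `robust_scale_stats`
#'   (`median`, `iqr`, `n_rows`); `robust_scale_apply`: the scaled matrix,
#'   same class as the input.
#' @export
robust_scale_fit <- function(matrix) {
  X <- if (inherits(matrix, "feature_matrix")) matrix$values else matrix
  if (nrow(X) < 2L) stop("robust scaling requires at least 2 rows")
  qs <- .col_quartiles(X)
  structure(list(median = qs$med, iqr = qs$q3 - qs$q1,
                 n_rows = nrow(X)), class = "robust_scale_stats")
}

#' @rdname robust_scale_fit
#' @param stats A `robust_scale_stats` from [robust_scale_fit()].
#' @export
robust_scale_apply <- function(matrix, stats) {
  is_fm <- inherits(matrix, "feature_matrix")
  X <- if (is_fm) matrix$values else matrix
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(stats$median))
    stop("width mismatch: stats fitted on ", length(stats$median),
         " features, matrix has ", ncol(X))
  divisor <- ifelse(stats$iqr > 0, stats$iqr, 1)
  out <- sweep(sweep(X, 2L, stats$median), 2L, divisor, "/")
  if (is_fm) {
    matrix$values <- out
    matrix
  } else out
}
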