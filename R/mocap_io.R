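# Readers and writers for motion-capture inputs and pipeline artifacts.
# TRC and C3D carry the 26 optical position channels; the wide CSV carries
# the 13-segment linear/angular velocity kinematics. All writers produce
# files their paired readers parse back to equal values.

.UNIT_SCALE <- c(m = 1, mm = 1e-3, cm = 1e-2,
                 "m/s" = 1, "mm/s" = 1e-3,
                 "rad/s" = 1, "deg/s" = pi / 180)

#' Map source channel labels to canonical channel names
#'
#' Canonical vocabularies are closed: the 26 optical positions
#' ([opt_channels()]) and the 13 segments x \{linear_velocity,
#' angular_velocity\} ([simu_segments()]). A map entry renames a source
#' label to a canonical one; unmapped canonical names are looked up under
#' their own name. The units declaration is explicit — file conventions vary
#' too much for silent guessing. Coordinates are assumed right-handed with
#' z vertical-up.
#'
#' @param positions Named character vector, `canonical = source_label`, for
#'   position channels (optional).
#' @param segments Named character vector, `canonical = source_prefix`, for
#'   segment kinematics; canonical names are segment names (optional).
#' @param units Named character vector with any of `position`
#'   (m/mm/cm), `velocity` (m/s, mm/s), `angular` (rad/s, deg/s).
#'
#' @return An object of class `channel_map`.
#' @export
channel_map <- function(positions = NULL, segments = NULL,
                        units = c(position = "m", velocity = "m/s",
                                  angular = "rad/s")) {
  if (!is.null(positions)) {
    if (!all(names(positions) %in% opt_channels()))
      stop("unknown canonical position channel(s): ",
           paste(setdiff(names(positions), opt_channels()), collapse = ", "))
    if (anyDuplicated(positions))
      stop("duplicate source assignment in position map")
  }
  if (!is.null(segments)) {
    if (!all(names(segments) %in% simu_segments()))
      stop("unknown canonical segment(s): ",
           paste(setdiff(names(segments), simu_segments()), collapse = ", "))
    if (anyDuplicated(segments))
      stop("duplicate source assignment in segment map")
  }
  u <- c(position = "m", velocity = "m/s", angular = "rad/s")
  u[names(units)] <- units
  bad <- !u %in% names(.UNIT_SCALE)
  if (any(bad)) stop("unsupported units: ", paste(u[bad], collapse = ", "))
  structure(list(positions = positions, segments = segments, units = u),
            class = "channel_map")
}

.map_source <- function(map, canonical, what = c("positions", "segments")) {
  what <- match.arg(what)
  src <- canonical
  if (!is.null(map[[what]])) {
    hit <- match(canonical, names(map[[what]]))
    src[!is.na(hit)] <- map[[what]][hit[!is.na(hit)]]
  }
  src
}

.check_uniform_time <- function(time, path) {
  if (length(time) < 2L) return(1 / max(diff(time), 1))
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-6)
    stop("non-uniform timestamps in ", path,
         " (jitter exceeds 1e-6 s); resample upstream")
  1 / dt[1]
}

#' Read a motion trial from file
#'
#' @param path File path.
#' @param format One of `"trc"`, `"csv"`, `"c3d"`. TRC and C3D carry
#'   optical positions; the wide CSV carries segment kinematics.
#' @param channel_map A [channel_map()] (identity map with SI units by
#'   default).
#' @param athlete_id,task Metadata attached to the returned trial (TRC/C3D
#'   files do not carry them; defaults are derived from the file name).
#'
#' @return A [motion_trial()].
#' @export
read_trial <- function(path, format = c("trc", "csv", "c3d"),
                       channel_map = NULL, athlete_id = NULL, task = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(channel_map)) channel_map <- channel_map()
  stem <- sub("\\.[^.]+$", "", basename(path))
  if (is.null(athlete_id)) athlete_id <- sub("\\..*$", "", stem)
  if (is.null(task)) {
    task <- sub("^[^.]*\\.", "", stem)
    if (identical(task, stem)) task <- "unknown"
  }
  switch(format,
         trc = .read_trc(path, channel_map, athlete_id, task),
         csv = .read_segment_csv(path, channel_map, athlete_id, task),
         c3d = .read_c3d_trial(path, channel_map, athlete_id, task))
}

#' Write a motion trial to file
#'
#' @param trial A [motion_trial()].
#' @param path Output path.
#' @param format `"trc"` or `"c3d"` (positions) or `"csv"` (segment
#'   kinematics). Output is always in SI units.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, format = c("trc", "csv", "c3d")) {
  format <- match.arg(format)
  switch(format,
         trc = .write_trc(trial, path),
         csv = .write_segment_csv(trial, path),
         c3d = .write_c3d_trial(trial, path))
  invisible(path)
}

## ---- TRC ------------------------------------------------------------------

.write_trc <- function(trial, path) {
  if (is.null(trial$positions)) stop("trial carries no position channels")
  n_mark <- length(opt_channels())
  fr <- trial$frames
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(trial$sample_rate, trial$sample_rate, fr, n_mark, "m",
          trial$sample_rate, 1, fr, sep = "\t"),
    paste(c("Frame#", "Time",
            as.vector(rbind(opt_channels(), "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), n_mark),
                           rep(seq_len(n_mark), each = 3))), collapse = "\t"),
    ""), con)
  tm <- (seq_len(fr) - 1) / trial$sample_rate
  body <- cbind(seq_len(fr), tm, trial$positions)
  utils::write.table(format(body, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

.read_trc <- function(path, map, athlete_id, task) {
  lines <- readLines(path)
  if (length(lines) < 6L) stop("not a TRC file: ", path)
  meta_names <- strsplit(lines[2], "\t")[[1]]
  meta_vals <- strsplit(lines[3], "\t")[[1]]
  meta <- setNames(meta_vals, meta_names)
  rate <- as.numeric(meta[["DataRate"]])
  units <- if ("Units" %in% names(meta)) meta[["Units"]] else
    map$units[["position"]]
  labels <- strsplit(lines[4], "\t")[[1]]
  labels <- labels[-(1:2)]
  labels <- labels[labels != ""]
  body_lines <- lines[-(1:5)]
  body_lines <- body_lines[nzchar(trimws(body_lines))]
  body <- do.call(rbind, lapply(strsplit(body_lines, "\t"), as.numeric))
  tm <- body[, 2]
  rate_chk <- .check_uniform_time(tm, path)
  if (abs(rate_chk - rate) > 1e-3 * rate) rate <- rate_chk
  xyz <- body[, -(1:2), drop = FALSE]
  if (ncol(xyz) != 3L * length(labels))
    stop("TRC column count does not match marker labels in ", path)
  if (anyNA(xyz))
    stop("NaN samples in ", path, "; gap-fill upstream before reading")
  src_wanted <- .map_source(map, opt_channels(), "positions")
  idx <- match(src_wanted, labels)
  if (anyNA(idx))
    stop("missing mapped channel(s) in ", path, ": ",
         paste(opt_channels()[is.na(idx)], collapse = ", "))
  scale <- .UNIT_SCALE[[units]]
  pos <- matrix(0, nrow(xyz), 78L, dimnames = list(NULL, .pos_colnames()))
  for (j in seq_along(idx))
    pos[, (3L * (j - 1L) + 1L):(3L * j)] <-
      xyz[, (3L * (idx[j] - 1L) + 1L):(3L * idx[j]), drop = FALSE] * scale
  motion_trial(athlete_id, task, rate, positions = pos)
}

## ---- wide segment-kinematics CSV ------------------------------------------

.write_segment_csv <- function(trial, path) {
  if (is.null(trial$lin_vel) || is.null(trial$ang_vel))
    stop("trial carries no segment kinematics")
  tm <- (seq_len(trial$frames) - 1) / trial$sample_rate
  df <- data.frame(time = tm, trial$lin_vel, trial$ang_vel,
                   check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
}

.read_segment_csv <- function(path, map, athlete_id, task) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("segment CSV must have a `time` column")
  rate <- .check_uniform_time(df$time, path)
  get_block <- function(kind, unit_key) {
    out <- matrix(0, nrow(df), 39L,
                  dimnames = list(NULL, .vel_colnames(kind)))
    src_seg <- .map_source(map, simu_segments(), "segments")
    for (j in seq_along(simu_segments())) {
      cols <- paste(src_seg[j], kind, .axes, sep = ".")
      if (!all(cols %in% names(df)))
        stop("missing mapped channel in ", path, ": ",
             paste0(simu_segments()[j], ".", kind))
      out[, (3L * (j - 1L) + 1L):(3L * j)] <- as.matrix(df[, cols]) *
        .UNIT_SCALE[[map$units[[unit_key]]]]
    }
    out
  }
  lin <- get_block("linear_velocity", "velocity")
  ang <- get_block("angular_velocity", "angular")
  if (anyNA(lin) || anyNA(ang))
    stop("NaN samples in ", path, "; gap-fill upstream before reading")
  motion_trial(athlete_id, task, rate, lin_vel = lin, ang_vel = ang)
}

## ---- feature-matrix serialization -----------------------------------------

.matrix_colnames <- function(variant, target_frames) {
  w <- max(3L, nchar(as.character(target_frames - 1L)))
  tt <- sprintf(paste0("t%0", w, "d"), seq_len(target_frames) - 1L)
  if (variant == "OPT") {
    as.vector(t(outer(as.vector(t(outer(opt_channels(),
                                        paste0("position.", .axes),
                                        paste, sep = "."))),
                      tt, paste, sep = ".")))
  } else {
    feats <- as.vector(t(outer(simu_segments(),
                               c("linear_acceleration_norm",
                                 "angular_velocity_norm"),
                               paste, sep = ".")))
    as.vector(t(outer(feats, tt, paste, sep = ".")))
  }
}

.matrix_width <- function(variant, target_frames) {
  if (variant == "OPT") 26L * 3L * target_frames else 13L * 2L * target_frames
}

#' Construct a feature matrix container
#'
#' @param values Numeric matrix, athletes x features, with `athlete_id`
#'   row names.
#' @param variant `"OPT"` (26 channels x 3 axes x frames) or `"sIMU"`
#'   (13 segments x 2 norm features x frames).
#' @param target_frames Number of time-normalized frames per feature.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, variant = c("OPT", "sIMU"),
                           target_frames) {
  variant <- match.arg(variant)
  target_frames <- as.integer(target_frames)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  want <- .matrix_width(variant, target_frames)
  if (ncol(values) != want)
    stop("column-count mismatch: ", variant, " at ", target_frames,
         " frames requires ", want, " columns, got ", ncol(values))
  if (is.null(rownames(values))) stop("values must have athlete_id row names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate athlete_id rows: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyNA(values)) stop("feature matrix must not contain NaN")
  colnames(values) <- .matrix_colnames(variant, target_frames)
  structure(list(values = values, variant = variant,
                 target_frames = target_frames),
            class = "feature_matrix")
}

#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %s> %d athletes x %d features (%d frames)\n",
              x$variant, nrow(x$values), ncol(x$values), x$target_frames))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' The first line is a schema comment (`# omat_matrix variant=... frames=...`),
#' followed by a header row carrying full column provenance
#' (`channel.feature.axis-or-norm.tNNN`) and one row per athlete with the
#' athlete id in the first column. Round-trips losslessly.
#'
#' @param matrix A [feature_matrix()].
#' @param path Output path.
#' @return `path` invisibly for `write_matrix`; a [feature_matrix()] for
#'   `read_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# omat_matrix variant=%s frames=%d",
                     matrix$variant, matrix$target_frames), con)
  writeLines(paste(c("athlete_id", colnames(matrix$values)), collapse = ","),
             con)
  vals <- format(matrix$values, digits = 17, trim = TRUE,
                 scientific = TRUE)
  writeLines(paste(rownames(matrix$values),
                   apply(vals, 1, paste, collapse = ","), sep = ","), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first,
                  regexec("variant=(OPT|sIMU) frames=([0-9]+)", first))[[1]]
  if (length(m) != 3L) stop("not an omat feature-matrix file: ", path)
  variant <- m[2]
  frames <- as.integer(m[3])
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  want <- .matrix_width(variant, frames)
  if (ncol(vals) != want)
    stop("column-count mismatch with declared variant in ", path,
         ": expected ", want, ", got ", ncol(vals))
  feature_matrix(vals, variant, frames)
}

## ---- cohort read/write -----------------------------------------------------

#' Write a cohort to a directory
#'
#' Athlete metadata goes to `athletes.csv` (`athlete_id`, `skill`, `sex`,
#' `height_m`); each trial is written as `<athlete>.<task>.trc` (positions)
#' and `<athlete>.<task>.segments.csv` (segment kinematics).
#'
#' @param cohort A list with `athletes` and `trials` as returned by
#'   [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- cohort$athletes
  names(meta)[names(meta) == "height"] <- "height_m"
  utils::write.csv(meta, file.path(dir, "athletes.csv"), row.names = FALSE)
  for (tr in cohort$trials) {
    stem <- file.path(dir, paste(tr$athlete_id, tr$task, sep = "."))
    if (!is.null(tr$positions)) .write_trc(tr, paste0(stem, ".trc"))
    if (!is.null(tr$lin_vel)) .write_segment_csv(tr,
                                                 paste0(stem, ".segments.csv"))
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `athletes.csv` and trial files.
#' @param channel_map Optional [channel_map()].
#' @return A list with `athletes` and `trials`.
#' @export
read_cohort <- function(dir, channel_map = NULL) {
  meta <- utils::read.csv(file.path(dir, "athletes.csv"),
                          stringsAsFactors = FALSE)
  names(meta)[names(meta) == "height_m"] <- "height"
  trials <- list()
  for (f in sort(list.files(dir, pattern = "\\.segments\\.csv$"))) {
    stem <- sub("\\.segments\\.csv$", "", f)
    aid <- sub("\\..*$", "", stem)
    task <- sub("^[^.]*\\.", "", stem)
    tr <- .read_segment_csv(file.path(dir, f), channel_map %||% channel_map(),
                            aid, task)
    trc <- file.path(dir, paste0(stem, ".trc"))
    if (file.exists(trc)) {
      p <- .read_trc(trc, channel_map %||% channel_map(), aid, task)
      tr$positions <- p$positions
    }
    trials[[stem]] <- tr
  }
  list(athletes = meta, trials = trials)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
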