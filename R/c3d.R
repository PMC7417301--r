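# Minimal C3D support (Intel processor type, floating-point 3D point data,
# no analog channels, no compressed parameters). Covers what the pipeline
# needs: POINT USED / RATE / FRAMES / LABELS / SCALE / UNITS and the 3D data
# section. C3D stores data in 512-byte blocks; words are 16-bit.

.c3d_write_param_section <- function(labels, rate, n_frames, units) {
  n <- length(labels)
  lab_w <- max(4L, max(nchar(labels)))
  lab_padded <- formatC(labels, width = -lab_w)  # left-justified, blank pad

  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  w8 <- function(x) writeBin(as.integer(x), con, size = 1L,
                             endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wchar <- function(s) writeBin(charToRaw(s), con)

  # section prologue: 2 reserved bytes, block count (patched later), proc 84
  w8(c(1L, 80L, 0L, 84L))

  group <- function(id, name, desc = "") {
    w8(nchar(name)); w8(-id); wchar(name)
    w16(2L + nchar(desc) + 1L)  # offset to next entry
    w8(nchar(desc)); if (nzchar(desc)) wchar(desc)
  }
  param <- function(gid, name, type, dims, data, char_data = NULL) {
    w8(nchar(name)); w8(gid); wchar(name)
    data_bytes <- if (type == -1L) length(char_data) else
      abs(type) * length(data)
    w16(2L + 1L + 1L + length(dims) + data_bytes + 1L)
    w8(type); w8(length(dims)); if (length(dims)) w8(dims)
    if (type == -1L) writeBin(char_data, con)
    else if (type == 2L) w16(data)
    else wf(data)
    w8(0L)  # no description
  }

  group(1L, "POINT")
  param(1L, "USED", 2L, integer(0), n)
  param(1L, "FRAMES", 2L, integer(0), n_frames)
  param(1L, "RATE", 4L, integer(0), rate)
  param(1L, "SCALE", 4L, integer(0), -1)
  param(1L, "UNITS", -1L, nchar(units),
        char_data = charToRaw(units))
  param(1L, "LABELS", -1L, c(lab_w, n),
        char_data = charToRaw(paste(lab_padded, collapse = "")))
  w8(c(0L, 0L))  # terminating zero offset

  buf <- rawConnectionValue(con)
  n_blocks <- ceiling(length(buf) / 512)
  buf[3] <- as.raw(n_blocks)
  c(buf, raw(n_blocks * 512 - length(buf)))
}

.write_c3d_trial <- function(trial, path) {
  if (is.null(trial$positions)) stop("trial carries no position channels")
  labels <- opt_channels()
  n <- length(labels)
  fr <- trial$frames

  par_sec <- .c3d_write_param_section(labels, trial$sample_rate, fr, "m")
  n_par_blocks <- length(par_sec) / 512
  data_start <- 2L + n_par_blocks  # header is block 1, params from block 2

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  # header block
  w16(2L + 256L * 80L)        # param block pointer (2) + 0x50 magic
  w16(n)                      # points
  w16(0L)                     # analog per frame
  w16(1L)                     # first frame
  w16(fr)                     # last frame
  w16(10L)                    # max interpolation gap
  wf(-1)                      # 3D scale, negative => float data
  w16(data_start)             # data start block
  w16(0L)                     # analog samples per frame
  wf(trial$sample_rate)
  writeBin(raw(512L - 24L), con)
  writeBin(par_sec, con)
  # data: frames x points x (x, y, z, residual) floats
  arr <- array(0, c(4L, n, fr))
  for (j in seq_len(n))
    arr[1:3, j, ] <- t(trial$positions[, (3L * (j - 1L) + 1L):(3L * j)])
  wf(as.vector(arr))
}

.c3d_read_params <- function(raw_all, start_block) {
  off <- (start_block - 1L) * 512L
  proc <- as.integer(raw_all[off + 4L])
  if (proc != 84L)
    stop("unsupported C3D processor type ", proc,
         " (only Intel/PC files are supported)")
  i <- off + 5L  # 1-based index of first group/param byte
  params <- list()
  groups <- character(0)
  r8s <- function(k) { v <- as.integer(raw_all[k]); if (v > 127) v - 256L
    else v }
  while (TRUE) {
    nname <- r8s(i)
    if (nname == 0L) break
    id <- r8s(i + 1L)
    name <- rawToChar(raw_all[(i + 2L):(i + 1L + abs(nname))])
    j <- i + 2L + abs(nname)
    offset <- readBin(raw_all[j:(j + 1L)], "integer", size = 2L,
                      endian = "little")
    if (offset == 0L) {
      if (id < 0L) groups[as.character(-id)] <- name
      break
    }
    nxt <- j + offset
    if (id < 0L) {
      groups[as.character(-id)] <- name
    } else {
      type <- r8s(j + 2L)
      ndim <- r8s(j + 3L)
      dims <- if (ndim > 0L)
        as.integer(raw_all[(j + 4L):(j + 3L + ndim)]) else integer(0)
      dstart <- j + 4L + ndim
      count <- if (length(dims)) prod(dims) else 1L
      data <- switch(as.character(type),
        "-1" = raw_all[dstart:(dstart + count - 1L)],
        "1" = as.integer(raw_all[dstart:(dstart + count - 1L)]),
        "2" = readBin(raw_all[dstart:(dstart + 2L * count - 1L)],
                      "integer", n = count, size = 2L, endian = "little"),
        "4" = readBin(raw_all[dstart:(dstart + 4L * count - 1L)],
                      "numeric", n = count, size = 4L, endian = "little"),
        stop("unsupported C3D parameter type ", type))
      params[[paste0(id, ":", name)]] <-
        list(gid = id, name = name, type = type, dims = dims, data = data)
    }
    i <- nxt
  }
  point_gid <- as.integer(names(groups)[groups == "POINT"])
  if (length(point_gid) != 1L) stop("C3D file has no POINT group")
  get <- function(nm) {
    p <- params[[paste0(point_gid, ":", nm)]]
    if (is.null(p)) stop("C3D POINT group lacks parameter ", nm)
    p
  }
  labels_p <- get("LABELS")
  lab_w <- labels_p$dims[1]
  n_lab <- if (length(labels_p$dims) > 1L) labels_p$dims[2] else 1L
  labels <- vapply(seq_len(n_lab), function(k)
    trimws(rawToChar(labels_p$data[((k - 1L) * lab_w + 1L):(k * lab_w)])),
    character(1))
  units <- tryCatch(trimws(rawToChar(get("UNITS")$data)),
                    error = function(e) "m")
  list(used = get("USED")$data, frames = get("FRAMES")$data,
       rate = get("RATE")$data, scale = get("SCALE")$data,
       labels = labels, units = units)
}

.read_c3d_trial <- function(path, map, athlete_id, task) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  hdr <- function(word) {
    readBin(raw_all[(2L * (word - 1L) + 1L):(2L * word)], "integer",
            size = 2L, endian = "little")
  }
  param_block <- as.integer(raw_all[1])
  if (as.integer(raw_all[2]) != 80L) stop("not a C3D file: ", path)
  n_points <- hdr(2)
  first_frame <- hdr(4)
  last_frame <- hdr(5)
  data_start <- hdr(9)
  rate <- readBin(raw_all[21:24], "numeric", size = 4L, endian = "little")

  p <- .c3d_read_params(raw_all, param_block)
  if (p$scale >= 0)
    stop("unsupported C3D variant: integer point data (scale >= 0)")
  n_frames <- last_frame - first_frame + 1L
  off <- (data_start - 1L) * 512L
  vals <- readBin(raw_all[(off + 1L):(off + 4L * 4L * n_points * n_frames)],
                  "numeric", n = 4L * n_points * n_frames, size = 4L,
                  endian = "little")
  arr <- array(vals, c(4L, n_points, n_frames))
  units <- if (p$units %in% names(.UNIT_SCALE)) p$units else
    map$units[["position"]]
  src_wanted <- .map_source(map, opt_channels(), "positions")
  idx <- match(src_wanted, p$labels)
  if (anyNA(idx))
    stop("missing mapped channel(s) in ", path, ": ",
         paste(opt_channels()[is.na(idx)], collapse = ", "))
  pos <- matrix(0, n_frames, 78L, dimnames = list(NULL, .pos_colnames()))
  for (j in seq_along(idx))
    pos[, (3L * (j - 1L) + 1L):(3L * j)] <-
      t(arr[1:3, idx[j], , drop = TRUE]) * .UNIT_SCALE[[units]]
  if (anyNA(pos))
    stop("NaN samples in ", path, "; gap-fill upstream before reading")
  motion_trial(athlete_id, task, rate, positions = pos)
}
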