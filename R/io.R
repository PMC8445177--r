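#' Read and write tractogram files
#'
#' Three on-disk formats are supported, all little-endian:
#'
#' * `trk`: TrackVis .trk — 1000-byte binary header followed by per-track
#'   records (`int32` point count, then xyz `float32` triples).
#' * `bundles`: BrainVISA bundles — a text header (`.bundles`) recording
#'   `curves_count`, plus a binary payload (`.bundlesdata`) storing, per
#'   fiber, an `int32` point count followed by xyz `float32` triples.
#' * `array`: headerless raw dump of an `N x 21 x 3` `float32` array,
#'   fiber-major.
#'
#' On read, fibers that do not have exactly `n_points` points are resampled
#' with [resample_fiber()], so any readable file yields a pipeline-ready
#' tractogram. Coordinates round-trip exactly at float32 precision.
#'
#' @param path file to read or write. For `bundles` this is the `.bundles`
#'   header; the payload lives beside it as `<path>data`.
#' @param format one of `"trk"`, `"bundles"`, `"array"`, or `"auto"`
#'   (guessed from the extension).
#' @param n_points number of points per fiber after reading (default 21).
#' @return `read_tractogram()` returns a [tractogram];
#'   `write_tractogram()` returns `path` invisibly.
#' @export
read_tractogram <- function(path, format = c("auto", "trk", "bundles", "array"),
                            n_points = 21L) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) {
    stop(sprintf("tractogram file not found: %s", path), call. = FALSE)
  }
  fibs <- switch(format,
    trk     = read_trk_fibers(path),
    bundles = read_bundles_fibers(path),
    array   = read_array_fibers(path, n_points)
  )
  if (length(fibs) == 0L) {
    stop(sprintf("format error in %s: file contains no fibers.", path),
         call. = FALSE)
  }
  same <- all(vapply(fibs, nrow, 1L) == n_points)
  if (!same) {
    fibs <- lapply(fibs, resample_fiber, n_points = n_points)
  }
  tractogram(fibs, space_note = sprintf("read from %s (%s)", basename(path), format))
}

#' @rdname read_tractogram
#' @param tt a [tractogram] (or any data frame with tractogram columns).
#' @export
write_tractogram <- function(tt, path, format = c("auto", "trk", "bundles", "array")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  tt <- as_tractogram(tt)
  fibs <- lapply(seq_len(n_fibers(tt)), function(i) fiber_matrix(tt, i))
  switch(format,
    trk     = write_trk_fibers(fibs, path),
    bundles = write_bundles_fibers(fibs, path),
    array   = write_array_fibers(fibs, path)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    trk = "trk",
    bundles = "bundles",
    bundlesdata = "bundles",
    "array"
  )
}

# --- low-level binary helpers -------------------------------------------

# all readers consume a raw vector with an explicit cursor so that format
# errors can name the byte offset at which parsing failed
raw_cursor <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n == 0L) {
    stop(sprintf("format error in %s: empty file.", path), call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$raw <- readBin(path, "raw", n = n)
  env$pos <- 0L
  env$path <- path
  env
}

cur_read <- function(cur, what, n, size) {
  need <- n * size
  if (cur$pos + need > length(cur$raw)) {
    stop(sprintf("format error in %s: truncated payload at byte offset %d (needed %d more bytes).",
                 cur$path, cur$pos, need), call. = FALSE)
  }
  out <- readBin(cur$raw[(cur$pos + 1L):(cur$pos + need)], what = what,
                 n = n, size = size, endian = "little")
  cur$pos <- cur$pos + need
  out
}

cur_remaining <- function(cur) length(cur$raw) - cur$pos

f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")
i32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
i16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
chr <- function(s, width) {
  r <- charToRaw(s)
  c(r, raw(width - length(r)))
}

# --- TRK ----------------------------------------------------------------

TRK_HDR_SIZE <- 1000L

write_trk_fibers <- function(fibs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    chr("TRACK", 6L),                       # id_string
    i16(c(1L, 1L, 1L)),                     # dim
    f32(c(1, 1, 1)),                        # voxel_size
    f32(c(0, 0, 0)),                        # origin
    i16(0L), raw(200L),                     # n_scalars, scalar_name
    i16(0L), raw(200L),                     # n_properties, property_name
    f32(as.vector(t(diag(4)))),             # vox_to_ras (row-major identity)
    raw(444L),                              # reserved
    chr("RAS", 4L), raw(4L),                # voxel_order, pad2
    f32(c(1, 0, 0, 0, 1, 0)),               # image_orientation_patient
    raw(2L), raw(6L),                       # pad1, invert/swap flags
    i32(length(fibs)),                      # n_count
    i32(2L),                                # version
    i32(TRK_HDR_SIZE)                       # hdr_size
  )
  stopifnot(length(hdr) == TRK_HDR_SIZE)
  writeBin(hdr, con)
  for (f in fibs) {
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    writeBin(as.numeric(t(f)), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_trk_fibers <- function(path) {
  cur <- raw_cursor(path)
  if (cur_remaining(cur) < TRK_HDR_SIZE) {
    stop(sprintf("format error in %s: header shorter than %d bytes (offset %d).",
                 path, TRK_HDR_SIZE, cur_remaining(cur)), call. = FALSE)
  }
  magic <- rawToChar(cur$raw[1:5])
  if (magic != "TRACK") {
    stop(sprintf("format error in %s: malformed header at byte offset 0 (id_string '%s', expected 'TRACK').",
                 path, magic), call. = FALSE)
  }
  cur$pos <- 36L
  n_scalars <- cur_read(cur, "integer", 1L, 2L)
  cur$pos <- 238L
  n_properties <- cur_read(cur, "integer", 1L, 2L)
  cur$pos <- 988L
  n_count <- cur_read(cur, "integer", 1L, 4L)
  cur$pos <- 996L
  hdr_size <- cur_read(cur, "integer", 1L, 4L)
  if (hdr_size != TRK_HDR_SIZE) {
    stop(sprintf("format error in %s: malformed header at byte offset 996 (hdr_size %d).",
                 path, hdr_size), call. = FALSE)
  }
  fibs <- list()
  while (cur_remaining(cur) > 0L && (n_count == 0L || length(fibs) < n_count)) {
    npts <- cur_read(cur, "integer", 1L, 4L)
    if (npts <= 0L) {
      stop(sprintf("format error in %s: non-positive point count at byte offset %d.",
                   path, cur$pos - 4L), call. = FALSE)
    }
    vals <- cur_read(cur, "numeric", npts * (3L + n_scalars), 4L)
    if (n_scalars > 0L) {
      vals <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3]
    } else {
      vals <- matrix(vals, ncol = 3L, byrow = TRUE)
    }
    if (n_properties > 0L) cur_read(cur, "numeric", n_properties, 4L)
    fibs[[length(fibs) + 1L]] <- vals
  }
  if (n_count > 0L && length(fibs) != n_count) {
    stop(sprintf("format error in %s: header n_count %d disagrees with payload (%d tracks read).",
                 path, n_count, length(fibs)), call. = FALSE)
  }
  fibs
}

# --- BrainVISA bundles --------------------------------------------------

bundlesdata_path <- function(path) paste0(path, "data")

write_bundles_fibers <- function(fibs, path) {
  hdr <- c(
    "attributes = {",
    "    'binary' : 1,",
    "    'bundles' : [ 'whole', 0 ],",
    "    'byte_order' : 'DCBA',",
    sprintf("    'curves_count' : %d,", length(fibs)),
    "    'data_file_name' : '*.bundlesdata',",
    "    'format' : 'bundles_1.0',",
    "    'space_dimension' : 3",
    "}"
  )
  writeLines(hdr, path)
  con <- file(bundlesdata_path(path), "wb")
  on.exit(close(con))
  for (f in fibs) {
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    writeBin(as.numeric(t(f)), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_bundles_fibers <- function(path) {
  hdr <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  if (length(hdr) == 0L) {
    stop(sprintf("format error in %s: empty file.", path), call. = FALSE)
  }
  m <- regmatches(hdr, regexpr("'curves_count'\\s*:\\s*[0-9]+", hdr))
  m <- unlist(m)
  if (length(m) != 1L) {
    stop(sprintf("format error in %s: malformed header ('curves_count' missing).", path),
         call. = FALSE)
  }
  n_count <- as.integer(sub(".*:\\s*", "", m))
  dpath <- bundlesdata_path(path)
  if (!file.exists(dpath)) {
    stop(sprintf("format error in %s: data file %s not found.", path, dpath),
         call. = FALSE)
  }
  cur <- raw_cursor(dpath)
  fibs <- list()
  while (cur_remaining(cur) > 0L) {
    npts <- cur_read(cur, "integer", 1L, 4L)
    if (npts <= 0L) {
      stop(sprintf("format error in %s: non-positive point count at byte offset %d.",
                   dpath, cur$pos - 4L), call. = FALSE)
    }
    vals <- cur_read(cur, "numeric", npts * 3L, 4L)
    fibs[[length(fibs) + 1L]] <- matrix(vals, ncol = 3L, byrow = TRUE)
  }
  if (length(fibs) != n_count) {
    stop(sprintf("format error in %s: header 'curves_count' %d disagrees with payload (%d fibers).",
                 path, n_count, length(fibs)), call. = FALSE)
  }
  fibs
}

# --- raw array dump -----------------------------------------------------

write_array_fibers <- function(fibs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (f in fibs) writeBin(as.numeric(t(f)), con, size = 4, endian = "little")
  invisible(path)
}

read_array_fibers <- function(path, n_points = 21L) {
  cur <- raw_cursor(path)
  bytes_per_fiber <- n_points * 3L * 4L
  if (length(cur$raw) %% bytes_per_fiber != 0L) {
    stop(sprintf("format error in %s: size %d bytes is not a multiple of %d (N x %d x 3 float32); truncated at byte offset %d.",
                 path, length(cur$raw), bytes_per_fiber, n_points,
                 (length(cur$raw) %/% bytes_per_fiber) * bytes_per_fiber),
         call. = FALSE)
  }
  n <- length(cur$raw) %/% bytes_per_fiber
  lapply(seq_len(n), function(i) {
    matrix(cur_read(cur, "numeric", n_points * 3L, 4L), ncol = 3L, byrow = TRUE)
  })
}
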