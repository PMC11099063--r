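#' Wavelength-shift video of one biosensor well
#'
#' Container for one well's recording on an 80x80-pixel RWG sensor: a
#' 3D array of wavelength-shift values (picometres) indexed
#' `[row, col, frame]` plus the acquisition time axis in minutes.
#'
#' @param values numeric array `nrow x ncol x T`, pm.
#' @param times numeric vector of length `T`, minutes, strictly increasing.
#' @param well_id well identifier (e.g. "A1").
#' @param measurement_id identifier of the measurement session (batch).
#' @return object of class `ws_video`.
#' @export
ws_video <- function(values, times, well_id = "A1", measurement_id = "M1") {
  check_that(is.array(values) && length(dim(values)) == 3,
             "values must be a 3D array [row, col, frame]")
  check_that(length(times) == dim(values)[3],
             "times length must equal the number of frames")
  check_that(length(times) == 1 || !is.unsorted(times, strictly = TRUE),
             "times must be strictly increasing")
  check_that(all(is.finite(values)), "values must be finite")
  structure(
    list(values = values, times = as.numeric(times),
         well_id = well_id, measurement_id = measurement_id),
    class = "ws_video"
  )
}

#' @export
print.ws_video <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ws_video> well %s (measurement %s): %dx%d px, %d frames, %.1f-%.1f min\n",
              x$well_id, x$measurement_id, d[1], d[2], d[3],
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
dim.ws_video <- function(x) dim(x$values)

N_WELLS_PER_PLATE <- 12L
SENSOR_PX <- 80L

# ---- raw container I/O -----------------------------------------------------
#
# A raw measurement is a sequence of frames, each frame 12 concatenated
# 80x80 wavelength-shift matrices (one per well, stacked along rows into a
# 960x80 block). Two dialects are supported:
#
#  * "text":   line 1 "RWGRAW text <n_wells> <n_rows> <n_cols> <T>",
#              line 2 the T frame times in minutes, then T frames, each
#              n_wells*n_rows lines of n_cols whitespace-separated values.
#  * "binary": magic "RWGRAWB1", then little-endian int32 header
#              (n_wells, n_rows, n_cols, T), T float64 times, then
#              frame-major float32 values (within a frame: well-major,
#              then column-major 80x80).

#' Write a raw multi-well container
#'
#' @param videos list of [ws_video()] objects (one per well, equal time axes).
#' @param path output file.
#' @param dialect `"text"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_raw_container <- function(videos, path, dialect = c("text", "binary")) {
  dialect <- match.arg(dialect)
  check_that(length(videos) >= 1, "need at least one well video")
  check_that(all(vapply(videos, inherits, logical(1), "ws_video")),
             "videos must be ws_video objects")
  d <- dim(videos[[1]]$values)
  times <- videos[[1]]$times
  for (v in videos) {
    check_that(identical(dim(v$values), d), "all wells must share frame shape")
    check_that(isTRUE(all.equal(v$times, times)), "all wells must share times")
  }
  n_wells <- length(videos); nr <- d[1]; nc <- d[2]; tt <- d[3]
  if (dialect == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("RWGRAW text %d %d %d %d", n_wells, nr, nc, tt), con)
    writeLines(paste(format(times, digits = 15), collapse = " "), con)
    for (f in seq_len(tt)) {
      for (w in seq_len(n_wells)) {
        m <- videos[[w]]$values[, , f]
        writeLines(apply(m, 1, function(r) paste(format(r, digits = 15),
                                                 collapse = " ")), con)
      }
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("RWGRAWB1", con, nchars = 8, eos = NULL)
    writeBin(as.integer(c(n_wells, nr, nc, tt)), con, size = 4,
             endian = "little")
    writeBin(as.numeric(times), con, size = 8, endian = "little")
    for (f in seq_len(tt)) {
      for (w in seq_len(n_wells)) {
        writeBin(as.numeric(videos[[w]]$values[, , f]), con, size = 4,
                 endian = "little")
      }
    }
  }
  invisible(path)
}

#' Read a raw multi-well container into per-well videos
#'
#' Splits the concatenated-well frames back into one [ws_video()] per well
#' with a shared time axis. The dialect is auto-detected from the file
#' magic. Well ids are `W01..Wnn`; `measurement_id` defaults to the file
#' name without extension.
#'
#' @param path container file written by [write_raw_container()].
#' @param measurement_id optional measurement identifier override.
#' @return list of [ws_video()] objects.
#' @export
load_raw_frames <- function(path, measurement_id = NULL) {
  check_that(file.exists(path), sprintf("no such file: %s", path))
  if (is.null(measurement_id)) {
    measurement_id <- sub("\\.[^.]*$", "", basename(path))
  }
  magic <- readChar(path, nchars = 8, useBytes = TRUE)
  if (identical(magic, "RWGRAWB1")) {
    con <- file(path, "rb")
    on.exit(close(con))
    readChar(con, nchars = 8, useBytes = TRUE)
    hdr <- readBin(con, "integer", n = 4, size = 4, endian = "little")
    n_wells <- hdr[1]; nr <- hdr[2]; nc <- hdr[3]; tt <- hdr[4]
    check_that(all(hdr > 0), "corrupt binary header")
    times <- readBin(con, "numeric", n = tt, size = 8, endian = "little")
    vals <- lapply(seq_len(n_wells), function(w) array(0, c(nr, nc, tt)))
    per_frame <- nr * nc
    for (f in seq_len(tt)) {
      for (w in seq_len(n_wells)) {
        x <- readBin(con, "numeric", n = per_frame, size = 4,
                     endian = "little")
        check_that(length(x) == per_frame,
                   sprintf("frame %d: truncated well block %d (expected %d values, got %d)",
                           f - 1, w - 1, per_frame, length(x)))
        vals[[w]][, , f] <- x
      }
    }
  } else {
    lines <- readLines(path)
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    check_that(length(hdr) == 6 && hdr[1] == "RWGRAW" && hdr[2] == "text",
               "not an RWGRAW text container")
    dims <- as.integer(hdr[3:6])
    n_wells <- dims[1]; nr <- dims[2]; nc <- dims[3]; tt <- dims[4]
    times <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
    check_that(length(times) == tt, "time axis length mismatch")
    body <- lines[-(1:2)]
    check_that(length(body) >= n_wells * nr * tt,
               sprintf("frame %d: container truncated (expected %d data lines, got %d)",
                       length(body) %/% (n_wells * nr), n_wells * nr * tt,
                       length(body)))
    vals <- lapply(seq_len(n_wells), function(w) array(0, c(nr, nc, tt)))
    li <- 0L
    for (f in seq_len(tt)) {
      for (w in seq_len(n_wells)) {
        block <- body[li + seq_len(nr)]
        li <- li + nr
        m <- t(vapply(strsplit(trimws(block), "\\s+"), as.numeric,
                      numeric(nc)))
        check_that(ncol(m) == nc && nrow(m) == nr,
                   sprintf("frame %d: malformed well block %d", f - 1, w - 1))
        vals[[w]][, , f] <- m
      }
    }
  }
  lapply(seq_len(n_wells), function(w) {
    ws_video(vals[[w]], times,
             well_id = sprintf("W%02d", w),
             measurement_id = measurement_id)
  })
}
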