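#' Global background correction of a well video
#'
#' Real recordings carry a baseline drift and an injection-artifact step
#' common to all pixels of a well. Background pixels — those that never
#' rise above `bg_threshold` at any frame, i.e. that carry no cell signal —
#' are averaged per frame, and that per-frame average is subtracted from
#' the whole frame. After correction the mean over background pixels is
#' exactly zero at every frame, and any signal common to all pixels
#' (drift, artifact, constant offset) is removed.
#'
#' @param video a [ws_video()].
#' @param bg_threshold pm; pixels whose value stays below this across all
#'   frames count as background. Use the cell detection threshold.
#' @return list with `video` (corrected [ws_video()]) and `background_mask`
#'   (logical matrix, TRUE = background pixel).
#' @export
global_background_correct <- function(video, bg_threshold) {
  check_that(inherits(video, "ws_video"), "video must be a ws_video")
  d <- dim(video$values)
  # a pixel is background if it never rises above threshold relative to the
  # per-frame spatial median; the median tracks drift and the injection
  # artifact (cells occupy a small minority of pixels), so slow common-mode
  # signals do not promote background pixels into "cells"
  flat0 <- matrix(video$values, d[1] * d[2], d[3])
  med <- apply(flat0, 2, stats::median)
  rel <- flat0 - rep(med, each = d[1] * d[2])
  rel <- rel - rel[, 1]
  peakmax <- apply(rel, 1, max)
  above <- matrix(peakmax >= bg_threshold, d[1], d[2])
  # exclude the 1-px fringe around above-threshold pixels as well: cell
  # footprints bleed sub-threshold signal into their immediate neighbours,
  # which would bias the background average
  dil <- above
  nr <- d[1]; nc <- d[2]
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      src_r <- max(1, 1 - dr):min(nr, nr - dr)
      src_c <- max(1, 1 - dc):min(nc, nc - dc)
      dil[src_r + dr, src_c + dc] <-
        dil[src_r + dr, src_c + dc] | above[src_r, src_c]
    }
  }
  mask <- !dil
  check_that(any(mask),
             "no background pixels under this threshold; lower bg_threshold")
  flat <- matrix(video$values, d[1] * d[2], d[3])
  bg_mean <- colMeans(flat[as.vector(mask), , drop = FALSE])
  corrected <- video$values - rep(bg_mean, each = d[1] * d[2])
  out <- video
  out$values <- corrected
  list(video = out, background_mask = mask)
}

#' Detect single-cell peaks on a wavelength-shift frame
#'
#' Adherent single cells appear as compact local maxima on the WS map, so
#' detection is a 2D local-maxima search: a pixel is a peak when it is
#' strictly greater than all its 8-connected neighbours (plateau ties are
#' broken in favour of the smallest (row, col) lexicographic index) and its
#' value is at least `threshold`. Peaks closer than `min_distance` px
#' (Euclidean) are thinned greedily in descending amplitude order.
#'
#' @param video a [ws_video()] (typically background-corrected).
#' @param threshold minimal detection threshold, pm; local maxima below it
#'   are neglected.
#' @param min_distance minimal peak separation, px.
#' @param detection_frame `"last"` (default; cells fully developed),
#'   `"max"` (per-pixel maximum projection over frames), or a 1-based
#'   frame index.
#' @return object of class `peak_set`: data.frame `peaks` (row, col,
#'   amplitude; 0-based coordinates, sorted by descending amplitude) plus
#'   the detection parameters.
#' @export
detect_cell_peaks <- function(video, threshold, min_distance = 2,
                              detection_frame = "last") {
  check_that(inherits(video, "ws_video"), "video must be a ws_video")
  check_that(threshold > 0, "threshold must be positive")
  d <- dim(video$values)
  frame <- if (identical(detection_frame, "last")) {
    video$values[, , d[3]]
  } else if (identical(detection_frame, "max")) {
    apply(video$values, c(1, 2), max)
  } else {
    check_that(is.numeric(detection_frame) && detection_frame >= 1 &&
                 detection_frame <= d[3], "invalid detection_frame")
    video$values[, , as.integer(detection_frame)]
  }
  peaks <- find_local_maxima(frame, threshold)
  peaks <- suppress_close_peaks(peaks, min_distance)
  structure(
    list(peaks = peaks, detection_threshold = threshold,
         min_distance = min_distance, detection_frame = detection_frame),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks (threshold %g pm, min distance %g px)\n",
              nrow(x$peaks), x$detection_threshold, x$min_distance))
  invisible(x)
}

# Vectorized 8-neighbour local-maxima scan on one frame. Strict inequality
# against all 8 neighbours; on plateaus (exact ties) the smallest (row, col)
# in lexicographic order wins. Returns 0-based coordinates sorted by
# descending amplitude (ties: lexicographic).
find_local_maxima <- function(frame, threshold) {
  nr <- nrow(frame); nc <- ncol(frame)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- frame
  is_max <- matrix(TRUE, nr, nc)
  # lexicographic rank of each pixel, used only to order exact ties
  rank_self <- matrix(seq_len(nr * nc), nr, nc, byrow = FALSE)
  rank_self <- (row(frame) - 1) * nc + (col(frame) - 1)
  rank_pad <- matrix(Inf, nr + 2, nc + 2)
  rank_pad[2:(nr + 1), 2:(nc + 1)] <- rank_self
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nbr <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
      nbr_rank <- rank_pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
      # neighbour strictly larger, or equal with smaller lexicographic
      # rank, disqualifies this pixel
      is_max <- is_max & !(nbr > frame | (nbr == frame & nbr_rank < rank_self))
    }
  }
  is_max <- is_max & frame >= threshold
  idx <- which(is_max, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                    amplitude = frame[idx])
  out[order(-out$amplitude, out$row, out$col), , drop = FALSE]
}

# Greedy suppression: walk peaks in descending amplitude, drop any peak
# within min_distance (Euclidean, strictly less) of an already kept one.
suppress_close_peaks <- function(peaks, min_distance) {
  if (nrow(peaks) <= 1 || min_distance <= 0) {
    rownames(peaks) <- NULL
    return(peaks)
  }
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    kept <- which(keep)
    if (length(kept) == 0 ||
        min((peaks$row[kept] - peaks$row[i])^2 +
              (peaks$col[kept] - peaks$col[i])^2) >= min_distance^2) {
      keep[i] <- TRUE
    }
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition the sensor area into per-cell Voronoi regions of interest
#'
#' Every pixel is assigned to its nearest detected peak (Euclidean
#' distance between pixel centres). Equidistant pixels go to the peak with
#' the lower index in the peak set (i.e. the higher-amplitude peak), which
#' makes the partition deterministic.
#'
#' @param peaks a `peak_set` from [detect_cell_peaks()].
#' @param grid_shape `c(n_rows, n_cols)`; default the 80x80 sensor.
#' @return object of class `roi_map`: integer matrix `labels` of region
#'   indices (1-based into `peaks$peaks`).
#' @export
assign_voronoi_rois <- function(peaks, grid_shape = c(SENSOR_PX, SENSOR_PX)) {
  check_that(inherits(peaks, "peak_set"), "peaks must be a peak_set")
  np <- nrow(peaks$peaks)
  check_that(np >= 1, "cannot tessellate an empty peak set")
  nr <- grid_shape[1]; nc <- grid_shape[2]
  pr <- peaks$peaks$row; pc <- peaks$peaks$col
  rows <- as.vector(row(matrix(0, nr, nc))) - 1L
  cols <- as.vector(col(matrix(0, nr, nc))) - 1L
  # distance matrix pixels x peaks; max.col(-d, "first") gives the nearest
  # peak with ties to the lowest peak index
  d2 <- outer(rows, pr, function(a, b) (a - b)^2) +
    outer(cols, pc, function(a, b) (a - b)^2)
  lab <- max.col(-d2, ties.method = "first")
  structure(
    list(labels = matrix(lab, nr, nc), n_regions = np),
    class = "roi_map"
  )
}

#' @export
print.roi_map <- function(x, ...) {
  cat(sprintf("<roi_map> %dx%d px, %d regions\n",
              nrow(x$labels), ncol(x$labels), x$n_regions))
  invisible(x)
}

#' Extract per-cell maxWS kinetic signals
#'
#' The maxWS signal of a cell is the maximum wavelength-shift value within
#' its region of interest at each frame. One record per detected peak.
#'
#' @param video a (corrected) [ws_video()].
#' @param rois an `roi_map` from [assign_voronoi_rois()].
#' @param peaks the matching `peak_set`.
#' @param labels optional class label applied to all cells of the well.
#' @return a [cell_records()] collection; `params` holds per-cell peak
#'   positions and ROI indices.
#' @export
extract_max_ws <- function(video, rois, peaks, labels = NA_character_) {
  check_that(inherits(video, "ws_video"), "video must be a ws_video")
  d <- dim(video$values)
  check_that(all(dim(rois$labels) == d[1:2]),
             "roi map shape does not match video")
  np <- nrow(peaks$peaks)
  flat <- matrix(video$values, d[1] * d[2], d[3])
  lab <- as.vector(rois$labels)
  sig <- matrix(-Inf, np, d[3])
  for (k in seq_len(np)) {
    sig[k, ] <- suppressWarnings(
      apply(flat[lab == k, , drop = FALSE], 2, max))
  }
  meta <- lapply(seq_len(np), function(k) {
    list(peak_row = peaks$peaks$row[k], peak_col = peaks$peaks$col[k],
         roi = k, well_id = video$well_id)
  })
  cell_records(sig, rep(labels, length.out = np),
               rep(video$measurement_id, np), video$times, meta)
}

#' Run the full single-well extraction chain
#'
#' Convenience wrapper: background correction, peak detection on the
#' configured frame, Voronoi partitioning, maxWS extraction.
#'
#' @param video a raw [ws_video()].
#' @param threshold detection threshold, pm.
#' @param min_distance minimal peak separation, px.
#' @param detection_frame see [detect_cell_peaks()].
#' @param labels optional class label for all cells in the well.
#' @return list with `records`, `peaks`, `rois`, `background_mask`,
#'   `corrected`.
#' @export
sensor_pipeline <- function(video, threshold, min_distance = 2,
                            detection_frame = "last",
                            labels = NA_character_) {
  bg <- global_background_correct(video, bg_threshold = threshold)
  peaks <- detect_cell_peaks(bg$video, threshold, min_distance,
                             detection_frame)
  if (nrow(peaks$peaks) == 0) {
    return(list(records = NULL, peaks = peaks, rois = NULL,
                background_mask = bg$background_mask,
                corrected = bg$video))
  }
  rois <- assign_voronoi_rois(peaks, dim(video$values)[1:2])
  records <- extract_max_ws(bg$video, rois, peaks, labels)
  list(records = records, peaks = peaks, rois = rois,
       background_mask = bg$background_mask, corrected = bg$video)
}

#' Export cell records as a delimited table
#'
#' Wide layout: `cell_id`, `well`, `batch`, `label`, then one column per
#' timestep (`t0001`...). Readable back with [read_cell_records()].
#'
#' @param records a [cell_records()].
#' @param path output TSV path.
#' @export
write_cell_records <- function(records, path) {
  sig <- records$signals
  colnames(sig) <- sprintf("t%04d", seq_len(ncol(sig)))
  df <- data.frame(cell_id = seq_len(nrow(sig)),
                   well = vapply(seq_len(nrow(sig)), function(i) {
                     p <- records$params[[i]]
                     if (is.list(p) && !is.null(p$well_id)) p$well_id else "NA"
                   }, character(1)),
                   batch = records$batch_ids,
                   label = records$labels,
                   sig, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  # sidecar with the time axis so the table round-trips
  writeLines(paste(format(records$times, digits = 15), collapse = " "),
             paste0(path, ".times"))
  invisible(path)
}

#' Read cell records written by [write_cell_records()]
#'
#' @param path TSV path.
#' @return a [cell_records()].
#' @export
read_cell_records <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  tcols <- grep("^t[0-9]{4}$", names(df))
  times_path <- paste0(path, ".times")
  times <- if (file.exists(times_path)) {
    as.numeric(strsplit(trimws(readLines(times_path)[1]), "\\s+")[[1]])
  } else {
    seq_len(length(tcols)) - 1
  }
  cell_records(as.matrix(df[, tcols, drop = FALSE]),
               labels = df$label, batch_ids = df$batch, times = times)
}
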