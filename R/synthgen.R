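#' Regular acquisition time grid
#'
#' @param duration_min total length in minutes.
#' @param delta_t_s frame period in seconds (default 9 s; the instrument
#'   scan itself is faster, but exported kinetic data are resampled to a
#'   fixed period, which stays configurable throughout the package).
#' @return minutes vector starting at 0.
#' @export
time_grid <- function(duration_min, delta_t_s = 9) {
  check_that(duration_min > 0 && delta_t_s > 0,
             "duration and frame period must be positive")
  seq(0, duration_min * 60, by = delta_t_s) / 60
}

#' Ground truth of one synthetic well
#'
#' Builds the truth record for [synthesize_well_video()]: cell positions on
#' the 80x80 grid, class labels, per-cell kinetic parameters, well-level
#' drift/artifact/noise. Positions are drawn uniformly without replacement,
#' keeping a 3-px margin from the sensor edge so every footprint fits.
#'
#' @param n_cells number of cells (the instrument resolves up to a few
#'   hundred per well; around a hundred is typical).
#' @param class_specs named list of [class_kinetic_spec()]; classes are
#'   assigned uniformly at random.
#' @param noise_sd frame noise sd, pm.
#' @param drift_rate linear baseline drift, pm/min.
#' @param artifact_jump injection-artifact step common to all pixels, pm;
#'   `NA` draws it uniformly from 5-25 pm.
#' @param artifact_frame frame index (1-based) at which the artifact step
#'   occurs; 1 means it is present from the start.
#' @param min_spacing minimum pairwise Euclidean distance between cell
#'   centres, px; cells closer than 2 px have overlapping footprints and
#'   are flagged. Set to 0 for unconstrained placement.
#' @param seed integer seed.
#' @return object of class `synthetic_well_truth`: data.frame `cells`
#'   (cell, row, col, class, amplitude) plus kinetic parameter list and
#'   well-level fields.
#' @export
synthetic_well_truth <- function(n_cells, class_specs,
                                 noise_sd = 0, drift_rate = 0,
                                 artifact_jump = 0, artifact_frame = 1L,
                                 min_spacing = 3, seed = 1L) {
  check_that(n_cells >= 0 && n_cells <= 200,
             "n_cells must be in [0, 200] (single-cell density regime)")
  check_that(length(class_specs) >= 1, "need at least one class spec")
  with_seed(seed, {
    margin <- 3L
    grid_pts <- expand.grid(row = margin:(SENSOR_PX - 1L - margin),
                            col = margin:(SENSOR_PX - 1L - margin))
    if (min_spacing > 0 && n_cells > 0) {
      # greedy thinning: scan shuffled candidates, keep those far enough
      # from all previously accepted centres
      ord <- sample(nrow(grid_pts))
      acc <- integer(0)
      for (j in ord) {
        if (length(acc) == n_cells) break
        if (length(acc) == 0 ||
            min((grid_pts$row[acc] - grid_pts$row[j])^2 +
                  (grid_pts$col[acc] - grid_pts$col[j])^2) >= min_spacing^2) {
          acc <- c(acc, j)
        }
      }
      check_that(length(acc) == n_cells,
                 "could not place all cells at the requested spacing")
      idx <- acc
    } else {
      idx <- sample(nrow(grid_pts), n_cells)
    }
    cls <- if (n_cells > 0) {
      names(class_specs)[sample(length(class_specs), n_cells, replace = TRUE)]
    } else character(0)
    params <- lapply(seq_len(n_cells), function(i) {
      sample_kinetic_params(class_specs[[cls[i]]])
    })
    if (is.na(artifact_jump)) artifact_jump <- stats::runif(1, 5, 25)
    cells <- data.frame(
      cell = seq_len(n_cells),
      row = if (n_cells > 0) grid_pts$row[idx] else integer(0),
      col = if (n_cells > 0) grid_pts$col[idx] else integer(0),
      class = cls,
      amplitude = vapply(params, function(p) p$amplitude, numeric(1)),
      stringsAsFactors = FALSE
    )
    crowded <- FALSE
    if (n_cells > 1) {
      dmat <- as.matrix(stats::dist(cells[, c("row", "col")]))
      diag(dmat) <- Inf
      crowded <- any(dmat < 2)
    }
    if (crowded) {
      warning("some synthetic cells are closer than 2 px; footprints overlap")
    }
    structure(
      list(cells = cells, params = params, noise_sd = noise_sd,
           drift_rate = drift_rate, artifact_jump = artifact_jump,
           artifact_frame = as.integer(artifact_frame),
           crowded = crowded, seed = seed),
      class = "synthetic_well_truth"
    )
  })
}

# Footprint of one cell: bright centre pixel plus up to 3 of its 4-neighbours
# at 40% amplitude ("a single cell usually occupying 1-4 pixels").
cell_footprint <- function(row, col, n_extra) {
  nb <- rbind(c(-1, 0), c(0, 1), c(1, 0), c(0, -1))
  keep <- seq_len(n_extra)
  rbind(
    data.frame(row = row, col = col, weight = 1),
    if (n_extra > 0) {
      data.frame(row = row + nb[keep, 1], col = col + nb[keep, 2],
                 weight = 0.4)
    }
  )
}

#' Synthesize one well's wavelength-shift video
#'
#' Renders each truth cell as a compact 1-4 px spatial peak whose
#' centre-pixel time course equals its kinetic curve, then overlays the
#' well-level nuisance terms every real recording carries: linear baseline
#' drift, a common injection-artifact step at the cell-addition frame, and
#' i.i.d. Gaussian sensor noise.
#'
#' @param truth a [synthetic_well_truth()].
#' @param times minutes vector from [time_grid()].
#' @param well_id,measurement_id identifiers stamped on the video.
#' @param seed seed for the noise stream (the truth object fixes everything
#'   else).
#' @return list with `video` ([ws_video()]) and `truth`.
#' @export
synthesize_well_video <- function(truth, times, well_id = "A1",
                                  measurement_id = "M1", seed = 1L) {
  check_that(inherits(truth, "synthetic_well_truth"),
             "truth must come from synthetic_well_truth()")
  tt <- length(times)
  vals <- array(0, c(SENSOR_PX, SENSOR_PX, tt))
  n_cells <- nrow(truth$cells)
  fp_sizes <- with_seed(truth$seed + 1L,
                        sample(0:3, max(n_cells, 1), replace = TRUE))
  for (i in seq_len(n_cells)) {
    curve <- render_cell_curve(truth$params[[i]], times)
    fp <- cell_footprint(truth$cells$row[i], truth$cells$col[i], fp_sizes[i])
    for (j in seq_len(nrow(fp))) {
      r <- fp$row[j] + 1L; c <- fp$col[j] + 1L
      vals[r, c, ] <- pmax(vals[r, c, ], fp$weight[j] * curve)
    }
  }
  common <- truth$drift_rate * times
  if (truth$artifact_jump != 0) {
    common <- common + truth$artifact_jump *
      (seq_len(tt) >= truth$artifact_frame)
  }
  vals <- vals + rep(common, each = SENSOR_PX * SENSOR_PX)
  if (truth$noise_sd > 0) {
    vals <- vals + with_seed(seed, array(
      stats::rnorm(length(vals), 0, truth$noise_sd), dim(vals)))
  }
  list(video = ws_video(vals, times, well_id, measurement_id),
       truth = truth)
}

#' Write a truth sidecar table
#'
#' Plain tab-delimited table (cell, row, col, class, amplitude) matching
#' the container written next to it.
#'
#' @param truth a [synthetic_well_truth()].
#' @param path output TSV path.
#' @export
write_truth_sidecar <- function(truth, path) {
  utils::write.table(truth$cells, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Generate a labeled single-cell signal collection directly
#'
#' Fast path that bypasses the imaging stage: draws kinetic parameters per
#' class, renders curves, adds per-signal Gaussian noise, and assigns
#' synthetic batch (measurement) ids round-robin. Signals are exact maxWS
#' analogues of what the sensor pipeline would extract from noiseless
#' wells.
#'
#' @param n_per_class named integer vector, cells per class; names must
#'   match `class_specs`.
#' @param class_specs named list of [class_kinetic_spec()].
#' @param times minutes vector from [time_grid()].
#' @param noise_sd per-sample additive Gaussian noise sd, pm.
#' @param n_batches number of synthetic measurement batches.
#' @param seed integer seed; the output is a pure function of the inputs.
#' @return object of class `cell_records`: list with `signals` (N x T
#'   matrix, pm), `labels`, `batch_ids`, `times`, `params`.
#' @export
generate_labeled_dataset <- function(n_per_class, class_specs, times,
                                     noise_sd = 0, n_batches = 3L,
                                     seed = 1L) {
  check_that(!is.null(names(n_per_class)) && all(nzchar(names(n_per_class))),
             "n_per_class must be a named vector")
  unknown <- setdiff(names(n_per_class), names(class_specs))
  check_that(length(unknown) == 0,
             sprintf("unknown class name(s): %s", paste(unknown, collapse = ", ")))
  check_that(all(n_per_class >= 1), "counts must be >= 1")
  with_seed(seed, {
    n_total <- sum(n_per_class)
    signals <- matrix(0, n_total, length(times))
    labels <- character(n_total)
    params <- vector("list", n_total)
    i <- 0L
    for (cl in names(n_per_class)) {
      for (k in seq_len(n_per_class[[cl]])) {
        i <- i + 1L
        p <- sample_kinetic_params(class_specs[[cl]])
        s <- render_cell_curve(p, times)
        if (noise_sd > 0) s <- s + stats::rnorm(length(s), 0, noise_sd)
        signals[i, ] <- s
        labels[i] <- cl
        params[[i]] <- p
      }
    }
    batch_ids <- sprintf("B%02d", (seq_len(n_total) - 1L) %% n_batches + 1L)
    cell_records(signals, labels, batch_ids, times, params)
  })
}

#' Construct a cell-record collection
#'
#' @param signals N x T matrix of maxWS values, pm.
#' @param labels length-N class labels (or NA).
#' @param batch_ids length-N measurement/batch identifiers.
#' @param times minutes vector of length T.
#' @param params optional per-cell metadata list.
#' @return object of class `cell_records`.
#' @export
cell_records <- function(signals, labels, batch_ids, times, params = NULL) {
  signals <- as.matrix(signals)
  check_that(length(labels) == nrow(signals), "labels length mismatch")
  check_that(length(batch_ids) == nrow(signals), "batch_ids length mismatch")
  check_that(length(times) == ncol(signals), "times length mismatch")
  structure(
    list(signals = signals, labels = as.character(labels),
         batch_ids = as.character(batch_ids), times = as.numeric(times),
         params = params),
    class = "cell_records"
  )
}

#' @export
print.cell_records <- function(x, ...) {
  cat(sprintf("<cell_records> %d cells x %d timesteps (%.1f min)\n",
              nrow(x$signals), ncol(x$signals), max(x$times)))
  if (any(!is.na(x$labels))) print(table(x$labels))
  invisible(x)
}
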