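#' Zero-offset a single-cell signal
#'
#' Subtracts the first measured value from the whole signal, pushing the
#' start to zero while preserving all differences. Idempotent.
#'
#' @param signal numeric pm vector, or an N x T matrix (row-wise).
#' @return same shape as the input.
#' @export
zero_offset <- function(signal) {
  if (is.matrix(signal)) {
    check_that(ncol(signal) >= 1, "signals must be non-empty")
    return(signal - signal[, 1])
  }
  check_that(length(signal) >= 1, "signal must be non-empty")
  signal - signal[1]
}

#' Remove per-measurement injection artifacts from cell records
#'
#' Adding the cell suspension introduces a measurement-specific additive
#' artifact (buffer temperature/consistency mismatch). Given one artifact
#' estimate per measurement id — typically the post-injection step seen on
#' background pixels — the common additive term is subtracted from every
#' signal of that measurement.
#'
#' @param records a [cell_records()].
#' @param artifact_estimates named numeric vector, pm per measurement id.
#' @return corrected [cell_records()].
#' @export
correct_batch_artifact <- function(records, artifact_estimates) {
  check_that(inherits(records, "cell_records"), "records must be cell_records")
  missing_ids <- setdiff(unique(records$batch_ids), names(artifact_estimates))
  check_that(length(missing_ids) == 0,
             sprintf("missing artifact estimate for measurement(s): %s",
                     paste(missing_ids, collapse = ", ")))
  out <- records
  out$signals <- records$signals - artifact_estimates[records$batch_ids]
  out
}

#' Estimate per-measurement injection artifacts from background pixels
#'
#' For each well the artifact is read off the background-pixel average of
#' the raw video: its value just after the injection frame minus just
#' before. Estimates of wells belonging to one measurement are averaged.
#'
#' @param videos list of raw [ws_video()] objects.
#' @param masks list of logical background masks (from
#'   [global_background_correct()]), parallel to `videos`.
#' @param artifact_frame 1-based injection frame index.
#' @return named numeric vector, pm per measurement id.
#' @export
estimate_batch_artifacts <- function(videos, masks, artifact_frame) {
  check_that(artifact_frame >= 2, "need at least one pre-injection frame")
  est <- vapply(seq_along(videos), function(i) {
    d <- dim(videos[[i]]$values)
    flat <- matrix(videos[[i]]$values, d[1] * d[2], d[3])
    bg <- colMeans(flat[as.vector(masks[[i]]), , drop = FALSE])
    bg[artifact_frame] - bg[artifact_frame - 1]
  }, numeric(1))
  ids <- vapply(videos, function(v) v$measurement_id, character(1))
  tapply(est, ids, mean)
}

#' Cut signals to a uniform length
#'
#' Truncates every record to the first `duration_min` minutes after cell
#' addition. Records too short to cover the duration are dropped (never
#' padded) with a logged count.
#'
#' @param records a [cell_records()].
#' @param duration_min one of the standard 30/60/90/120/150-min variants
#'   (other values allowed).
#' @param delta_t_s frame period in seconds; defaults to the spacing of the
#'   record time axis.
#' @return object of class `signal_dataset` with fields `X` (N x L matrix),
#'   `y`, `batch_ids`, `length_variant`, `delta_t_s`, `standardization`
#'   (NULL until [standardize_datasets()]).
#' @export
cut_to_length <- function(records, duration_min, delta_t_s = NULL) {
  check_that(inherits(records, "cell_records"), "records must be cell_records")
  if (is.null(delta_t_s)) {
    check_that(length(records$times) >= 2, "cannot infer frame period")
    delta_t_s <- (records$times[2] - records$times[1]) * 60
  }
  L <- floor(duration_min * 60 / delta_t_s)
  check_that(L >= 1, "duration shorter than one frame period")
  n_avail <- ncol(records$signals)
  if (n_avail < L) {
    message(sprintf("cut_to_length: all %d records shorter than %d min; none kept",
                    nrow(records$signals), duration_min))
    X <- records$signals[integer(0), , drop = FALSE]
    return(signal_dataset(X[, integer(0), drop = FALSE], character(0),
                          character(0), duration_min, delta_t_s))
  }
  signal_dataset(records$signals[, seq_len(L), drop = FALSE],
                 records$labels, records$batch_ids, duration_min, delta_t_s)
}

#' Construct a signal dataset
#'
#' @param X N x L matrix of signal values (pm, or standardized).
#' @param y length-N class labels.
#' @param batch_ids length-N measurement ids.
#' @param length_variant nominal duration, minutes.
#' @param delta_t_s frame period, seconds.
#' @param standardization NULL or `list(mean=, sd=)`.
#' @return object of class `signal_dataset`.
#' @export
signal_dataset <- function(X, y, batch_ids, length_variant, delta_t_s,
                           standardization = NULL) {
  X <- as.matrix(X)
  check_that(!anyNA(X), "dataset must not contain missing values")
  check_that(length(y) == nrow(X), "label length mismatch")
  structure(
    list(X = X, y = as.character(y), batch_ids = as.character(batch_ids),
         length_variant = length_variant, delta_t_s = delta_t_s,
         standardization = standardization),
    class = "signal_dataset"
  )
}

#' @export
print.signal_dataset <- function(x, ...) {
  cat(sprintf("<signal_dataset> %d signals x %d samples (%g min at %g s)%s\n",
              nrow(x$X), ncol(x$X), x$length_variant, x$delta_t_s,
              if (is.null(x$standardization)) "" else ", standardized"))
  if (length(x$y)) print(table(x$y))
  invisible(x)
}

#' Stratified k-fold split
#'
#' Shuffles each class independently (seeded) and deals its members to the
#' k folds round-robin, so every fold's per-class count differs from the
#' exact proportional share by at most one sample. With k = 5 each test
#' fold holds ~20% of the data, the complement ~80%.
#'
#' @param y class labels.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return object of class `fold_split`: `assignments` (fold index per
#'   sample) and `folds` (list of `list(train=, test=)` index vectors).
#' @export
stratified_kfold_split <- function(y, k = 5L, seed = 1L) {
  check_that(k >= 2, "k must be >= 2 (k = 1 allows no rotation)")
  y <- as.character(y)
  counts <- table(y)
  small <- names(counts)[counts < k]
  check_that(length(small) == 0,
             sprintf("class(es) smaller than k: %s", paste(small, collapse = ", ")))
  assignments <- integer(length(y))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(y == cl)
      idx <- idx[sample(length(idx))]
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    list(train = which(assignments != f), test = which(assignments == f))
  })
  structure(list(k = as.integer(k), assignments = assignments,
                 folds = folds, seed = seed),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d folds over %d samples\n",
              x$k, length(x$assignments)))
  invisible(x)
}

#' SMOTE oversampling of minority classes
#'
#' Balances the training portion so every class matches the majority-class
#' count. Each synthetic sample is a convex combination
#' `x = (1 - lambda) * a + lambda * b` of a minority sample `a` and one of
#' its k nearest same-class neighbours `b` (Euclidean distance on the
#' full-length signal vectors), with a single `lambda ~ U(0, 1)` applied to
#' all timesteps so the kinetic shape is preserved. Provenance (base index,
#' neighbour index, lambda) is returned for every synthetic row.
#'
#' @param X N x L training signal matrix.
#' @param y length-N training labels.
#' @param k_neighbors number of nearest neighbours considered (default 5).
#' @param seed integer seed.
#' @return list with balanced `X`, `y`, and `provenance` (data.frame
#'   `base`, `neighbor`, `lambda`, `class`; indices into the input rows).
#' @export
smote_oversample <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  counts <- table(y)
  singleton <- names(counts)[counts < 2]
  check_that(length(singleton) == 0,
             sprintf("cannot SMOTE singleton class(es): %s",
                     paste(singleton, collapse = ", ")))
  target <- max(counts)
  new_X <- list(); new_y <- list()
  prov <- data.frame(base = integer(0), neighbor = integer(0),
                     lambda = numeric(0), class = character(0))
  with_seed(seed, {
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need == 0) next
      idx <- which(y == cl)
      Xc <- X[idx, , drop = FALSE]
      k_eff <- min(k_neighbors, length(idx) - 1L)
      dm <- as.matrix(stats::dist(Xc))
      diag(dm) <- Inf
      nn <- t(apply(dm, 1, function(dr) order(dr)[seq_len(k_eff)]))
      base_pick <- sample(length(idx), need, replace = TRUE)
      nb_pick <- vapply(base_pick, function(b) {
        nn[b, sample(k_eff, 1)]
      }, integer(1))
      lam <- stats::runif(need)
      syn <- (1 - lam) * Xc[base_pick, , drop = FALSE] +
        lam * Xc[nb_pick, , drop = FALSE]
      new_X[[cl]] <- syn
      new_y[[cl]] <- rep(cl, need)
      prov <- rbind(prov, data.frame(base = idx[base_pick],
                                     neighbor = idx[nb_pick],
                                     lambda = lam, class = cl))
    }
  })
  list(X = rbind(X, do.call(rbind, new_X)),
       y = c(y, unlist(new_y, use.names = FALSE)),
       provenance = prov)
}

#' Standardize datasets with training-set statistics
#'
#' Computes the global scalar mean and standard deviation over all values
#' of the training matrix and applies the same affine transform to the
#' training set and to every other dataset supplied, so no test statistic
#' leaks into the transform.
#'
#' @param train_X training matrix.
#' @param ... further matrices to transform with the training statistics.
#' @return list with `train` (standardized), `others` (list), `mean`, `sd`.
#' @export
standardize_signals <- function(train_X, ...) {
  train_X <- as.matrix(train_X)
  mu <- mean(train_X)
  sd_ <- stats::sd(as.vector(train_X))
  check_that(is.finite(sd_) && sd_ > 0,
             "training set has zero variance; cannot standardize")
  others <- lapply(list(...), function(m) (as.matrix(m) - mu) / sd_)
  list(train = (train_X - mu) / sd_, others = others, mean = mu, sd = sd_)
}

#' Apply a label-combination map (e.g. merge breast-cancer lines)
#'
#' @param y labels.
#' @param combine named list mapping new label -> character vector of old
#'   labels, e.g. `list("Breastcancer" = c("MDA-MB-231", "MCF-7"))`.
#' @return relabeled character vector.
#' @export
combine_classes <- function(y, combine) {
  y <- as.character(y)
  for (new_lab in names(combine)) {
    y[y %in% combine[[new_lab]]] <- new_lab
  }
  y
}
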