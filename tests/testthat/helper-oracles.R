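# Independent brute-force oracles used by both the unit and the
# acceptance suites. Deliberately written as plain per-pixel loops so they
# share no code with the vectorized production path.

# 8-neighbourhood local-maxima scan; strict inequality, plateau ties to the
# smallest (row, col) lexicographic rank. 0-based output sorted by
# descending amplitude.
brute_force_maxima <- function(frame, threshold) {
  nr <- nrow(frame); nc <- ncol(frame)
  rank_of <- function(r, c) (r - 1) * nc + (c - 1)
  out <- data.frame(row = integer(0), col = integer(0),
                    amplitude = numeric(0))
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      v <- frame[r, c]
      if (v < threshold) next
      ok <- TRUE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr; cc <- c + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          nv <- frame[rr, cc]
          if (nv > v || (nv == v && rank_of(rr, cc) < rank_of(r, c))) {
            ok <- FALSE
          }
        }
      }
      if (ok) {
        out <- rbind(out, data.frame(row = r - 1L, col = c - 1L,
                                     amplitude = v))
      }
    }
  }
  out[order(-out$amplitude, out$row, out$col), , drop = FALSE]
}

# Nearest-peak label per pixel by explicit loop; which.min resolves
# equidistant ties to the lowest peak index.
brute_force_voronoi <- function(peaks_df, nr, nc) {
  lab <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      d2 <- (peaks_df$row - (r - 1))^2 + (peaks_df$col - (c - 1))^2
      lab[r, c] <- which.min(d2)
    }
  }
  lab
}

# Wrap a single frame as a one-frame video.
frame_video <- function(frame) {
  ws_video(array(frame, c(nrow(frame), ncol(frame), 1)), 0)
}

# Small smooth conv net (CNN: sigmoid activations, no batch norm) trained
# on two separated classes; keeps finite-difference comparisons clean of
# ReLU kinks. Shared by the grad-CAM unit and acceptance tests.
tiny_conv_fit <- function() {
  memo("tiny_conv_fit", function() {
    specs <- separated_specs()[c("A", "D")]
    tg <- time_grid(30, 9)
    rec <- generate_labeled_dataset(c(A = 40L, D = 40L), specs, tg,
                                    noise_sd = 10, seed = 81)
    ds <- cut_to_length(rec, 30, 9)
    std <- standardize_signals(ds$X)
    m <- build_model("CNN", ncol(ds$X), 2, seed = 82)
    cfg <- train_config("CNN", epochs = 15, learning_rate = 1e-3,
                        early_stopping_patience = Inf, seed = 83)
    m <- train_model(m, list(X = std$train, y = ds$y),
                     list(X = std$train, y = ds$y), cfg)
    list(model = m, X = std$train, y = ds$y)
  })
}
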