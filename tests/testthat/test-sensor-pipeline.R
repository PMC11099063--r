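# Oracles live in helper-oracles.R.

test_that("peak detection matches the exhaustive neighbourhood oracle", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(c(12, 20), 1)
    frame <- matrix(rnorm(n * n, mean = 30, sd = 40), n, n)
    # inject plateaus to exercise the tie rule
    if (i %% 3 == 0) {
      r <- sample(n - 1, 1); c <- sample(n - 1, 1)
      frame[r:(r + 1), c:(c + 1)] <- max(frame) + 5
    }
    got <- detect_cell_peaks(frame_video(frame), threshold = 50,
                             min_distance = 0)$peaks
    want <- brute_force_maxima(frame, 50)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("threshold separates planted peaks and flat frames yield none", {
  frame <- matrix(0, 40, 40)
  frame[10 + 1, 10 + 1] <- 300
  frame[20 + 1, 30 + 1] <- 150
  frame[35 + 1, 5 + 1] <- 40
  ps <- detect_cell_peaks(frame_video(frame), threshold = 75)
  expect_equal(nrow(ps$peaks), 2)
  expect_equal(ps$peaks$row, c(10, 20))
  expect_equal(ps$peaks$col, c(10, 30))
  expect_equal(ps$peaks$amplitude, c(300, 150))
  empty <- detect_cell_peaks(frame_video(matrix(0, 20, 20)), threshold = 75)
  expect_equal(nrow(empty$peaks), 0)
})

test_that("greedy min-distance suppression keeps the stronger peak", {
  frame <- matrix(0, 20, 20)
  frame[5, 5] <- 200
  frame[5, 7] <- 180 # 2 px away: suppressed at min_distance > 2
  ps <- detect_cell_peaks(frame_video(frame), threshold = 50,
                          min_distance = 3)
  expect_equal(nrow(ps$peaks), 1)
  expect_equal(ps$peaks$amplitude, 200)
  ps2 <- detect_cell_peaks(frame_video(frame), threshold = 50,
                           min_distance = 2)
  expect_equal(nrow(ps2$peaks), 2)
})

test_that("Voronoi partition matches brute force, including tie cases", {
  set.seed(22)
  for (i in 1:15) {
    np <- sample(2:12, 1)
    pk <- data.frame(row = sample(0:19, np), col = sample(0:19, np),
                     amplitude = sort(runif(np, 100, 500), decreasing = TRUE))
    ps <- structure(list(peaks = pk, detection_threshold = 75,
                         min_distance = 0, detection_frame = "last"),
                    class = "peak_set")
    rois <- assign_voronoi_rois(ps, c(20, 20))
    expect_equal(rois$labels, brute_force_voronoi(pk, 20, 20))
  }
  # explicit equidistant tie: pixel (0, 5) between peaks at (0,0) and (0,10)
  pk <- data.frame(row = c(0, 0), col = c(0, 10), amplitude = c(2, 1))
  ps <- structure(list(peaks = pk, detection_threshold = 1,
                       min_distance = 0, detection_frame = "last"),
                  class = "peak_set")
  rois <- assign_voronoi_rois(ps, c(3, 11))
  expect_equal(rois$labels[1, 6], 1L) # lower index wins
  # single peak claims every pixel
  ps1 <- structure(list(peaks = pk[1, ], detection_threshold = 1,
                        min_distance = 0, detection_frame = "last"),
                   class = "peak_set")
  expect_true(all(assign_voronoi_rois(ps1, c(80, 80))$labels == 1L))
  # every region contains its own generating peak
  rois2 <- assign_voronoi_rois(ps, c(3, 11))
  expect_equal(rois2$labels[1, 1], 1L)
  expect_equal(rois2$labels[1, 11], 2L)
})

test_that("maxWS extraction equals per-frame brute force over ROI pixels", {
  set.seed(23)
  tt <- 5
  vid <- ws_video(array(rnorm(20 * 20 * tt, 50, 30), c(20, 20, tt)),
                  seq(0, by = 0.15, length.out = tt))
  pk <- data.frame(row = c(3, 15), col = c(4, 12),
                   amplitude = c(400, 300))
  ps <- structure(list(peaks = pk, detection_threshold = 75,
                       min_distance = 0, detection_frame = "last"),
                  class = "peak_set")
  rois <- assign_voronoi_rois(ps, c(20, 20))
  rec <- extract_max_ws(vid, rois, ps)
  for (k in 1:2) {
    for (f in seq_len(tt)) {
      px <- which(rois$labels == k, arr.ind = TRUE)
      want <- max(vid$values[cbind(px, f)])
      expect_identical(rec$signals[k, f], want)
    }
  }
  # ROI max always >= the peak pixel's own value
  for (k in 1:2) {
    peak_trace <- vid$values[pk$row[k] + 1, pk$col[k] + 1, ]
    expect_true(all(rec$signals[k, ] >= peak_trace))
  }
})

test_that("background correction zeroes common drift and is shift invariant", {
  tg <- time_grid(60, 9)
  specs <- conservation_spec()
  # pure drift, no cells -> identically zero after correction
  drift <- 0.4 * tg
  vid <- ws_video(array(rep(drift, each = 80 * 80), c(80, 80, length(tg))),
                  tg)
  out <- global_background_correct(vid, 75)
  expect_lt(max(abs(out$video$values)), 1e-9)
  expect_true(all(out$background_mask))
  # with cells + drift: endpoint equals the planted amplitude
  truth <- synthetic_well_truth(10, specs, drift_rate = 0.5,
                                artifact_jump = 15, seed = 31)
  wv <- synthesize_well_video(truth, time_grid(150, 9), seed = 31)
  res <- sensor_pipeline(wv$video, threshold = 75)
  expect_equal(sort(res$records$signals[, ncol(res$records$signals)]),
               sort(truth$cells$amplitude), tolerance = 1e-9)
  # adding a constant offset changes nothing after correction
  vid2 <- wv$video
  vid2$values <- vid2$values + 37.5
  res2 <- sensor_pipeline(vid2, threshold = 75)
  expect_equal(res2$records$signals, res$records$signals, tolerance = 1e-9)
  # a video where every pixel transiently spikes above the per-frame
  # median leaves no background pixels: the correction must refuse
  vals <- array(0, c(10, 10, 3))
  vals[, 1:5, 2] <- 100 # half the pixels spike at frame 2
  vals[, 6:10, 3] <- 100 # the other half at frame 3
  expect_error(global_background_correct(ws_video(vals, c(0, 0.15, 0.3)), 10),
               "background")
})

test_that("noiseless end-to-end recovery finds exactly the supra-threshold cells", {
  tg <- time_grid(150, 9)
  specs <- conservation_spec()
  truth <- synthetic_well_truth(20, specs, seed = 33)
  wv <- synthesize_well_video(truth, tg, seed = 33)
  res <- sensor_pipeline(wv$video, threshold = 75)
  pk <- res$peaks$peaks
  expect_equal(nrow(pk), nrow(truth$cells))
  m <- merge(pk, truth$cells, by = c("row", "col"))
  expect_equal(nrow(m), nrow(truth$cells)) # zero position error
  expect_equal(sort(res$records$signals[, length(tg)]),
               sort(truth$cells$amplitude), tolerance = 1e-6 / 600)
  # sub-threshold cells are absent from detection
  res_hi <- sensor_pipeline(wv$video, threshold = 700)
  expect_equal(nrow(res_hi$peaks$peaks), sum(truth$cells$amplitude >= 700))
})
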