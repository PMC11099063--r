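test_that("zero offset is exact, difference preserving and idempotent", {
  expect_equal(zero_offset(c(12.5, 20, 30)), c(0, 7.5, 17.5))
  expect_equal(zero_offset(rep(4.2, 10)), rep(0, 10))
  x <- cumsum(rnorm(50))
  expect_equal(zero_offset(zero_offset(x)), zero_offset(x))
  expect_equal(diff(zero_offset(x)), diff(x))
  m <- matrix(c(1, 2, 3, 10, 20, 30), 2, byrow = TRUE)
  expect_equal(zero_offset(m), matrix(c(0, 1, 2, 0, 10, 20), 2, byrow = TRUE))
  expect_error(zero_offset(numeric(0)), "non-empty")
})

test_that("batch-artifact correction recovers pre-artifact truth", {
  specs <- separated_specs()
  tg <- time_grid(30, 9)
  clean <- generate_labeled_dataset(c(A = 10L, C = 10L), specs, tg,
                                    n_batches = 2L, seed = 41)
  shifted <- clean
  art <- c(B01 = 15, B02 = -5)
  shifted$signals <- clean$signals + art[clean$batch_ids]
  fixed <- correct_batch_artifact(shifted, art)
  expect_equal(fixed$signals, clean$signals, tolerance = 1e-12)
  # zero artifact is the identity
  same <- correct_batch_artifact(clean, c(B01 = 0, B02 = 0))
  expect_equal(same$signals, clean$signals)
  # between-batch endpoint difference shrinks to the truth difference
  ep_shift <- tapply(shifted$signals[, ncol(shifted$signals)],
                     shifted$batch_ids, mean)
  ep_fixed <- tapply(fixed$signals[, ncol(fixed$signals)],
                     fixed$batch_ids, mean)
  ep_clean <- tapply(clean$signals[, ncol(clean$signals)],
                     clean$batch_ids, mean)
  expect_equal(diff(ep_fixed), diff(ep_clean), tolerance = 1e-12)
  expect_gt(abs(diff(ep_shift) - diff(ep_clean)), 10)
  expect_error(correct_batch_artifact(clean, c(B01 = 1)), "B02")
})

test_that("artifact estimates from background pixels match the planted jumps", {
  tg <- time_grid(30, 9)
  specs <- conservation_spec()
  jumps <- c(M1 = 18, M2 = 7)
  videos <- list(); masks <- list()
  for (i in 1:2) {
    truth <- synthetic_well_truth(8, specs, artifact_jump = jumps[i],
                                  artifact_frame = 5, seed = 50 + i)
    wv <- synthesize_well_video(truth, tg, measurement_id = names(jumps)[i],
                                seed = 50 + i)
    bg <- global_background_correct(wv$video, 75)
    videos[[i]] <- wv$video
    masks[[i]] <- bg$background_mask
  }
  est <- estimate_batch_artifacts(videos, masks, artifact_frame = 5)
  expect_equal(as.numeric(est[names(jumps)]), as.numeric(jumps),
               tolerance = 1e-9)
})

test_that("length cuts follow L = floor(duration*60/delta_t)", {
  specs <- separated_specs()
  rec <- generate_labeled_dataset(c(A = 4L), specs, time_grid(150, 9),
                                  seed = 42)
  expect_equal(ncol(cut_to_length(rec, 30, 9)$X), 200)
  expect_equal(ncol(cut_to_length(rec, 150, 9)$X), 1000)
  expect_equal(ncol(cut_to_length(rec, 60, 12)$X), 300)
  # a record of exactly L samples passes through unchanged
  rec200 <- cell_records(rec$signals[, 1:200], rec$labels, rec$batch_ids,
                         rec$times[1:200])
  expect_equal(cut_to_length(rec200, 30, 9)$X, rec$signals[, 1:200])
  # shorter records are dropped with a message, never padded
  expect_message(out <- cut_to_length(rec200, 60, 9), "none kept")
  expect_equal(nrow(out$X), 0)
})

test_that("stratified folds are disjoint, covering and balanced within one", {
  set.seed(43)
  y <- rep(c("a", "b"), c(60, 40))[sample(100)]
  fs <- stratified_kfold_split(y, k = 5, seed = 7)
  tests <- lapply(fs$folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100)
  expect_equal(sum(vapply(tests, length, integer(1))), 100)
  for (f in 1:5) {
    expect_equal(sum(y[tests[[f]]] == "a"), 12)
    expect_equal(sum(y[tests[[f]]] == "b"), 8)
    expect_length(intersect(fs$folds[[f]]$train, tests[[f]]), 0)
    # ~80-20 split
    expect_equal(length(fs$folds[[f]]$train), 80)
  }
  # determinism
  fs2 <- stratified_kfold_split(y, k = 5, seed = 7)
  expect_identical(fs$assignments, fs2$assignments)
  # uneven counts stay within +-1 per class per fold
  y2 <- rep(c("a", "b", "c"), c(23, 17, 11))
  fs3 <- stratified_kfold_split(y2, k = 5, seed = 1)
  for (cl in c("a", "b", "c")) {
    per_fold <- table(fs3$assignments[y2 == cl])
    expect_lte(diff(range(per_fold)), 1)
  }
  expect_error(stratified_kfold_split(y, k = 1), "rotation")
  expect_error(stratified_kfold_split(c("a", "a", "b"), k = 3), "b")
})

test_that("SMOTE balances to the majority count with convex synthetic rows", {
  set.seed(44)
  X <- rbind(matrix(rnorm(10 * 20, 0), 10),
             matrix(rnorm(4 * 20, 5), 4))
  y <- rep(c("A", "B"), c(10, 4))
  out <- smote_oversample(X, y, k_neighbors = 5, seed = 9)
  expect_equal(as.vector(table(out$y)[c("A", "B")]), c(10L, 10L))
  expect_equal(nrow(out$provenance), 6)
  expect_true(all(out$provenance$class == "B"))
  # convexity: synthetic rows reproduce from provenance exactly and lie
  # pointwise between their endpoints
  syn <- out$X[15:20, , drop = FALSE]
  for (i in 1:6) {
    pr <- out$provenance[i, ]
    want <- (1 - pr$lambda) * X[pr$base, ] + pr$lambda * X[pr$neighbor, ]
    expect_equal(syn[i, ], want, tolerance = 1e-12)
    lo <- pmin(X[pr$base, ], X[pr$neighbor, ])
    hi <- pmax(X[pr$base, ], X[pr$neighbor, ])
    expect_true(all(syn[i, ] >= lo - 1e-12 & syn[i, ] <= hi + 1e-12))
    # neighbours are same-class originals
    expect_gte(pr$neighbor, 11)
  }
  # original rows pass through untouched
  expect_identical(out$X[1:14, ], X)
  # already-balanced input is returned as-is
  bal <- smote_oversample(X[c(1:4, 11:14), ], rep(c("A", "B"), each = 4),
                          seed = 9)
  expect_equal(nrow(bal$X), 8)
  expect_equal(nrow(bal$provenance), 0)
  expect_error(smote_oversample(X, rep(c("A", "B"), c(13, 1)), seed = 1),
               "singleton")
})

test_that("standardization uses train statistics only and round-trips", {
  set.seed(45)
  tr <- matrix(rnorm(40 * 10, 200, 50), 40)
  te <- matrix(rnorm(20 * 10, 300, 80), 20)
  out <- standardize_signals(tr, te)
  expect_equal(mean(out$train), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(out$train)), 1, tolerance = 1e-12)
  # identical test set standardizes identically
  out2 <- standardize_signals(tr, tr)
  expect_equal(out2$others[[1]], out2$train)
  # inverse transform recovers originals
  back <- out$others[[1]] * out$sd + out$mean
  expect_equal(back, te, tolerance = 1e-10)
  expect_error(standardize_signals(matrix(5, 3, 4)), "variance")
})

test_that("class combination maps merge labels before splitting", {
  y <- c("MDA-MB-231", "MCF-7", "HeLa", "MCF-7")
  out <- combine_classes(y, list(Breastcancer = c("MDA-MB-231", "MCF-7")))
  expect_equal(out, c("Breastcancer", "Breastcancer", "HeLa", "Breastcancer"))
})
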