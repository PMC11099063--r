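tiny_config <- function(...) {
  experiment_config(utils::modifyList(list(
    seed = 11L,
    n_per_class = c(HeLa = 12L, `MC3T3-E1` = 12L),
    lengths = 30,
    duration_min = 30,
    models = "MCDCNN",
    k_folds = 3L,
    train = list(epochs = 2L, early_stopping_patience = Inf)
  ), list(...)))
}

test_that("experiments are deterministic and validated before compute", {
  r1 <- run_experiment(tiny_config())
  r2 <- run_experiment(tiny_config())
  expect_equal(r1$comparison, r2$comparison, tolerance = 1e-12)
  expect_identical(r1$cv$MCDCNN$`30`$pooled$confusion,
                   r2$cv$MCDCNN$`30`$pooled$confusion)
  # invalid model name rejected at config time, before any compute
  expect_error(experiment_config(list(models = "lstm")), "unknown model")
  expect_error(experiment_config(list(lengths = 60, duration_min = 30)),
               "exceed")
})

test_that("accuracy-vs-length tables carry one row per model and length", {
  res <- run_experiment(tiny_config(lengths = c(15, 30)))
  expect_equal(nrow(res$comparison), 2)
  expect_setequal(res$comparison$length_min, c(15, 30))
  expect_true(res$comparison$best[1])
  expect_equal(res$comparison$accuracy_mean[1],
               max(res$comparison$accuracy_mean))
})

test_that("well-imaging source recovers labeled cells end to end", {
  res <- run_experiment(tiny_config(
    source = "wells", n_wells = 2L, cells_per_well = 25L,
    noise_sd = 2, n_per_class = c(HeLa = 1L, `MDA-MB-231` = 1L),
    duration_min = 90, detection_threshold = 60))
  expect_gt(nrow(res$records$signals), 20)
  expect_setequal(unique(res$records$labels),
                  c("HeLa", "MDA-MB-231"))
  # zero-offset applied: every extracted signal starts at 0
  expect_equal(max(abs(res$records$signals[, 1])), 0)
})

test_that("label merges shrink the class set before splitting", {
  res <- run_experiment(tiny_config(
    n_per_class = c(`MDA-MB-231` = 8L, `MCF-7` = 8L, HeLa = 8L),
    combine = list(Breastcancer = c("MDA-MB-231", "MCF-7")),
    k_folds = 2L))
  expect_setequal(res$manifest$classes, c("Breastcancer", "HeLa"))
  expect_equal(sum(res$records$labels == "Breastcancer"), 16)
})

test_that("model ranking recomputes from per-fold values and sorts by accuracy", {
  res <- run_experiment(tiny_config(lengths = c(15, 30), k_folds = 3L))
  bundles <- unlist(res$cv, recursive = FALSE)
  cmp <- compare_models(bundles)
  expect_equal(cmp$accuracy_mean, sort(cmp$accuracy_mean, decreasing = TRUE))
  for (i in seq_len(nrow(cmp))) {
    b <- bundles[[which(vapply(bundles, function(x) {
      x$length_variant == cmp$length_min[i]
    }, logical(1)))[1]]]
    expect_equal(cmp$accuracy_mean[i], mean(b$per_fold[, "accuracy"]),
                 tolerance = 1e-12)
    expect_equal(cmp$accuracy_sd[i], sd(b$per_fold[, "accuracy"]),
                 tolerance = 1e-12)
  }
  expect_error(compare_models(list()), "at least one")
})

test_that("result bundles are written to disk when out_dir is set", {
  out <- withr::local_tempdir()
  run_experiment(tiny_config(out_dir = out))
  expect_true(file.exists(file.path(out, "comparison.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "mcdcnn_30min_confusion.csv")))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 11L)
})
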