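test_that("kinetic parameter sampling respects spec bounds and determinism", {
  spec <- class_kinetic_spec("X", c(100, 500), onset_delay = c(10, 3),
                             rise_time = c(15, 4))
  # degenerate interval pins the amplitude
  degen <- class_kinetic_spec("X", c(100, 100))
  expect_equal(sample_kinetic_params(degen, seed = 1)$amplitude, 100)
  # determinism
  p1 <- sample_kinetic_params(spec, seed = 42)
  p2 <- sample_kinetic_params(spec, seed = 42)
  expect_identical(p1, p2)
  # exhaustive bound check over many draws
  set.seed(7)
  draws <- replicate(10000, sample_kinetic_params(spec), simplify = FALSE)
  amps <- vapply(draws, function(p) p$amplitude, numeric(1))
  expect_gte(min(amps), 100)
  expect_lte(max(amps), 500)
  expect_true(all(vapply(draws[1:200], function(p) {
    p$onset_delay >= 0 && p$rise_time > 0
  }, logical(1))))
  # invalid interval rejected
  expect_error(class_kinetic_spec("X", c(500, 100)), "low")
})

test_that("rendered curves are anchored, monotone to plateau, and causal", {
  tg <- time_grid(150, 9)
  p <- list(class_name = "X", amplitude = 400, onset_delay = 30,
            rise_time = 5, shape_exponent = 1, plateau_slope = 0)
  s <- render_cell_curve(p, tg)
  expect_identical(s[1], 0)
  # onset semantics: essentially flat before the onset delay
  expect_lt(max(s[tg < 30]), 0.05 * 400)
  # asymptote: reaches the amplitude with zero plateau slope
  expect_lt(abs(s[length(s)] - 400), 0.01 * 400)
  # monotone rise (no noise in the deterministic curve)
  expect_true(all(diff(s) >= -1e-9))
  # zero amplitude gives the zero curve
  p0 <- p; p0$amplitude <- 0
  expect_identical(render_cell_curve(p0, tg), numeric(length(tg)))
  # shape exponent does not break the onset anchoring
  for (m in c(0.3, 1, 4)) {
    pm_ <- p; pm_$shape_exponent <- m
    sm <- render_cell_curve(pm_, tg)
    expect_lt(max(sm[tg < 30]), 0.05 * 400)
  }
  expect_error(render_cell_curve(p, numeric(0)), "non-empty")
})

test_that("well synthesis plants exact peaks over drift, artifact and noise", {
  tg <- time_grid(60, 9)
  specs <- conservation_spec()
  # zero cells, zero nuisance -> all-zero video
  t0 <- synthetic_well_truth(0, specs, seed = 1)
  v0 <- synthesize_well_video(t0, tg, seed = 1)
  expect_true(all(v0$video$values == 0))
  # one cell, no nuisance: center pixel time course equals the curve
  t1 <- synthetic_well_truth(1, specs, seed = 2)
  v1 <- synthesize_well_video(t1, tg, seed = 2)
  curve <- render_cell_curve(t1$params[[1]], tg)
  r <- t1$cells$row[1] + 1; c <- t1$cells$col[1] + 1
  expect_equal(v1$video$values[r, c, ], curve, tolerance = 1e-12)
  expect_equal(max(v1$video$values[, , length(tg)]),
               curve[length(curve)], tolerance = 1e-12)
  # background pixel carries exactly drift + artifact
  t2 <- synthetic_well_truth(1, specs, drift_rate = 0.5, artifact_jump = 12,
                             artifact_frame = 3, seed = 3)
  v2 <- synthesize_well_video(t2, tg, seed = 3)
  bg_expect <- 0.5 * tg + 12 * (seq_along(tg) >= 3)
  expect_equal(v2$video$values[1, 1, ], bg_expect, tolerance = 1e-12)
})

test_that("direct dataset generation is labeled, counted and reproducible", {
  specs <- separated_specs()
  tg <- time_grid(30, 9)
  rec <- generate_labeled_dataset(c(A = 5L, B = 7L), specs, tg, seed = 5)
  expect_equal(nrow(rec$signals), 12)
  expect_equal(as.vector(table(rec$labels)[c("A", "B")]), c(5L, 7L))
  # byte-identical under the same seed
  rec2 <- generate_labeled_dataset(c(A = 5L, B = 7L), specs, tg, seed = 5)
  expect_identical(rec, rec2)
  # disjoint amplitude ranges yield non-overlapping endpoint distributions
  rec3 <- generate_labeled_dataset(c(A = 40L, E = 40L), specs,
                                   time_grid(90, 9), seed = 6)
  ep <- rec3$signals[, ncol(rec3$signals)]
  expect_lt(max(ep[rec3$labels == "A"]), min(ep[rec3$labels == "E"]))
  expect_error(generate_labeled_dataset(c(Zz = 3L), specs, tg, seed = 1),
               "unknown class")
})
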