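#' Build or load an experiment configuration
#'
#' An experiment config drives a full run: synthesize signals (directly or
#' through the imaging pipeline), build fixed-length datasets,
#' cross-validate the requested models, and report. Accepts a YAML file
#' path or a named list; missing fields take the defaults below.
#'
#' Fields: `seed`; `source` ("signals" for the direct generator, "wells"
#' to synthesize well videos and run the sensor pipeline); `n_per_class`
#' (named counts; with `source = "wells"`, cells are drawn per well
#' instead); `n_wells`, `cells_per_well`, `noise_sd`, `drift_rate`,
#' `detection_threshold`, `min_distance`; `lengths` (minutes, subset of
#' 30/60/90/120/150 by convention); `delta_t_s`; `models` (architecture
#' names); `combine` (label merge map, e.g. Breastcancer);
#' `train` (overrides for [train_config()]: epochs, batch_size,
#' learning_rate, early_stopping_patience); `k_folds`; `smote_k`;
#' `out_dir` (NULL = no files written).
#'
#' @param config named list or YAML path.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(config = list()) {
  if (is.character(config)) {
    check_that(file.exists(config), sprintf("no such config file: %s", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L,
    source = "signals",
    n_per_class = NULL,
    n_wells = 4L,
    cells_per_well = 60L,
    noise_sd = 5,
    drift_rate = 0.3,
    detection_threshold = 75,
    min_distance = 2,
    duration_min = 150,
    lengths = c(30, 60, 90, 120, 150),
    delta_t_s = 9,
    models = "MCDCNN",
    combine = NULL,
    train = list(),
    k_folds = 5L,
    smote_k = 5L,
    out_dir = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  check_that(cfg$source %in% c("signals", "wells"),
             "source must be 'signals' or 'wells'")
  canon <- c(mlp = "MLP", cnn = "CNN", fcn = "FCN", resnet = "ResNet",
             mcdcnn = "MCDCNN", inception = "Inception")
  bad <- setdiff(tolower(cfg$models), names(canon))
  check_that(length(bad) == 0,
             sprintf("unknown model name(s): %s", paste(bad, collapse = ", ")))
  cfg$models <- unname(canon[tolower(cfg$models)])
  check_that(all(cfg$lengths <= cfg$duration_min),
             "lengths must not exceed duration_min")
  structure(cfg, class = "experiment_config")
}

#' Run a configuration-driven end-to-end experiment
#'
#' Stages: (1) synthesize labeled signals — either directly, or by
#' rendering multi-well videos and recovering cells with the sensor
#' pipeline (peaks matched to ground truth within 1 px for labels);
#' (2) zero-offset and cut to each requested length; (3) stratified
#' k-fold cross-validation of every requested model on every length, with
#' per-fold SMOTE and train-statistics standardization; (4) an
#' accuracy-vs-length table across models. Each stage draws its seed from
#' the master seed via [split_seed()], so any stage can be reproduced in
#' isolation. With `out_dir` set, metrics JSON, confusion CSVs, the
#' comparison table and a manifest are written there.
#'
#' @param config an [experiment_config()], list, or YAML path.
#' @return object of class `experiment_result`: `records`, `datasets`
#'   (per length), `cv` (nested list model -> length -> `cv_report`),
#'   `comparison` (ranking data.frame), `manifest`.
#' @export
run_experiment <- function(config) {
  cfg <- if (inherits(config, "experiment_config")) {
    config
  } else {
    experiment_config(config)
  }
  specs <- default_class_specs()
  if (is.null(cfg$n_per_class)) {
    cfg$n_per_class <- stats::setNames(rep(60L, length(specs)), names(specs))
  }
  check_that(all(names(cfg$n_per_class) %in% names(specs)),
             "n_per_class names must be default class names")
  specs <- specs[names(cfg$n_per_class)]
  seeds <- split_seed(cfg$seed, 4L)
  times <- time_grid(cfg$duration_min, cfg$delta_t_s)

  records <- if (cfg$source == "signals") {
    generate_labeled_dataset(cfg$n_per_class, specs, times,
                             noise_sd = cfg$noise_sd, seed = seeds[1])
  } else {
    extract_from_synthetic_wells(cfg, specs, times, seeds[1])
  }

  sigs <- zero_offset(records$signals)
  labels <- records$labels
  if (!is.null(cfg$combine)) labels <- combine_classes(labels, cfg$combine)
  base_records <- cell_records(sigs, labels, records$batch_ids,
                               records$times)
  datasets <- lapply(cfg$lengths, function(len) {
    cut_to_length(base_records, len, cfg$delta_t_s)
  })
  names(datasets) <- as.character(cfg$lengths)

  cv <- list()
  for (mn in cfg$models) {
    cv[[mn]] <- list()
    for (li in seq_along(datasets)) {
      ds <- datasets[[li]]
      folds <- stratified_kfold_split(ds$y, cfg$k_folds, seed = seeds[2])
      tc <- do.call(train_config, c(list(model_name = mn, seed = seeds[3]),
                                    cfg$train))
      cv[[mn]][[names(datasets)[li]]] <-
        cross_validate(ds, folds, mn, tc, smote_k = cfg$smote_k)
    }
  }
  comparison <- compare_models(unlist(cv, recursive = FALSE))
  manifest <- list(
    seed = cfg$seed, stage_seeds = seeds, source = cfg$source,
    n_signals = nrow(base_records$signals),
    classes = sort(unique(labels)), lengths = cfg$lengths,
    models = cfg$models, timestamp = format(Sys.time(), tz = "UTC"))
  result <- structure(
    list(records = base_records, datasets = datasets, cv = cv,
         comparison = comparison, manifest = manifest, config = cfg),
    class = "experiment_result"
  )
  if (!is.null(cfg$out_dir)) write_experiment_result(result, cfg$out_dir)
  result
}

# Synthesize wells, run the extraction chain, and label recovered cells by
# nearest planted cell (within 1 px).
extract_from_synthetic_wells <- function(cfg, specs, times, seed) {
  seeds <- split_seed(seed, cfg$n_wells * 2L)
  all_records <- list()
  for (w in seq_len(cfg$n_wells)) {
    truth <- synthetic_well_truth(
      cfg$cells_per_well, specs, noise_sd = cfg$noise_sd,
      drift_rate = cfg$drift_rate, artifact_jump = NA,
      seed = seeds[w])
    well <- synthesize_well_video(truth, times,
                                  well_id = sprintf("W%02d", w),
                                  measurement_id = sprintf("M%02d", (w - 1) %/% 2 + 1),
                                  seed = seeds[cfg$n_wells + w])
    out <- sensor_pipeline(well$video, cfg$detection_threshold,
                           cfg$min_distance)
    if (is.null(out$records)) next
    lab <- vapply(seq_len(nrow(out$peaks$peaks)), function(i) {
      d2 <- (truth$cells$row - out$peaks$peaks$row[i])^2 +
        (truth$cells$col - out$peaks$peaks$col[i])^2
      if (length(d2) && min(d2) <= 2) truth$cells$class[which.min(d2)]
      else NA_character_
    }, character(1))
    rec <- out$records
    rec$labels <- lab
    keep <- !is.na(lab)
    rec <- cell_records(rec$signals[keep, , drop = FALSE], rec$labels[keep],
                        rec$batch_ids[keep], rec$times)
    all_records[[w]] <- rec
  }
  check_that(length(all_records) > 0, "no cells recovered from any well")
  sig <- do.call(rbind, lapply(all_records, function(r) r$signals))
  cell_records(sig,
               unlist(lapply(all_records, function(r) r$labels)),
               unlist(lapply(all_records, function(r) r$batch_ids)),
               times)
}

#' Rank cross-validation results across models and lengths
#'
#' @param bundles named list of `cv_report` objects (names like
#'   "MCDCNN.90").
#' @return data.frame sorted by descending mean accuracy, with mean +- sd
#'   for precision, accuracy and recall and a `best` flag on the
#'   top-accuracy row.
#' @export
compare_models <- function(bundles) {
  check_that(length(bundles) >= 1, "need at least one cv_report")
  check_that(all(vapply(bundles, inherits, logical(1), "cv_report")),
             "bundles must be cv_report objects")
  cls <- lapply(bundles, function(b) rownames(b$pooled$confusion))
  check_that(length(unique(vapply(cls, paste, character(1), collapse = "|"))) == 1,
             "bundles have mismatched class sets")
  rows <- lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    s <- b$summary
    get <- function(m, col) s[s$metric == m, col]
    data.frame(
      setup = names(bundles)[i] %||% sprintf("bundle%d", i),
      network = b$model_name,
      length_min = b$length_variant,
      precision_mean = get("macro_precision", "mean"),
      precision_sd = get("macro_precision", "sd"),
      accuracy_mean = get("accuracy", "mean"),
      accuracy_sd = get("accuracy", "sd"),
      recall_mean = get("macro_recall", "mean"),
      recall_sd = get("macro_recall", "sd"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy_mean), , drop = FALSE]
  out$best <- seq_len(nrow(out)) == 1
  rownames(out) <- NULL
  out
}

# Write metrics JSON, confusion CSVs and manifest under out_dir.
write_experiment_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (mn in names(result$cv)) {
    for (len in names(result$cv[[mn]])) {
      rep <- result$cv[[mn]][[len]]
      base <- file.path(out_dir, sprintf("%s_%smin", tolower(mn), len))
      utils::write.csv(rep$pooled$confusion,
                       paste0(base, "_confusion.csv"))
      jsonlite::write_json(
        list(model = mn, length_min = as.numeric(len),
             summary = rep$summary, per_fold = as.data.frame(rep$per_fold)),
        paste0(base, "_metrics.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  utils::write.csv(result$comparison,
                   file.path(out_dir, "comparison.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d signals, %d classes, models: %s\n",
              nrow(x$records$signals), length(x$manifest$classes),
              paste(x$manifest$models, collapse = ", ")))
  print(x$comparison, digits = 3)
  invisible(x)
}
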