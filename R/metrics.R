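#' Confusion-matrix metrics for a set of predictions
#'
#' Builds the confusion matrix (rows: true class, columns: predicted
#' class) and derives accuracy (trace over total), per-class recall
#' (diagonal over row sum — the true positive rate), per-class precision
#' (diagonal over column sum), and their macro (unweighted) means. A class
#' never predicted contributes a precision of 0 to the macro mean.
#'
#' @param predicted predicted labels.
#' @param truth true labels.
#' @param levels optional class level ordering; defaults to the sorted
#'   union of both label sets.
#' @return object of class `metrics_report`: `confusion`, `accuracy`,
#'   `recall` (per class), `precision` (per class), `macro_recall`,
#'   `macro_precision`, `n`.
#' @export
evaluate <- function(predicted, truth, levels = NULL) {
  check_that(length(predicted) == length(truth),
             "predicted and truth must have equal length")
  check_that(length(truth) >= 1, "cannot evaluate an empty prediction set")
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  levels <- levels %||% sort(unique(c(predicted, truth)))
  cm <- table(factor(truth, levels = levels),
              factor(predicted, levels = levels))
  cm <- matrix(as.integer(cm), length(levels), length(levels),
               dimnames = list(true = levels, predicted = levels))
  rs <- rowSums(cm)
  cs <- colSums(cm)
  recall <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  precision <- ifelse(cs > 0, diag(cm) / cs, 0)
  structure(
    list(confusion = cm,
         accuracy = sum(diag(cm)) / sum(cm),
         recall = stats::setNames(recall, levels),
         precision = stats::setNames(precision, levels),
         macro_recall = mean(recall, na.rm = TRUE),
         macro_precision = mean(precision),
         n = length(truth)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  accuracy %.3f  macro precision %.3f  macro recall %.3f\n",
              x$n, x$accuracy, x$macro_precision, x$macro_recall))
  print(x$confusion)
  invisible(x)
}

#' Row-normalize a confusion matrix to per-class rates
#'
#' @param cm counts matrix (rows: true class).
#' @return matrix of row proportions.
#' @export
confusion_rates <- function(cm) {
  sweep(cm, 1, pmax(rowSums(cm), 1), "/")
}

#' Cross-validated training and evaluation of one architecture
#'
#' For each fold: the training portion is SMOTE-balanced and
#' standardization statistics are fitted on it (never on test rows); the
#' test portion is transformed with the training statistics and doubles as
#' the early-stopping validation set; a fresh model is built (per-fold
#' seed derived from `config$seed`), trained, and evaluated on the fold's
#' test rows. Reports per-fold metrics, their mean and standard deviation,
#' and the confusion matrix pooled over all test sets (each sample is
#' tested exactly once).
#'
#' @param dataset a [signal_dataset()] (zero-offset, batch-corrected, cut).
#' @param folds a [stratified_kfold_split()] on `dataset$y`.
#' @param model_name one of the six architecture names.
#' @param config a [train_config()]; `NULL` takes the architecture
#'   defaults.
#' @param smote_k SMOTE neighbour count.
#' @param verbose per-epoch progress interval for [train_model()].
#' @return object of class `cv_report`: `fold_metrics` (list of
#'   `metrics_report`), `summary` (data.frame of mean +- sd for accuracy,
#'   macro precision, macro recall), `pooled` (pooled-test
#'   `metrics_report`), `pooled_predictions` (data.frame index, fold,
#'   truth, predicted), `leakage` (per-fold audit: SMOTE provenance
#'   indices, standardization stats, train/test indices).
#' @export
cross_validate <- function(dataset, folds, model_name, config = NULL,
                           smote_k = 5L, verbose = 0L) {
  check_that(inherits(dataset, "signal_dataset"), "dataset must be a signal_dataset")
  check_that(inherits(folds, "fold_split"), "folds must be a fold_split")
  check_that(length(folds$assignments) == nrow(dataset$X),
             "fold split does not match dataset size")
  config <- config %||% train_config(model_name)
  levels <- sort(unique(dataset$y))
  seeds <- split_seed(config$seed, folds$k * 2L)
  fold_metrics <- vector("list", folds$k)
  leakage <- vector("list", folds$k)
  pooled <- data.frame(index = integer(0), fold = integer(0),
                       truth = character(0), predicted = character(0))
  for (f in seq_len(folds$k)) {
    tr <- folds$folds[[f]]$train
    te <- folds$folds[[f]]$test
    sm <- smote_oversample(dataset$X[tr, , drop = FALSE], dataset$y[tr],
                           k_neighbors = smote_k, seed = seeds[f])
    std <- standardize_signals(sm$X, dataset$X[te, , drop = FALSE])
    model <- build_model(model_name, ncol(dataset$X), length(levels),
                         seed = seeds[folds$k + f])
    cfg <- config
    cfg$seed <- seeds[f]
    model <- tryCatch(
      train_model(model, list(X = std$train, y = sm$y),
                  list(X = std$others[[1]], y = dataset$y[te]),
                  cfg, class_levels = levels, verbose = verbose),
      error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                               call. = FALSE))
    pred <- predict_model(model, std$others[[1]])
    fold_metrics[[f]] <- evaluate(pred$labels, dataset$y[te], levels)
    pooled <- rbind(pooled, data.frame(index = te, fold = f,
                                       truth = dataset$y[te],
                                       predicted = pred$labels))
    leakage[[f]] <- list(
      train_indices = tr, test_indices = te,
      smote_provenance = sm$provenance,
      standardization = list(mean = std$mean, sd = std$sd),
      post_smote_counts = table(sm$y))
  }
  metric_rows <- t(vapply(fold_metrics, function(m) {
    c(accuracy = m$accuracy, macro_precision = m$macro_precision,
      macro_recall = m$macro_recall)
  }, numeric(3)))
  summary <- data.frame(
    metric = colnames(metric_rows),
    mean = colMeans(metric_rows),
    sd = apply(metric_rows, 2, stats::sd),
    row.names = NULL
  )
  structure(
    list(model_name = config$model_name, fold_metrics = fold_metrics,
         per_fold = metric_rows, summary = summary,
         pooled = evaluate(pooled$predicted, pooled$truth, levels),
         pooled_predictions = pooled, leakage = leakage,
         length_variant = dataset$length_variant),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d folds, %g-min signals\n",
              x$model_name, length(x$fold_metrics), x$length_variant))
  print(x$summary, digits = 3)
  invisible(x)
}
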