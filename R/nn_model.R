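#' Architecture plans of the six time-series classifiers
#'
#' Declared layer plan per architecture: total layer count, convolutional
#' stage count, normalization, pooling, feature layer and activation, as
#' used for introspective validation of built models.
#'
#' @return data.frame, one row per architecture.
#' @export
model_zoo <- function() {
  data.frame(
    name = c("MLP", "CNN", "FCN", "ResNet", "MCDCNN", "Inception"),
    layers = c(4L, 4L, 5L, 11L, 4L, 7L),
    conv = c(0L, 3L, 3L, 9L, 2L, 6L),
    norm = c("", "", "batch", "batch", "", "batch"),
    pooling = c("", "avg", "gap", "gap", "max", "max+gap"),
    feature = c("fc", "fc", "", "", "fc", ""),
    activation = c("relu", "sigmoid", "relu", "relu", "relu", "relu"),
    regularization = c("dropout", "", "", "", "", ""),
    stringsAsFactors = FALSE
  )
}

#' Build a time-series classification model
#'
#' Instantiates one of the six architectures (MLP, CNN, FCN, ResNet,
#' MCDCNN, Inception) for univariate signals of length `input_length` and
#' `n_classes` output classes. Layer widths and kernel sizes follow the
#' reference time-series-classification benchmark implementations; layer
#' and convolutional-stage counts match the declared plan in
#' [model_zoo()]. The output layer is linear; probabilities are obtained
#' by softmax at prediction time.
#'
#' @param name architecture name (case-insensitive).
#' @param input_length number of timesteps L.
#' @param n_classes number of classes (>= 2).
#' @param seed integer seed for weight initialisation.
#' @return object of class `tsc_model`.
#' @export
build_model <- function(name, input_length, n_classes, seed = 1L) {
  check_that(n_classes >= 2, "need at least 2 classes")
  check_that(input_length >= 1, "input_length must be positive")
  canon <- c(mlp = "MLP", cnn = "CNN", fcn = "FCN", resnet = "ResNet",
             mcdcnn = "MCDCNN", inception = "Inception")
  key <- tolower(name)
  check_that(key %in% names(canon),
             sprintf("unknown model name '%s'; choose one of %s", name,
                     paste(canon, collapse = ", ")))
  name <- canon[[key]]
  L <- as.integer(input_length)
  stages <- switch(
    name,
    MLP = list(
      mk_flatten("fl"),
      mk_dropout("d0", 0.1),
      mk_dense("h1", L, 500L, act = "relu"),
      mk_dropout("d1", 0.2),
      mk_dense("h2", 500L, 500L, act = "relu"),
      mk_dropout("d2", 0.2),
      mk_dense("h3", 500L, 500L, act = "relu"),
      mk_dropout("d3", 0.3),
      mk_dense("out", 500L, n_classes)
    ),
    CNN = {
      check_that(L >= 27, "CNN needs input_length >= 27 (three 3x pools)")
      l1 <- L %/% 3L; l2 <- l1 %/% 3L; l3 <- l2 %/% 3L
      list(
        mk_conv_block("c1", 7L, 1L, 6L, act = "sigmoid"),
        mk_pool("p1", 3L, "avg"),
        mk_conv_block("c2", 7L, 6L, 12L, act = "sigmoid"),
        mk_pool("p2", 3L, "avg"),
        mk_conv_block("c3", 7L, 12L, 12L, act = "sigmoid"),
        mk_pool("p3", 3L, "avg"),
        mk_flatten("fl"),
        mk_dense("out", l3 * 12L, n_classes)
      )
    },
    FCN = list(
      mk_conv_block("c1", 8L, 1L, 128L, bn = TRUE, act = "relu"),
      mk_conv_block("c2", 5L, 128L, 256L, bn = TRUE, act = "relu"),
      mk_conv_block("c3", 3L, 256L, 128L, bn = TRUE, act = "relu"),
      mk_gap("gap"),
      mk_dense("out", 128L, n_classes)
    ),
    ResNet = list(
      mk_resblock("r1", 1L, 64L),
      mk_resblock("r2", 64L, 128L),
      mk_resblock("r3", 128L, 128L),
      mk_gap("gap"),
      mk_dense("out", 128L, n_classes)
    ),
    MCDCNN = {
      check_that(L >= 8, "MCDCNN needs input_length >= 8 (two 2x pools)")
      l2 <- (L %/% 2L) %/% 2L
      list(
        mk_conv_block("c1", 5L, 1L, 8L, act = "relu"),
        mk_pool("p1", 2L, "max"),
        mk_conv_block("c2", 5L, 8L, 8L, act = "relu"),
        mk_pool("p2", 2L, "max"),
        mk_flatten("fl"),
        mk_dense("fc", l2 * 8L, 732L, act = "relu"),
        mk_dense("out", 732L, n_classes)
      )
    },
    Inception = {
      k <- if (L >= 40) c(39L, 19L, 9L) else c(9L, 5L, 3L)
      list(
        mk_incepgroup("g1", 1L, nf = 32L, kernels = k),
        mk_incepgroup("g2", 128L, nf = 32L, kernels = k),
        mk_gap("gap"),
        mk_dense("out", 128L, n_classes)
      )
    }
  )
  params <- list()
  state <- list()
  with_seed(seed, {
    for (st in stages) {
      params <- c(params, stage_init_params(st))
      state <- c(state, stage_init_state(st))
    }
  })
  structure(
    list(name = name, stages = stages, params = params, state = state,
         input_length = L, n_classes = as.integer(n_classes),
         takes_3d = TRUE, seed = seed,
         class_levels = NULL, trained = FALSE),
    class = "tsc_model"
  )
}

#' @export
print.tsc_model <- function(x, ...) {
  cat(sprintf("<tsc_model> %s: L=%d, %d classes, %d conv stages, %d parameters%s\n",
              x$name, x$input_length, x$n_classes, count_conv_layers(x),
              sum(vapply(x$params, length, numeric(1))),
              if (x$trained) ", trained" else ""))
  invisible(x)
}

#' Count convolutional stages of a built model by introspection
#'
#' Walks the stage list: a plain conv block counts 1, a residual block its
#' main-path convolutions (3), an inception group its inception modules.
#' Shortcut 1x1 convolutions are not counted, matching how the
#' architectures are conventionally tabulated.
#'
#' @param model a `tsc_model`.
#' @return integer.
#' @export
count_conv_layers <- function(model) {
  sum(vapply(model$stages, function(st) {
    if (!isTRUE(st$is_conv)) return(0L)
    if (!is.null(st$n_conv)) st$n_conv else 1L
  }, integer(1)))
}

#' Count declared layers of a built model
#'
#' Main-path parameterized stages: convolutional stages (as in
#' [count_conv_layers()]) plus dense layers, plus the global-average-pooling
#' head where the architecture is conventionally tabulated with it (FCN,
#' ResNet).
#'
#' @param model a `tsc_model`.
#' @return integer.
#' @export
count_layers <- function(model) {
  n_dense <- sum(vapply(model$stages, function(st) st$type == "dense",
                        logical(1)))
  n_gap <- if (model$name %in% c("FCN", "ResNet")) {
    sum(vapply(model$stages, function(st) st$type == "gap", logical(1)))
  } else 0L
  count_conv_layers(model) + n_dense + n_gap
}

#' Class probabilities and labels for new signals
#'
#' Deterministic inference pass (dropout off, batch-norm running
#' statistics). Probabilities are softmax rows summing to one; labels are
#' the argmax class.
#'
#' @param model a (trained) `tsc_model`.
#' @param X N x L matrix of standardized signals.
#' @param batch_size inference batch size.
#' @return list with `proba` (N x n_classes matrix) and `labels`
#'   (character when the model knows its class levels, else integer).
#' @export
predict_model <- function(model, X, batch_size = 256L) {
  X <- as.matrix(X)
  check_that(ncol(X) == model$input_length,
             sprintf("input length %d does not match model length %d",
                     ncol(X), model$input_length))
  n <- nrow(X)
  proba <- matrix(0, n, model$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fw <- model_forward(model, X[i:j, , drop = FALSE], training = FALSE)
    proba[i:j, ] <- softmax(fw$logits)
    i <- j + 1L
  }
  idx <- max.col(proba, ties.method = "first")
  labels <- if (!is.null(model$class_levels)) {
    model$class_levels[idx]
  } else {
    idx
  }
  if (!is.null(model$class_levels)) colnames(proba) <- model$class_levels
  list(proba = proba, labels = labels)
}

#' @export
predict.tsc_model <- function(object, newdata, ...) {
  predict_model(object, newdata, ...)
}
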