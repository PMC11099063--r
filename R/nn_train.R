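#' Training configuration for a model, with per-architecture defaults
#'
#' Defaults follow the published hyperparameter table of the six
#' architectures: optimizer (AdaDelta for MLP; Adam for CNN, FCN, ResNet,
#' Inception; SGD with momentum 0.9 for MCDCNN), cross-entropy loss,
#' 500 epochs, batch size 16 for CNN and 32 otherwise, learning rate
#' 0.001 for MLP and MCDCNN and 0.0001 for the rest, and a 0.5
#' reduce-on-plateau learning-rate decay where listed (MLP, FCN, ResNet,
#' Inception). Any field can be overridden.
#'
#' @param model_name one of the six architecture names.
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param learning_rate optimizer learning rate.
#' @param optimizer `"adam"`, `"adadelta"` or `"sgd"`.
#' @param momentum SGD momentum.
#' @param lr_decay reduce-on-plateau factor (`NA` disables decay).
#' @param lr_patience epochs without validation-loss improvement before
#'   the learning rate is multiplied by `lr_decay`.
#' @param early_stopping_patience epochs without validation-loss
#'   improvement before training stops (best weights restored). `Inf`
#'   disables early stopping.
#' @param seed integer seed for shuffling and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(model_name,
                         epochs = 500L,
                         batch_size = NULL,
                         learning_rate = NULL,
                         optimizer = NULL,
                         momentum = 0.9,
                         lr_decay = NULL,
                         lr_patience = 20L,
                         early_stopping_patience = 50,
                         seed = 1L) {
  canon <- c(mlp = "MLP", cnn = "CNN", fcn = "FCN", resnet = "ResNet",
             mcdcnn = "MCDCNN", inception = "Inception")
  key <- tolower(model_name)
  check_that(key %in% names(canon), sprintf("unknown model name '%s'", model_name))
  nm <- canon[[key]]
  defaults <- list(
    MLP = list(optimizer = "adadelta", batch_size = 32L,
               learning_rate = 0.001, lr_decay = 0.5),
    CNN = list(optimizer = "adam", batch_size = 16L,
               learning_rate = 0.0001, lr_decay = NA),
    FCN = list(optimizer = "adam", batch_size = 32L,
               learning_rate = 0.0001, lr_decay = 0.5),
    ResNet = list(optimizer = "adam", batch_size = 32L,
                  learning_rate = 0.0001, lr_decay = 0.5),
    MCDCNN = list(optimizer = "sgd", batch_size = 32L,
                  learning_rate = 0.001, lr_decay = NA),
    Inception = list(optimizer = "adam", batch_size = 32L,
                     learning_rate = 0.0001, lr_decay = 0.5)
  )[[nm]]
  structure(
    list(model_name = nm,
         epochs = as.integer(epochs),
         batch_size = as.integer(batch_size %||% defaults$batch_size),
         learning_rate = learning_rate %||% defaults$learning_rate,
         optimizer = optimizer %||% defaults$optimizer,
         momentum = momentum,
         loss = "cross-entropy",
         lr_decay = if (is.null(lr_decay)) defaults$lr_decay else lr_decay,
         lr_patience = as.integer(lr_patience),
         early_stopping_patience = early_stopping_patience,
         seed = seed),
    class = "train_config"
  )
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf("<train_config> %s: %s lr=%g batch=%d epochs<=%d%s, ES patience %s\n",
              x$model_name, x$optimizer, x$learning_rate, x$batch_size,
              x$epochs,
              if (is.na(x$lr_decay)) "" else sprintf(" decay=%g", x$lr_decay),
              format(x$early_stopping_patience)))
  invisible(x)
}

# ---- optimizers ------------------------------------------------------------

opt_init <- function(optimizer, params) {
  slots <- lapply(params, function(p) {
    switch(optimizer,
           sgd = list(v = array(0, dim(p) %||% length(p))),
           adam = list(m = array(0, dim(p) %||% length(p)),
                       v = array(0, dim(p) %||% length(p))),
           adadelta = list(Eg = array(0, dim(p) %||% length(p)),
                           Ed = array(0, dim(p) %||% length(p))))
  })
  list(optimizer = optimizer, slots = slots, t = 0L)
}

opt_step <- function(opt, params, grads, lr, momentum = 0.9) {
  opt$t <- opt$t + 1L
  for (key in names(grads)) {
    g <- grads[[key]]
    p <- params[[key]]
    s <- opt$slots[[key]]
    if (opt$optimizer == "sgd") {
      s$v <- momentum * s$v - lr * g
      p <- p + s$v
    } else if (opt$optimizer == "adam") {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g^2
      mhat <- s$m / (1 - b1^opt$t)
      vhat <- s$v / (1 - b2^opt$t)
      p <- p - lr * mhat / (sqrt(vhat) + eps)
    } else { # adadelta
      rho <- 0.95; eps <- 1e-7
      s$Eg <- rho * s$Eg + (1 - rho) * g^2
      upd <- sqrt(s$Ed + eps) / sqrt(s$Eg + eps) * g
      s$Ed <- rho * s$Ed + (1 - rho) * upd^2
      p <- p - lr * upd
    }
    opt$slots[[key]] <- s
    params[[key]] <- p
  }
  list(opt = opt, params = params)
}

# ---- training --------------------------------------------------------------

encode_onehot <- function(y, levels) {
  m <- matrix(0, length(y), length(levels))
  m[cbind(seq_along(y), match(y, levels))] <- 1
  m
}

eval_loss_acc <- function(model, X, onehot, batch_size = 256L) {
  n <- nrow(X)
  loss_sum <- 0; correct <- 0L
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fw <- model_forward(model, X[i:j, , drop = FALSE], training = FALSE)
    xl <- xent_loss(fw$logits, onehot[i:j, , drop = FALSE])
    loss_sum <- loss_sum + xl$loss * (j - i + 1L)
    pred <- max.col(fw$logits, ties.method = "first")
    truth <- max.col(onehot[i:j, , drop = FALSE], ties.method = "first")
    correct <- correct + sum(pred == truth)
    i <- j + 1L
  }
  list(loss = loss_sum / n, acc = correct / n)
}

#' Train a model with minibatch gradient descent and early stopping
#'
#' Cross-entropy loss on softmax outputs, optimizer and hyperparameters
#' from the [train_config()]. After each epoch the validation loss and
#' accuracy are recorded; training stops at the epoch budget or when the
#' validation loss has not improved for `early_stopping_patience` epochs,
#' and the best-validation-loss weights are restored. Where the config
#' lists a decay factor, the learning rate is multiplied by it when the
#' validation loss plateaus (reduce-on-plateau).
#'
#' @param model an untrained `tsc_model` from [build_model()].
#' @param train list with `X` (N x L standardized matrix) and `y` labels.
#' @param val list with `X` and `y` used for early stopping monitoring.
#' @param config a [train_config()].
#' @param class_levels label set fixing the output-column order; defaults
#'   to the sorted union of train and val labels.
#' @param verbose print per-epoch progress every `verbose` epochs (0 = quiet).
#' @return the trained `tsc_model`, with a `history` data.frame attached
#'   (epoch, train_loss, train_acc, val_loss, val_acc, lr).
#' @export
train_model <- function(model, train, val, config,
                        class_levels = NULL, verbose = 0L) {
  check_that(inherits(model, "tsc_model"), "model must come from build_model()")
  check_that(inherits(config, "train_config"), "config must be a train_config")
  X <- as.matrix(train$X); y <- as.character(train$y)
  Xv <- as.matrix(val$X); yv <- as.character(val$y)
  check_that(ncol(X) == model$input_length, "train length mismatch")
  check_that(ncol(Xv) == model$input_length, "val length mismatch")
  levels <- class_levels %||% sort(unique(c(y, yv)))
  check_that(length(levels) == model$n_classes,
             "number of classes does not match the model output width")
  onehot <- encode_onehot(y, levels)
  onehot_v <- encode_onehot(yv, levels)
  n <- nrow(X)
  lr <- config$learning_rate
  opt <- opt_init(config$optimizer, model$params)
  best_loss <- Inf
  best_params <- model$params
  best_state <- model$state
  since_improve <- 0L
  since_lr <- 0L
  hist <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + config$batch_size - 1L, n)
        bi <- ord[i:j]
        fw <- model_forward(model, X[bi, , drop = FALSE], training = TRUE)
        model$state <- fw$state
        xl <- xent_loss(fw$logits, onehot[bi, , drop = FALSE])
        if (!is.finite(xl$loss)) {
          stop(sprintf("NaN/Inf loss at epoch %d; lower the learning rate",
                       epoch), call. = FALSE)
        }
        bw <- model_backward(model, fw$caches, xl$dlogits)
        step <- opt_step(opt, model$params, bw$grads, lr, config$momentum)
        opt <- step$opt
        model$params <- step$params
        ep_loss <- ep_loss + xl$loss * length(bi)
        ep_correct <- ep_correct +
          sum(max.col(fw$logits, ties.method = "first") ==
                max.col(onehot[bi, , drop = FALSE], ties.method = "first"))
        i <- j + 1L
      }
      ev <- eval_loss_acc(model, Xv, onehot_v)
      if (!is.finite(ev$loss)) {
        stop(sprintf("NaN/Inf validation loss at epoch %d; lower the learning rate",
                     epoch), call. = FALSE)
      }
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = ev$loss, val_acc = ev$acc, lr = lr)
      if (verbose > 0 && epoch %% verbose == 0) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
                        epoch, ep_loss / n, ep_correct / n, ev$loss, ev$acc))
      }
      if (ev$loss < best_loss - 1e-9) {
        best_loss <- ev$loss
        best_params <- model$params
        best_state <- model$state
        since_improve <- 0L
        since_lr <- 0L
      } else {
        since_improve <- since_improve + 1L
        since_lr <- since_lr + 1L
      }
      if (!is.na(config$lr_decay) && since_lr > config$lr_patience) {
        lr <- max(lr * config$lr_decay, 1e-7)
        since_lr <- 0L
      }
      if (since_improve > config$early_stopping_patience) break
    }
  })
  model$params <- best_params
  model$state <- best_state
  model$class_levels <- levels
  model$trained <- TRUE
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model
}
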