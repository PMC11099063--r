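#' Gradient-weighted class activation map for a 1D conv classifier
#'
#' Computes `L^c = ReLU(sum_k alpha_k^c A^k)` at a convolutional stage:
#' `A^k` is the stage's k-th output feature map for the given input, and
#' the neuron importance `alpha_k^c` is the global average over positions
#' of the gradient of the class score `y^c` (the pre-softmax output of
#' class `c`) with respect to `A^k`. Positive weights mark feature maps
#' whose activation supports the target class; the ReLU keeps only the
#' positions correlating positively with it.
#'
#' @param model a trained `tsc_model` containing at least one
#'   convolutional stage (MLP is unsupported).
#' @param x one signal: numeric vector of length `input_length`
#'   (standardized like the training data).
#' @param target_class class label (or 1-based index) whose score is
#'   explained.
#' @param layer 1-based index among the model's convolutional stages;
#'   default the last one, which is the conventional grad-CAM target.
#' @return object of class `grad_cam`: `weights` (length = feature-map
#'   length), `upsampled_weights` (length = input length),
#'   `neuron_importances` (alpha_k^c), `feature_maps` (L' x K matrix),
#'   `target_class`, `layer` (stage index).
#' @export
compute_gradcam <- function(model, x, target_class, layer = NULL) {
  check_that(inherits(model, "tsc_model"), "model must be a tsc_model")
  conv_idx <- which(vapply(model$stages, function(st) isTRUE(st$is_conv),
                           logical(1)))
  check_that(length(conv_idx) > 0,
             sprintf("%s has no convolutional layers; grad-CAM unsupported",
                     model$name))
  stage_i <- if (is.null(layer)) {
    conv_idx[length(conv_idx)]
  } else {
    check_that(layer >= 1 && layer <= length(conv_idx),
               "layer index out of range of convolutional stages")
    conv_idx[layer]
  }
  x <- as.numeric(x)
  check_that(length(x) == model$input_length, "input length mismatch")
  cls <- if (is.character(target_class)) {
    check_that(!is.null(model$class_levels), "model has no class levels")
    m <- match(target_class, model$class_levels)
    check_that(!is.na(m), sprintf("unknown class '%s'", target_class))
    m
  } else {
    as.integer(target_class)
  }
  check_that(cls >= 1 && cls <= model$n_classes, "target class out of range")
  X <- matrix(x, 1, length(x))
  fw <- model_forward(model, X, training = FALSE, collect = TRUE)
  A <- fw$outs[[stage_i]] # 1 x L' x K
  dLogits <- matrix(0, 1, model$n_classes)
  dLogits[1, cls] <- 1
  bw <- model_backward(model, fw$caches, dLogits, stop_at = stage_i)
  dA <- bw$dX # 1 x L' x K, gradient of y^c w.r.t. A
  Lp <- dim(A)[2]; K <- dim(A)[3]
  Amat <- matrix(A[1, , ], Lp, K)
  dAmat <- matrix(dA[1, , ], Lp, K)
  alpha <- colMeans(dAmat)
  weights <- pmax(as.vector(Amat %*% alpha), 0)
  structure(
    list(weights = weights,
         upsampled_weights = upsample_cam(weights, model$input_length),
         neuron_importances = alpha,
         feature_maps = Amat,
         target_class = target_class,
         layer = stage_i,
         score = fw$logits[1, cls]),
    class = "grad_cam"
  )
}

#' @export
print.grad_cam <- function(x, ...) {
  cat(sprintf("<grad_cam> class %s at stage %d: %d map positions -> %d timesteps, max weight %.4g\n",
              format(x$target_class), x$layer, length(x$weights),
              length(x$upsampled_weights), max(x$upsampled_weights)))
  invisible(x)
}

#' Upsample a CAM to the input resolution
#'
#' Linear interpolation from the feature-map length to the input length;
#' endpoints are preserved and non-negativity (and the maximum) cannot
#' increase under linear interpolation.
#'
#' @param weights CAM values at feature-map resolution (or a `grad_cam`).
#' @param input_length target length.
#' @return numeric vector of length `input_length`.
#' @export
upsample_cam <- function(weights, input_length) {
  if (inherits(weights, "grad_cam")) weights <- weights$weights
  n <- length(weights)
  check_that(n >= 1 && n <= input_length,
             "CAM length must be between 1 and input_length")
  if (n == input_length) return(weights)
  if (n == 1) return(rep(weights, input_length))
  stats::approx(x = seq(0, 1, length.out = n), y = weights,
                xout = seq(0, 1, length.out = input_length))$y
}

#' Finite-difference oracle for grad-CAM neuron importances
#'
#' Recomputes `alpha_k^c` by central differences: perturbing feature map
#' `k` of the target stage by a constant epsilon changes the class score
#' by `epsilon * sum_l dy/dA_lk`, so the average-pooled gradient is the
#' difference quotient divided by the map length. Independent of the
#' backpropagation path — used to validate it.
#'
#' @param model a trained `tsc_model`.
#' @param x one input signal.
#' @param target_class class index or label.
#' @param layer conv-stage index as in [compute_gradcam()].
#' @param eps perturbation size.
#' @return numeric vector of alpha estimates, one per feature map.
#' @export
gradcam_alpha_fd <- function(model, x, target_class, layer = NULL,
                             eps = 1e-3) {
  conv_idx <- which(vapply(model$stages, function(st) isTRUE(st$is_conv),
                           logical(1)))
  stage_i <- if (is.null(layer)) conv_idx[length(conv_idx)] else conv_idx[layer]
  cls <- if (is.character(target_class)) {
    match(target_class, model$class_levels)
  } else {
    as.integer(target_class)
  }
  X <- matrix(as.numeric(x), 1, length(x))
  fw <- model_forward(model, X, training = FALSE, collect = TRUE)
  A <- fw$outs[[stage_i]]
  Lp <- dim(A)[2]; K <- dim(A)[3]
  vapply(seq_len(K), function(k) {
    Ap <- A; Am <- A
    Ap[1, , k] <- Ap[1, , k] + eps
    Am[1, , k] <- Am[1, , k] - eps
    yp <- model_forward_from(model, stage_i, Ap)[1, cls]
    ym <- model_forward_from(model, stage_i, Am)[1, cls]
    (yp - ym) / (2 * eps) / Lp
  }, numeric(1))
}

#' Endpoint wavelength-shift distributions of correct vs misclassified cells
#'
#' For each true class, histograms the endpoint WS (final signal value,
#' pm) of its test cells split by outcome: correctly classified versus
#' misclassified-as-X for every other class. Mirrors the false-negative
#' distribution analysis used to see where in the adhesion range a
#' classifier fails.
#'
#' @param predicted predicted labels.
#' @param truth true labels.
#' @param endpoint_ws numeric vector, endpoint wavelength shift per sample,
#'   pm.
#' @param breaks histogram breaks (passed to [hist()]); default 20 bins
#'   over the data range.
#' @return object of class `fn_distribution`: list per true class with
#'   `breaks`, `correct` (counts), and `false_negative` (named list of
#'   counts per predicted class), plus `totals`.
#' @export
false_negative_distribution <- function(predicted, truth, endpoint_ws,
                                        breaks = NULL) {
  check_that(length(predicted) == length(truth) &&
               length(truth) == length(endpoint_ws),
             "predicted, truth and endpoint_ws must be parallel")
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  if (is.null(breaks)) {
    rng <- range(endpoint_ws)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = 21)
  }
  bin_counts <- function(v) {
    if (length(v) == 0) return(numeric(length(breaks) - 1))
    graphics::hist(pmin(pmax(v, breaks[1]), breaks[length(breaks)]),
                   breaks = breaks, plot = FALSE)$counts
  }
  per_class <- lapply(classes, function(cl) {
    sel <- truth == cl
    if (!any(sel)) {
      warning(sprintf("class %s has no test samples", cl))
    }
    fn_classes <- setdiff(unique(predicted[sel]), cl)
    list(
      breaks = breaks,
      correct = bin_counts(endpoint_ws[sel & predicted == cl]),
      false_negative = stats::setNames(
        lapply(fn_classes, function(pc) {
          bin_counts(endpoint_ws[sel & predicted == pc])
        }), fn_classes),
      total = sum(sel)
    )
  })
  structure(stats::setNames(per_class, classes), class = "fn_distribution")
}

#' Total CAM mass fraction inside a time window
#'
#' Helper for localization analyses: the share of the (non-negative)
#' upsampled CAM weight falling into `window` (fractions of the input
#' length, e.g. `c(2/3, 1)` for the final third).
#'
#' @param cam a `grad_cam` (or numeric upsampled weights).
#' @param window `c(from, to)` fractions in `[0, 1]`.
#' @return fraction in `[0, 1]` (NaN if the CAM is identically zero).
#' @export
cam_mass_fraction <- function(cam, window) {
  w <- if (inherits(cam, "grad_cam")) cam$upsampled_weights else as.numeric(cam)
  n <- length(w)
  idx <- seq(floor(window[1] * n) + 1, ceiling(window[2] * n))
  idx <- idx[idx >= 1 & idx <= n]
  sum(w[idx]) / sum(w)
}
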