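## Inception-ResNet-style binary pathology classifiers.
##
## One binary model per pathology (IRF / SRF / PED). The architecture
## follows the published skeleton -- stem, a stack of Inception-ResNet-A
## blocks, Reduction-A, Inception-ResNet-B blocks, Reduction-B,
## Inception-ResNet-C blocks, global average pooling, dropout and a
## two-way softmax -- realized compactly on the in-package CNN engine:
## blocks are multi-branch convolutions concatenated, linearly projected
## back to the trunk width and added residually with a 0.2 scale;
## reductions are stride-2 convolutions. Presets fix the published block
## counts (standard 10/20/10, small 8/7/4) plus a desk-scale tiny preset
## (1/1/1 at reduced width) for fast experiments and tests; parameter
## counts decrease strictly from standard to small to tiny.

#' Classifier configuration
#'
#' @param preset `"standard"` (block counts 10/20/10), `"small"` (8/7/4) or
#'   `"tiny"` (1/1/1 at reduced width). Explicit block counts override the
#'   preset's.
#' @param n_blocks_a,n_blocks_b,n_blocks_c Numbers of Inception-ResNet
#'   A/B/C blocks, each >= 1.
#' @param input_size Square model input resolution in pixels (default 450);
#'   grayscale B-scans are bilinearly resized and replicated to 3 channels.
#' @param n_classes Fixed at 2 (pathology absent / present).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param width Stem output width (trunk channels); defaults to 48 for
#'   standard/small and 8 for tiny.
#' @param dropout Dropout rate before the final dense layer.
#' @return Object of class `model_config`.
#' @export
model_config <- function(preset = c("small", "standard", "tiny"),
                         n_blocks_a = NULL, n_blocks_b = NULL,
                         n_blocks_c = NULL, input_size = 450L,
                         n_classes = 2L, learning_rate = 1e-4,
                         width = NULL, dropout = 0.2) {
  preset <- match.arg(preset)
  blocks <- switch(preset,
                   standard = c(10L, 20L, 10L),
                   small = c(8L, 7L, 4L),
                   tiny = c(1L, 1L, 1L))
  if (!is.null(n_blocks_a)) blocks[1L] <- as.integer(n_blocks_a)
  if (!is.null(n_blocks_b)) blocks[2L] <- as.integer(n_blocks_b)
  if (!is.null(n_blocks_c)) blocks[3L] <- as.integer(n_blocks_c)
  if (any(blocks < 1L))
    stop("block counts must all be >= 1", call. = FALSE)
  if (n_classes != 2L)
    stop("binary classifiers only: n_classes is fixed at 2", call. = FALSE)
  if (is.null(width)) width <- if (preset == "tiny") 8L else 48L
  if (input_size < 16L)
    stop("input_size must be at least 16 pixels", call. = FALSE)
  structure(list(preset = preset, n_blocks_a = blocks[1L],
                 n_blocks_b = blocks[2L], n_blocks_c = blocks[3L],
                 input_size = as.integer(input_size),
                 n_classes = 2L, learning_rate = learning_rate,
                 width = as.integer(width), dropout = dropout),
            class = "model_config")
}

## Multi-branch residual blocks. `cw` is the trunk width, `bw` the branch
## width; the concatenated branches are projected back to `cw` by a linear
## 1x1 convolution and added with a 0.2 residual scale.
block_a <- function(cw, bw) {
  nn_residual(nn_seq(
    nn_branch(list(
      nn_conv(1L, 1L, cw, bw),
      nn_seq(nn_conv(1L, 1L, cw, bw), nn_conv(3L, 3L, bw, bw)),
      nn_seq(nn_conv(1L, 1L, cw, bw), nn_conv(3L, 3L, bw, bw),
             nn_conv(3L, 3L, bw, bw)))),
    nn_conv(1L, 1L, 3L * bw, cw, act = "linear")))
}

## B and C blocks use factorized 1x3 + 3x1 convolutions in their second
## branch, at different branch widths.
block_bc <- function(cw, bw) {
  nn_residual(nn_seq(
    nn_branch(list(
      nn_conv(1L, 1L, cw, bw),
      nn_seq(nn_conv(1L, 1L, cw, bw), nn_conv(1L, 3L, bw, bw),
             nn_conv(3L, 1L, bw, bw)))),
    nn_conv(1L, 1L, 2L * bw, cw, act = "linear")))
}

#' Build a pathology classifier
#'
#' Assembles the network for a [model_config()]: stem (two stride-2 3x3
#' convolutions) -> A blocks -> Reduction-A -> B blocks -> Reduction-B ->
#' C blocks -> global average pooling -> dropout -> dense softmax over two
#' classes. The activations of the final convolutional stage and the
#' gradients of any class score with respect to them are exposed through
#' [model_cam_interface()], as required by every CAM technique. Weights are
#' randomly initialized under `seed` (He initialization); externally
#' trained parameter sets can be injected with [set_model_params()].
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @param pathology Optional pathology tag ("IRF", "SRF" or "PED") carried
#'   for bookkeeping and checked by [cscan_volume()].
#' @return Object of class `fluidcam_model`.
#' @export
build_classifier <- function(config = model_config(), seed = 1L,
                             pathology = NULL) {
  stopifnot(inherits(config, "model_config"))
  w <- config$width
  ba <- max(4L, w %/% 4L)
  bb <- max(4L, w %/% 2L)
  bc <- max(8L, w)
  withr::with_seed(as.integer(seed), {
    stem <- nn_seq(nn_conv(3L, 3L, 3L, w %/% 2L, stride = 2L),
                   nn_conv(3L, 3L, w %/% 2L, w, stride = 2L))
    mods <- list(stem)
    for (i in seq_len(config$n_blocks_a)) mods <- c(mods, list(block_a(w, ba)))
    mods <- c(mods, list(nn_conv(3L, 3L, w, 2L * w, stride = 2L)))  # Reduction-A
    for (i in seq_len(config$n_blocks_b)) mods <- c(mods, list(block_bc(2L * w, bb)))
    mods <- c(mods, list(nn_conv(3L, 3L, 2L * w, 4L * w, stride = 2L)))  # Reduction-B
    for (i in seq_len(config$n_blocks_c)) mods <- c(mods, list(block_bc(4L * w, bc)))
    features <- nn_seq(mods)
    head <- nn_seq(list(nn_gap(), nn_dropout(config$dropout),
                        nn_dense(4L * w, 2L)))
    structure(list(config = config, features = features, head = head,
                   pathology = pathology, log = NULL),
              class = "fluidcam_model")
  })
}

#' @export
print.fluidcam_model <- function(x, ...) {
  cat(sprintf("<fluidcam classifier: preset=%s blocks=%d/%d/%d width=%d input=%d params=%d%s>\n",
              x$config$preset, x$config$n_blocks_a, x$config$n_blocks_b,
              x$config$n_blocks_c, x$config$width, x$config$input_size,
              model_param_count(x),
              if (is.null(x$pathology)) "" else paste0(" pathology=", x$pathology)))
  invisible(x)
}

#' Number of trainable parameters of a classifier
#'
#' @param model A `fluidcam_model`.
#' @return Integer-valued count over all convolutional and dense weights
#'   and biases.
#' @export
model_param_count <- function(model) {
  nn_param_count(model$features) + nn_param_count(model$head)
}

model_all_params <- function(model) {
  c(nn_params(model$features, "f"), nn_params(model$head, "h"))
}

#' Replace the parameter set of a classifier
#'
#' Injection hook for externally trained weights: the flat named list must
#' match the layout returned by the internal parameter walk of the same
#' architecture.
#'
#' @param model A `fluidcam_model`.
#' @param params Flat named parameter list.
#' @return The model with parameters replaced.
#' @export
set_model_params <- function(model, params) {
  model$features <- nn_set_params(model$features, params, "f")
  model$head <- nn_set_params(model$head, params, "h")
  model
}

#' Categorical cross-entropy loss
#'
#' `-sum(y * log(y_hat))` with natural logarithm; predictions are clamped
#' to \[1e-7, 1\] so a hard zero never produces an infinite loss.
#'
#' @param y One-hot target vector.
#' @param y_hat Prediction vector of the same length (softmax scores).
#' @return Non-negative scalar; 0 iff the predicted probability of the true
#'   class is 1.
#' @export
cce_loss <- function(y, y_hat) {
  if (length(y) != length(y_hat))
    stop("target and prediction lengths differ", call. = FALSE)
  if (sum(y == 1) != 1L || any(!(y %in% c(0, 1))))
    stop("y must be one-hot", call. = FALSE)
  -sum(y * log(pmin(pmax(y_hat, 1e-7), 1)))
}

#' Classify one B-scan
#'
#' Resizes the grayscale image to the model input resolution (bilinear,
#' replicated to 3 channels), runs the network and returns softmax scores.
#'
#' @param object A `fluidcam_model`.
#' @param image Grayscale matrix in \[0, 255\].
#' @param ... Unused.
#' @return List of class `prediction_vector`: `y_hat` (scores over
#'   \{absent, present\}, summing to 1) and `positive_score` (the
#'   pathology-present probability). A slice enters the visualization stage
#'   of [cscan_volume()] only when `positive_score` is strictly greater
#'   than the gate.
#' @export
predict.fluidcam_model <- function(object, image, ...) {
  if (!is.matrix(image))
    stop("image must be a 2-D grayscale matrix", call. = FALSE)
  x <- prep_image(image, object$config$input_size)
  A <- nn_forward(object$features, x)$out
  p <- softmax(nn_forward(object$head, A)$out)
  structure(list(y_hat = p, positive_score = p[2L]),
            class = "prediction_vector")
}

#' Train a classifier with Adam on categorical cross-entropy
#'
#' Mini-batch Adam at the configured learning rate (default 1e-4),
#' seeded shuffling and dropout, per-epoch loss/accuracy logging. With
#' `epochs = 0` the model is returned unchanged. Two runs with identical
#' seed and data produce identical parameters.
#'
#' @param model A `fluidcam_model`.
#' @param images List of grayscale matrices in \[0, 255\].
#' @param labels 0/1 vector (1 = pathology present), one per image.
#' @param epochs Number of passes over the data.
#' @param seed Integer RNG seed covering shuffling and dropout.
#' @param batch_size Mini-batch size (gradients averaged per batch).
#' @param learning_rate Overrides the config value when given.
#' @param verbose Print per-epoch loss/accuracy.
#' @return The trained model; `model$log` holds a data frame with columns
#'   `epoch`, `loss`, `accuracy`.
#' @export
train_classifier <- function(model, images, labels, epochs, seed = 1L,
                             batch_size = 16L, learning_rate = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(model, "fluidcam_model"))
  if (length(images) == 0L)
    stop("training dataset is empty", call. = FALSE)
  if (length(labels) != length(images))
    stop("one label per image required", call. = FALSE)
  if (epochs == 0L) return(model)
  lr <- if (is.null(learning_rate)) model$config$learning_rate else learning_rate
  n <- length(images)
  xs <- lapply(images, prep_image, input_size = model$config$input_size)
  ys <- lapply(labels, function(l) if (l == 1) c(0, 1) else c(1, 0))
  params <- model_all_params(model)
  opt <- adam_init(params)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    accuracy = numeric(0))
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      for (b0 in seq(1L, n, by = batch_size)) {
        model <- set_model_params(model, params)
        idx <- perm[b0:min(b0 + batch_size - 1L, n)]
        acc <- NULL
        for (i in idx) {
          ff <- nn_forward(model$features, xs[[i]], training = TRUE)
          hf <- nn_forward(model$head, ff$out, training = TRUE)
          p <- softmax(hf$out)
          ep_loss <- ep_loss + cce_loss(ys[[i]], p)
          ep_correct <- ep_correct + (which.max(p) == which.max(ys[[i]]))
          dz <- p - ys[[i]]                # d(CCE o softmax)/dlogits
          hb <- nn_backward(model$head, hf$cache, dz)
          fb <- nn_backward(model$features, ff$cache, hb$gin)
          g <- c(nn_flatten_grads(model$features, fb$grads, "f"),
                 nn_flatten_grads(model$head, hb$grads, "h"))
          acc <- nn_grad_accumulate(acc, g)
        }
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(idx)
        step <- adam_step(opt, params, acc, lr)
        opt <- step$state
        params <- step$params
      }
      log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n,
                                   accuracy = ep_correct / n))
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  acc %.3f", ep,
                        ep_loss / n, ep_correct / n))
    }
  })
  model <- set_model_params(model, params)
  model$log <- log
  model
}

#' Training accuracy of a model on a labelled image set
#'
#' @inheritParams train_classifier
#' @param gate Decision threshold on the positive score.
#' @return Fraction of images classified correctly.
#' @export
classification_accuracy <- function(model, images, labels, gate = 0.5) {
  preds <- vapply(images, function(im)
    predict(model, im)$positive_score, numeric(1L))
  mean((preds > gate) == (labels == 1))
}

#' CAM interface of a classifier
#'
#' Exposes the final convolutional stage activations, the class-score
#' gradient with respect to them (backpropagation through the pooling/dense
#' head), and full forward scoring, at the model input resolution.
#'
#' @param model A `fluidcam_model`.
#' @return A [cam_interface()].
#' @export
model_cam_interface <- function(model) {
  sz <- model$config$input_size
  cam_interface(
    activations = function(image)
      nn_forward(model$features, prep_image(image, sz))$out,
    head_score = function(A, class_index)
      nn_forward(model$head, A)$out[class_index],
    head_grad = function(A, class_index) {
      hf <- nn_forward(model$head, A)
      gy <- numeric(length(hf$out))
      gy[class_index] <- 1
      nn_backward(model$head, hf$cache, gy)$gin
    },
    forward_score = function(image, class_index) {
      A <- nn_forward(model$features, prep_image(image, sz))$out
      nn_forward(model$head, A)$out[class_index]
    },
    analysis_size = c(sz, sz))
}

#' Save / load a classifier or despeckler checkpoint
#'
#' Serialized with R's native RDS format.
#'
#' @param model Model object.
#' @param path Checkpoint path.
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
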