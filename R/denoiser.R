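## Gated convolution-deconvolution despeckler.
##
## An encoder of stride-1 convolutions builds a representation that retains
## structural features while discarding speckle; a mirrored deconvolution
## decoder reconstructs the image. Every encoder output e_i is split by a
## learnable gate g_i in [0, 1]: g_i * e_i crosses the skip connection to
## the mirrored decoder layer and (1 - g_i) * e_i continues down the
## encoder, so with all gates at 0 the decoder receives no skip information
## and reconstructs from the bottleneck path alone. Gates are
## sigmoid-parameterized, which keeps them in [0, 1] throughout training.
## Trained with mean-squared error on clean/speckled image pairs.

#' Despeckler configuration
#'
#' @param n_encoder_layers Encoder depth (default 5); the decoder mirrors
#'   it, giving exactly one gated skip connection per encoder layer.
#' @param widths Channel widths of the encoder layers, one per layer
#'   (default `c(32, 64, 128, 256, 256)` truncated/recycled to the depth).
#' @param gate_init Initial gate value in (0, 1) for every skip.
#' @param kernel Convolution kernel size (default 3).
#' @param seed Weight initialization seed.
#' @return Object of class `denoiser_config`.
#' @export
denoiser_config <- function(n_encoder_layers = 5L,
                            widths = c(32L, 64L, 128L, 256L, 256L),
                            gate_init = 0.5, kernel = 3L, seed = 1L) {
  n <- as.integer(n_encoder_layers)
  if (n < 1L) stop("n_encoder_layers must be >= 1", call. = FALSE)
  if (gate_init <= 0 || gate_init >= 1)
    stop("gate_init must lie strictly inside (0, 1)", call. = FALSE)
  widths <- rep_len(as.integer(widths), n)
  structure(list(n_encoder_layers = n, widths = widths,
                 gate_init = gate_init, kernel = as.integer(kernel),
                 seed = as.integer(seed)),
            class = "denoiser_config")
}

#' Build a gated encoder-decoder despeckler
#'
#' @param config A [denoiser_config()].
#' @return Object of class `fluidcam_denoiser` with encoder convolutions,
#'   a bottleneck convolution, mirrored decoder deconvolutions, a final
#'   linear 1x1 projection and one gate parameter per skip connection.
#' @export
build_denoiser <- function(config = denoiser_config()) {
  stopifnot(inherits(config, "denoiser_config"))
  n <- config$n_encoder_layers
  w <- config$widths
  k <- config$kernel
  withr::with_seed(config$seed, {
    enc <- vector("list", n)
    cin <- 1L
    for (i in seq_len(n)) {
      enc[[i]] <- nn_conv(k, k, cin, w[i])
      cin <- w[i]
    }
    bottleneck <- nn_conv(k, k, w[n], w[n])
    dec <- vector("list", n)
    for (i in seq_len(n)) {
      cout <- if (i == 1L) w[1L] else w[i - 1L]
      dec[[i]] <- nn_conv(k, k, w[i], cout)
    }
    out_conv <- nn_conv(1L, 1L, w[1L], 1L, act = "linear")
    theta <- rep(stats::qlogis(config$gate_init), n)
    structure(list(config = config, enc = enc, bottleneck = bottleneck,
                   dec = dec, out_conv = out_conv, theta = theta,
                   log = NULL),
              class = "fluidcam_denoiser")
  })
}

#' Gate values of a despeckler
#'
#' @param model A `fluidcam_denoiser`.
#' @return Numeric vector of skip-gate values, each in \[0, 1\].
#' @export
denoiser_gates <- function(model) stats::plogis(model$theta)

## Full forward pass on a [0, 1]-scaled single-channel array; returns the
## output plus all caches needed for backpropagation.
denoiser_forward <- function(model, x) {
  n <- model$config$n_encoder_layers
  g <- stats::plogis(model$theta)
  e <- vector("list", n)
  ecache <- vector("list", n)
  cur <- x
  for (i in seq_len(n)) {
    r <- nn_conv_forward(model$enc[[i]], cur)
    e[[i]] <- r$out
    ecache[[i]] <- r$cache
    cur <- (1 - g[i]) * r$out           # pass-through to the next layer
  }
  bn <- nn_conv_forward(model$bottleneck, cur)
  dcache <- vector("list", n)
  cur <- bn$out
  for (i in rev(seq_len(n))) {
    inp <- cur + g[i] * e[[i]]          # gated skip joins the decoder
    r <- nn_conv_forward(model$dec[[i]], inp)
    dcache[[i]] <- list(cache = r$cache)
    cur <- r$out
  }
  out <- nn_conv_forward(model$out_conv, cur)
  list(out = out$out, e = e, g = g, ecache = ecache, bn_cache = bn$cache,
       dcache = dcache, out_cache = out$cache)
}

## Backward pass for dL/d(output); returns parameter gradients in a flat
## named list (matching denoiser_params) including the gate parameters.
denoiser_backward <- function(model, fwd, gout) {
  n <- model$config$n_encoder_layers
  g <- fwd$g
  grads <- list()
  r <- nn_conv_backward(model$out_conv, fwd$out_cache, gout)
  grads[["out/W"]] <- r$grads$W
  grads[["out/b"]] <- r$grads$b
  gcur <- r$gin
  gskip <- vector("list", n)            # dL/d(e_i) via the skip path
  dtheta <- numeric(n)
  for (i in seq_len(n)) {               # decoder ran n..1, so backprop 1..n
    r <- nn_conv_backward(model$dec[[i]], fwd$dcache[[i]]$cache, gcur)
    grads[[paste0("dec", i, "/W")]] <- r$grads$W
    grads[[paste0("dec", i, "/b")]] <- r$grads$b
    gskip[[i]] <- g[i] * r$gin
    dtheta[i] <- dtheta[i] + sum(r$gin * fwd$e[[i]]) * g[i] * (1 - g[i])
    gcur <- r$gin                       # continues to the deeper stage
  }
  r <- nn_conv_backward(model$bottleneck, fwd$bn_cache, gcur)
  grads[["bn/W"]] <- r$grads$W
  grads[["bn/b"]] <- r$grads$b
  gcur <- r$gin                         # dL/d((1-g_n) e_n)
  for (i in rev(seq_len(n))) {
    ge <- (1 - g[i]) * gcur + gskip[[i]]
    dtheta[i] <- dtheta[i] - sum(gcur * fwd$e[[i]]) * g[i] * (1 - g[i])
    r <- nn_conv_backward(model$enc[[i]], fwd$ecache[[i]], ge)
    grads[[paste0("enc", i, "/W")]] <- r$grads$W
    grads[[paste0("enc", i, "/b")]] <- r$grads$b
    gcur <- r$gin
  }
  grads[["theta"]] <- dtheta
  grads
}

denoiser_params <- function(model) {
  n <- model$config$n_encoder_layers
  p <- list()
  for (i in seq_len(n)) {
    p[[paste0("enc", i, "/W")]] <- model$enc[[i]]$W
    p[[paste0("enc", i, "/b")]] <- model$enc[[i]]$b
  }
  p[["bn/W"]] <- model$bottleneck$W
  p[["bn/b"]] <- model$bottleneck$b
  for (i in seq_len(n)) {
    p[[paste0("dec", i, "/W")]] <- model$dec[[i]]$W
    p[[paste0("dec", i, "/b")]] <- model$dec[[i]]$b
  }
  p[["out/W"]] <- model$out_conv$W
  p[["out/b"]] <- model$out_conv$b
  p[["theta"]] <- model$theta
  p
}

denoiser_set_params <- function(model, p) {
  n <- model$config$n_encoder_layers
  for (i in seq_len(n)) {
    model$enc[[i]]$W <- p[[paste0("enc", i, "/W")]]
    model$enc[[i]]$b <- p[[paste0("enc", i, "/b")]]
    model$dec[[i]]$W <- p[[paste0("dec", i, "/W")]]
    model$dec[[i]]$b <- p[[paste0("dec", i, "/b")]]
  }
  model$bottleneck$W <- p[["bn/W"]]
  model$bottleneck$b <- p[["bn/b"]]
  model$out_conv$W <- p[["out/W"]]
  model$out_conv$b <- p[["out/b"]]
  model$theta <- p[["theta"]]
  model
}

#' Despeckle a B-scan
#'
#' @param model A trained `fluidcam_denoiser`.
#' @param image Grayscale matrix in \[0, 255\] (any resolution; the network
#'   is fully convolutional).
#' @return Same-shape matrix with values in \[0, 255\].
#' @export
denoise <- function(model, image) {
  stopifnot(inherits(model, "fluidcam_denoiser"))
  if (!is.matrix(image))
    stop("image must be a 2-D grayscale matrix", call. = FALSE)
  x <- array(image / 255, dim = c(dim(image), 1L))
  y <- denoiser_forward(model, x)$out
  clip255(matrix(y, nrow(image), ncol(image)) * 255)
}

#' Train a despeckler on clean/noisy image pairs
#'
#' Mini-batch Adam on mean-squared error over \[0, 1\]-scaled intensities.
#'
#' @param model A `fluidcam_denoiser`.
#' @param noisy,clean Lists of grayscale matrices in \[0, 255\], pairwise
#'   aligned.
#' @param epochs Number of passes.
#' @param seed RNG seed (shuffling).
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param verbose Print per-epoch loss.
#' @return The trained model; `model$log` holds per-epoch mean loss.
#' @export
train_denoiser <- function(model, noisy, clean, epochs, seed = 1L,
                           learning_rate = 1e-3, batch_size = 8L,
                           verbose = FALSE) {
  stopifnot(inherits(model, "fluidcam_denoiser"))
  if (length(noisy) == 0L || length(noisy) != length(clean))
    stop("noisy and clean must be non-empty aligned lists", call. = FALSE)
  if (epochs == 0L) return(model)
  n <- length(noisy)
  xs <- lapply(noisy, function(m) array(m / 255, dim = c(dim(m), 1L)))
  ts <- lapply(clean, function(m) array(m / 255, dim = c(dim(m), 1L)))
  params <- denoiser_params(model)
  opt <- adam_init(params)
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1L, n, by = batch_size)) {
        model <- denoiser_set_params(model, params)
        idx <- perm[b0:min(b0 + batch_size - 1L, n)]
        acc <- NULL
        for (i in idx) {
          fwd <- denoiser_forward(model, xs[[i]])
          err <- fwd$out - ts[[i]]
          ep_loss <- ep_loss + mean(err^2)
          g <- denoiser_backward(model, fwd, 2 * err / length(err))
          acc <- nn_grad_accumulate(acc, g)
        }
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(idx)
        step <- adam_step(opt, params, acc, learning_rate)
        opt <- step$state
        params <- step$params
      }
      log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n))
      if (verbose) message(sprintf("epoch %d  mse %.6f", ep, ep_loss / n))
    }
  })
  model <- denoiser_set_params(model, params)
  model$log <- log
  model
}

#' Peak signal-to-noise ratio between two images
#'
#' @param a,b Same-shape numeric matrices.
#' @param peak Peak signal value (default 255).
#' @return PSNR in decibels (`Inf` for identical images).
#' @export
psnr <- function(a, b, peak = 255) {
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}
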