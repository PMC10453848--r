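## Minimal CNN engine used by the classifier and the despeckler.
##
## Networks are nested lists of "modules"; every module supports a forward
## pass returning (output, cache) and a backward pass returning (input
## gradient, parameter gradients). Convolutions run through im2col patch
## matrices (src/conv_ops.cpp) and BLAS matrix products. Feature tensors are
## H x W x C arrays; vectors (after global average pooling) are plain numeric
## vectors. Single-example passes only: mini-batches are averaged by the
## training loops. Everything is deterministic given the R RNG state.

nn_he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

## ---- module constructors ---------------------------------------------------

nn_conv <- function(kh, kw, cin, cout, stride = 1L, pad = NULL,
                    act = c("relu", "linear")) {
  act <- match.arg(act)
  if (is.null(pad)) pad <- c((kh - 1L) %/% 2L, (kw - 1L) %/% 2L)
  pad <- rep_len(as.integer(pad), 2L)
  list(type = "conv", kh = as.integer(kh), kw = as.integer(kw),
       cin = as.integer(cin), cout = as.integer(cout),
       stride = as.integer(stride), pad = pad, act = act,
       W = nn_he_init(c(kh, kw, cin, cout), kh * kw * cin),
       b = numeric(cout))
}

nn_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.null(mods[[1L]]$type)) mods <- mods[[1L]]
  list(type = "seq", mods = mods)
}

## Parallel branches on a shared input, concatenated along channels.
nn_branch <- function(branches) list(type = "branch", branches = branches)

## out = act(x + scale * inner(x)); inner must preserve the channel count.
nn_residual <- function(inner, scale = 0.2, act = "relu") {
  list(type = "residual", inner = inner, scale = scale, act = act)
}

nn_gap <- function() list(type = "gap")

nn_dropout <- function(rate) list(type = "dropout", rate = rate)

nn_dense <- function(nin, nout) {
  list(type = "dense", nin = as.integer(nin), nout = as.integer(nout),
       W = matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

## ---- forward / backward ----------------------------------------------------

nn_conv_forward <- function(mod, x) {
  d <- dim(x)
  cols <- im2col_cpp(x, d[1L], d[2L], d[3L], mod$kh, mod$kw, mod$stride,
                     mod$pad[1L], mod$pad[2L])
  wm <- matrix(mod$W, nrow = mod$kh * mod$kw * mod$cin, ncol = mod$cout)
  out <- cols %*% wm
  out <- sweep(out, 2L, mod$b, "+")
  ho <- (d[1L] + 2L * mod$pad[1L] - mod$kh) %/% mod$stride + 1L
  wo <- (d[2L] + 2L * mod$pad[2L] - mod$kw) %/% mod$stride + 1L
  y <- array(out, dim = c(ho, wo, mod$cout))
  mask <- NULL
  if (mod$act == "relu") {
    mask <- y > 0
    y[!mask] <- 0
  }
  list(out = y, cache = list(cols = cols, indim = d, mask = mask))
}

nn_conv_backward <- function(mod, cache, gy) {
  if (mod$act == "relu") gy <- gy * cache$mask
  d <- dim(gy)
  gmat <- matrix(gy, nrow = d[1L] * d[2L], ncol = d[3L])
  wm <- matrix(mod$W, nrow = mod$kh * mod$kw * mod$cin, ncol = mod$cout)
  gW <- array(crossprod(cache$cols, gmat), dim = dim(mod$W))
  gb <- colSums(gmat)
  gcols <- tcrossprod(gmat, wm)
  gx <- array(col2im_cpp(gcols, cache$indim[1L], cache$indim[2L], cache$indim[3L],
                         mod$kh, mod$kw, mod$stride, mod$pad[1L], mod$pad[2L]),
              dim = cache$indim)
  list(gin = gx, grads = list(W = gW, b = gb))
}

nn_forward <- function(mod, x, training = FALSE) {
  switch(mod$type,
    conv = nn_conv_forward(mod, x),
    seq = {
      caches <- vector("list", length(mod$mods))
      for (i in seq_along(mod$mods)) {
        r <- nn_forward(mod$mods[[i]], x, training)
        x <- r$out
        caches[[i]] <- r$cache
      }
      list(out = x, cache = caches)
    },
    branch = {
      outs <- vector("list", length(mod$branches))
      caches <- vector("list", length(mod$branches))
      for (i in seq_along(mod$branches)) {
        r <- nn_forward(mod$branches[[i]], x, training)
        outs[[i]] <- r$out
        caches[[i]] <- r$cache
      }
      d <- dim(outs[[1L]])
      nc <- vapply(outs, function(o) dim(o)[3L], integer(1L))
      y <- array(0, dim = c(d[1L], d[2L], sum(nc)))
      at <- 0L
      for (i in seq_along(outs)) {
        y[, , at + seq_len(nc[i])] <- outs[[i]]
        at <- at + nc[i]
      }
      list(out = y, cache = list(caches = caches, nc = nc))
    },
    residual = {
      r <- nn_forward(mod$inner, x, training)
      y <- x + mod$scale * r$out
      mask <- NULL
      if (mod$act == "relu") {
        mask <- y > 0
        y[!mask] <- 0
      }
      list(out = y, cache = list(inner = r$cache, mask = mask))
    },
    gap = {
      d <- dim(x)
      list(out = colMeans(matrix(x, d[1L] * d[2L], d[3L])),
           cache = list(indim = d))
    },
    dropout = {
      if (training && mod$rate > 0) {
        keep <- stats::runif(length(x)) >= mod$rate
        y <- x * keep / (1 - mod$rate)
        list(out = y, cache = list(keep = keep))
      } else {
        list(out = x, cache = list(keep = NULL))
      }
    },
    dense = list(out = drop(crossprod(mod$W, x)) + mod$b, cache = list(x = x)),
    stop("unknown module type: ", mod$type)
  )
}

nn_backward <- function(mod, cache, gy) {
  switch(mod$type,
    conv = nn_conv_backward(mod, cache, gy),
    seq = {
      n <- length(mod$mods)
      grads <- vector("list", n)
      for (i in rev(seq_len(n))) {
        r <- nn_backward(mod$mods[[i]], cache[[i]], gy)
        gy <- r$gin
        grads[i] <- list(r$grads)   # [i] <- list(): keep NULL placeholders
      }
      list(gin = gy, grads = grads)
    },
    branch = {
      grads <- vector("list", length(mod$branches))
      gin <- NULL
      at <- 0L
      for (i in seq_along(mod$branches)) {
        gslice <- gy[, , at + seq_len(cache$nc[i]), drop = FALSE]
        at <- at + cache$nc[i]
        r <- nn_backward(mod$branches[[i]], cache$caches[[i]], gslice)
        gin <- if (is.null(gin)) r$gin else gin + r$gin
        grads[i] <- list(r$grads)
      }
      list(gin = gin, grads = grads)
    },
    residual = {
      if (!is.null(cache$mask)) gy <- gy * cache$mask
      r <- nn_backward(mod$inner, cache$inner, mod$scale * gy)
      list(gin = gy + r$gin, grads = r$grads)
    },
    gap = {
      d <- cache$indim
      g <- array(rep(gy, each = d[1L] * d[2L]) / (d[1L] * d[2L]), dim = d)
      list(gin = g, grads = NULL)
    },
    dropout = {
      if (!is.null(cache$keep)) gy <- gy * cache$keep / (1 - mod$rate)
      list(gin = gy, grads = NULL)
    },
    dense = list(gin = drop(mod$W %*% gy),
                 grads = list(W = tcrossprod(cache$x, gy), b = gy)),
    stop("unknown module type: ", mod$type)
  )
}

## ---- parameter flattening and Adam ----------------------------------------

nn_params <- function(mod, path = "m") {
  out <- list()
  if (mod$type %in% c("conv", "dense")) {
    out[[paste0(path, "/W")]] <- mod$W
    out[[paste0(path, "/b")]] <- mod$b
  } else if (mod$type == "seq") {
    for (i in seq_along(mod$mods))
      out <- c(out, nn_params(mod$mods[[i]], paste0(path, "/", i)))
  } else if (mod$type == "branch") {
    for (i in seq_along(mod$branches))
      out <- c(out, nn_params(mod$branches[[i]], paste0(path, "/b", i)))
  } else if (mod$type == "residual") {
    out <- c(out, nn_params(mod$inner, paste0(path, "/r")))
  }
  out
}

nn_set_params <- function(mod, params, path = "m") {
  if (mod$type %in% c("conv", "dense")) {
    mod$W <- params[[paste0(path, "/W")]]
    mod$b <- params[[paste0(path, "/b")]]
  } else if (mod$type == "seq") {
    for (i in seq_along(mod$mods))
      mod$mods[[i]] <- nn_set_params(mod$mods[[i]], params, paste0(path, "/", i))
  } else if (mod$type == "branch") {
    for (i in seq_along(mod$branches))
      mod$branches[[i]] <- nn_set_params(mod$branches[[i]], params, paste0(path, "/b", i))
  } else if (mod$type == "residual") {
    mod$inner <- nn_set_params(mod$inner, params, paste0(path, "/r"))
  }
  mod
}

## Flattens a gradient tree (as returned by nn_backward) with the same names
## as nn_params so the optimizer can walk both in lockstep.
nn_flatten_grads <- function(mod, grads, path = "m") {
  out <- list()
  if (mod$type %in% c("conv", "dense")) {
    out[[paste0(path, "/W")]] <- grads$W
    out[[paste0(path, "/b")]] <- grads$b
  } else if (mod$type == "seq") {
    for (i in seq_along(mod$mods))
      out <- c(out, nn_flatten_grads(mod$mods[[i]], grads[[i]], paste0(path, "/", i)))
  } else if (mod$type == "branch") {
    for (i in seq_along(mod$branches))
      out <- c(out, nn_flatten_grads(mod$branches[[i]], grads[[i]], paste0(path, "/b", i)))
  } else if (mod$type == "residual") {
    out <- c(out, nn_flatten_grads(mod$inner, grads, paste0(path, "/r")))
  }
  out
}

nn_grad_accumulate <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

nn_param_count <- function(mod) {
  sum(vapply(nn_params(mod), length, numeric(1L)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
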