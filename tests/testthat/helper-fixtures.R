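## Shared fixtures: analytic CAM interfaces, phantom training sets, and a
## lazily trained lesion-sensitive tiny classifier reused across test files.

## Toy CAM interface with a linear head: score(class) = sum_k W[k, class] *
## mean(A_k). Gradients are exact and constant per channel, which makes
## every CAM technique analytically checkable.
toy_cam_iface <- function(A, Wc, analysis = c(16L, 16L)) {
  cam_interface(
    activations = function(image) A,
    head_score = function(Aa, cls) {
      d <- dim(Aa)
      sum(colMeans(matrix(Aa, d[1L] * d[2L], d[3L])) * Wc[, cls])
    },
    head_grad = function(Aa, cls) {
      d <- dim(Aa)
      array(rep(Wc[, cls], each = d[1L] * d[2L]) / (d[1L] * d[2L]), dim = d)
    },
    analysis_size = analysis)
}

## Balanced lesion-present / lesion-absent slice set from two phantoms.
phantom_training_set <- function(n_per_class, height = 64L, width = 96L,
                                 seed = 11L, pathology = "IRF") {
  counts_pos <- c(IRF = 0L, SRF = 0L, PED = 0L)
  counts_pos[pathology] <- 1L
  pos <- generate_cscan(phantom_spec(height = height, width = width,
                                     n_slices = n_per_class,
                                     lesion_counts = counts_pos, seed = seed))
  neg <- generate_cscan(phantom_spec(height = height, width = width,
                                     n_slices = n_per_class,
                                     lesion_counts = c(IRF = 0L, SRF = 0L, PED = 0L),
                                     seed = seed + 1L))
  list(images = c(lapply(seq_len(n_per_class), function(s) pos$cscan$slices[, , s]),
                  lapply(seq_len(n_per_class), function(s) neg$cscan$slices[, , s])),
       labels = rep(c(1L, 0L), each = n_per_class),
       pos = pos, neg = neg)
}

## One small trained classifier shared by the CAM smoke tests (built on
## first use, then cached for the remainder of the run).
trained_tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- phantom_training_set(30L, seed = 31L)
      cfg <- model_config("tiny", input_size = 96L, learning_rate = 3e-3)
      m <- build_classifier(cfg, seed = 7L, pathology = "IRF")
      cache <<- train_classifier(m, ds$images, ds$labels, epochs = 20L,
                                 seed = 7L, batch_size = 8L)
    }
    cache
  }
})

## Independent scalar-queue breadth-first region growing (seed reference).
oracle_region_grow <- function(image, seeds, thr, conn = 8L) {
  h <- nrow(image)
  w <- ncol(image)
  offs <- if (conn == 8L) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  out <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(seeds))) {
    ref <- image[seeds$row[i], seeds$col[i]]
    reg <- matrix(FALSE, h, w)
    reg[seeds$row[i], seeds$col[i]] <- TRUE
    queue <- list(c(seeds$row[i], seeds$col[i]))
    while (length(queue) > 0L) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      for (k in seq_len(nrow(offs))) {
        nr <- p[1L] + offs[k, 1L]
        nc <- p[2L] + offs[k, 2L]
        if (nr >= 1 && nr <= h && nc >= 1 && nc <= w && !reg[nr, nc] &&
            abs(image[nr, nc] - ref) < thr) {
          reg[nr, nc] <- TRUE
          queue <- c(queue, list(c(nr, nc)))
        }
      }
    }
    out <- out | reg
  }
  out
}

## Exhaustive Otsu oracle: minimize the within-class (intra-class) variance
## over all 256 candidate thresholds; smallest minimizer wins.
oracle_otsu_threshold <- function(levels) {
  counts <- tabulate(levels + 1L, 256L)
  n <- sum(counts)
  best_t <- NA_integer_
  best_v <- Inf
  for (t in 0:255) {
    lo <- levels[levels <= t]
    hi <- levels[levels > t]
    v0 <- if (length(lo) > 0L) mean((lo - mean(lo))^2) else 0
    v1 <- if (length(hi) > 0L) mean((hi - mean(hi))^2) else 0
    v <- length(lo) / n * v0 + length(hi) / n * v1
    if (v < best_v - 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

random_mask <- function(h, w, p = 0.5) matrix(stats::runif(h * w) < p, h, w)
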