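## Class activation mapping.
##
## Every technique produces a per-pixel relevance heat map in [0, 1] at the
## analysis resolution (the model input resolution), from the activations A^k
## of the model's final convolutional stage and, depending on the technique,
## gradients of the target-class score with respect to those activations,
## masked forward passes, or channel ablations. Heat maps are binarized by
## in-package Otsu thresholding and fused across techniques by the >= 3-of-5
## pixelwise majority rule (Ensemble-CAM).

#' Heat map container
#'
#' @param values Numeric matrix in \[0, 1\].
#' @param technique Name of the producing technique.
#' @param slice_ref Optional `(scan_id, slice_index)` annotation.
#' @param target_class Optional pathology / class annotation.
#' @return Object of class `heatmap`.
#' @export
heatmap <- function(values, technique = NA_character_, slice_ref = NULL,
                    target_class = NULL) {
  if (!is.matrix(values) || min(values) < 0 || max(values) > 1)
    stop("heat map values must form a matrix in [0, 1]", call. = FALSE)
  structure(list(values = values, technique = technique,
                 slice_ref = slice_ref, target_class = target_class),
            class = "heatmap")
}

heatmap_values <- function(x) if (inherits(x, "heatmap")) x$values else x

#' CAM model interface
#'
#' The capability surface every CAM technique needs, decoupled from any
#' particular model implementation: classifier models are converted
#' automatically, and tests can supply hand-built analytic models.
#'
#' @param activations `function(image) -> H x W x K array`: activations of
#'   the target (final) convolutional stage.
#' @param head_score `function(A, class_index) -> scalar`: the target-class
#'   score (pre-softmax logit) computed from the target-stage activations.
#' @param head_grad `function(A, class_index) -> array like A`: gradient of
#'   the class score with respect to the activations. Required by the
#'   gradient-based techniques.
#' @param forward_score `function(image, class_index) -> scalar`: class
#'   score of a full forward pass (used by Score-CAM's masked passes);
#'   defaults to `head_score(activations(image), class_index)`.
#' @param analysis_size `c(height, width)` of the produced heat maps.
#' @return Object of class `cam_interface`.
#' @export
cam_interface <- function(activations, head_score, head_grad = NULL,
                          forward_score = NULL, analysis_size) {
  if (is.null(forward_score))
    forward_score <- function(image, class_index)
      head_score(activations(image), class_index)
  structure(list(activations = activations, head_score = head_score,
                 head_grad = head_grad, forward_score = forward_score,
                 analysis_size = as.integer(analysis_size)),
            class = "cam_interface")
}

as_cam_iface <- function(model) {
  if (inherits(model, "cam_interface")) return(model)
  if (inherits(model, "fluidcam_model")) return(model_cam_interface(model))
  stop("model exposes no CAM capabilities (need a cam_interface or a ",
       "fluidcam classifier)", call. = FALSE)
}

need_grad <- function(iface) {
  if (is.null(iface$head_grad))
    stop("model does not expose activation gradients", call. = FALSE)
}

## Weighted channel combination -> ReLU -> upsample -> min-max normalize.
## The shared tail of every technique.
cam_combine <- function(A, w, analysis_size, technique, guard_relu = TRUE) {
  d <- dim(A)
  m <- matrix(A, d[1L] * d[2L], d[3L]) %*% w
  m <- matrix(m, d[1L], d[2L])
  if (guard_relu) m <- pmax(m, 0)
  m <- resize_bilinear(m, analysis_size[1L], analysis_size[2L])
  m <- pmax(m, 0)                      # bilinear interpolation cannot
  heatmap(minmax01(m), technique)      # introduce negatives, but be safe
}

#' Grad-CAM heat map
#'
#' Channel weights are the spatial means of the class-score gradient with
#' respect to the final convolutional activations; the weighted activation
#' sum is rectified, upsampled bilinearly to the analysis resolution and
#' min-max normalized (an all-zero map stays all-zero).
#'
#' @param model A classifier model or [cam_interface()].
#' @param image Grayscale matrix in \[0, 255\].
#' @param target_class Class index of the score to explain (default 2, the
#'   pathology-present class).
#' @return A [heatmap()].
#' @export
grad_cam <- function(model, image, target_class = 2L) {
  iface <- as_cam_iface(model)
  need_grad(iface)
  A <- iface$activations(image)
  G <- iface$head_grad(A, target_class)
  w <- colMeans(matrix(G, prod(dim(G)[1:2]), dim(G)[3L]))
  cam_combine(A, w, iface$analysis_size, "gradcam")
}

#' Grad-CAM++ heat map
#'
#' Per-pixel weights `alpha = g^2 / (2 g^2 + S_k g^3)` (with `g` the
#' class-score gradient at each activation pixel and `S_k` the spatial sum
#' of channel k, `0/0 -> 0`), combined with rectified gradients into channel
#' weights `w_k = sum(alpha * relu(g))`. This is the closed form of the
#' second/third-order derivative weighting for an exponentially transformed
#' class score, exact when the score head is linear in the target
#' activations (as it is after global average pooling).
#'
#' @inheritParams grad_cam
#' @return A [heatmap()].
#' @export
grad_cam_pp <- function(model, image, target_class = 2L) {
  iface <- as_cam_iface(model)
  need_grad(iface)
  A <- iface$activations(image)
  G <- iface$head_grad(A, target_class)
  d <- dim(A)
  S <- colSums(matrix(A, d[1L] * d[2L], d[3L]))
  denom <- 2 * G^2 + sweep(G^3, 3L, S, "*")
  alpha <- ifelse(abs(denom) < 1e-12, 0, G^2 / denom)
  w <- colSums(matrix(alpha * pmax(G, 0), d[1L] * d[2L], d[3L]))
  cam_combine(A, w, iface$analysis_size, "gradcampp")
}

#' Score-CAM heat map
#'
#' Gradient-free: each activation channel, upsampled and min-max normalized,
#' masks the input image (pixel-wise product); channel weights are the
#' softmax over channels of the masked-input score increase relative to an
#' all-zero baseline image.
#'
#' @inheritParams grad_cam
#' @return A [heatmap()].
#' @export
score_cam <- function(model, image, target_class = 2L) {
  iface <- as_cam_iface(model)
  A <- iface$activations(image)
  K <- dim(A)[3L]
  base <- iface$forward_score(image * 0, target_class)
  scores <- vapply(seq_len(K), function(k) {
    u <- minmax01(resize_bilinear(A[, , k], nrow(image), ncol(image)))
    iface$forward_score(image * u, target_class) - base
  }, numeric(1L))
  cam_combine(A, softmax(scores), iface$analysis_size, "scorecam")
}

#' Ablation-CAM heat map
#'
#' Gradient-free: channel weights are the relative score drop
#' `w_k = (y - y_k) / y` when activation channel k is zeroed; weights are 0
#' when the unablated score magnitude is below 1e-12.
#'
#' @inheritParams grad_cam
#' @return A [heatmap()].
#' @export
ablation_cam <- function(model, image, target_class = 2L) {
  iface <- as_cam_iface(model)
  A <- iface$activations(image)
  K <- dim(A)[3L]
  y <- iface$head_score(A, target_class)
  w <- if (abs(y) < 1e-12) {
    numeric(K)
  } else {
    vapply(seq_len(K), function(k) {
      Ak <- A
      Ak[, , k] <- 0
      (y - iface$head_score(Ak, target_class)) / y
    }, numeric(1L))
  }
  cam_combine(A, w, iface$analysis_size, "ablationcam")
}

#' Self-Matching-CAM heat map
#'
#' Channel weights are obtained by matching each upsampled, min-max
#' normalized activation map against the normalized input image (cosine
#' similarity); the weighted activation sum then follows the common CAM
#' contract (ReLU, upsample, normalize).
#'
#' @inheritParams grad_cam
#' @return A [heatmap()].
#' @export
self_matching_cam <- function(model, image, target_class = 2L) {
  iface <- as_cam_iface(model)
  A <- iface$activations(image)
  K <- dim(A)[3L]
  ref <- minmax01(resize_bilinear(image, iface$analysis_size[1L],
                                  iface$analysis_size[2L]))
  nref <- sqrt(sum(ref^2))
  w <- vapply(seq_len(K), function(k) {
    u <- minmax01(resize_bilinear(A[, , k], iface$analysis_size[1L],
                                  iface$analysis_size[2L]))
    nu <- sqrt(sum(u^2))
    if (nu == 0 || nref == 0) 0 else sum(u * ref) / (nu * nref)
  }, numeric(1L))
  cam_combine(A, w, iface$analysis_size, "selfmatching")
}

#' Otsu binarization of a heat map
#'
#' Quantizes the \[0, 1\] map to 256 gray levels, picks the threshold
#' maximizing the between-class variance over the 256-bin histogram (ties
#' broken towards the smallest threshold) and returns `level > t*`. A
#' constant map yields an all-false mask.
#'
#' @param map A [heatmap()] or numeric matrix in \[0, 1\].
#' @return Logical matrix with attributes `threshold` (the chosen level) and
#'   `provenance`.
#' @export
otsu_binarize <- function(map) {
  technique <- if (inherits(map, "heatmap")) map$technique else NA_character_
  v <- heatmap_values(map)
  if (!is.matrix(v) || length(v) == 0L)
    stop("heat map must be a non-empty matrix", call. = FALSE)
  if (min(v) < 0 || max(v) > 1)
    stop("heat map values must lie in [0, 1]", call. = FALSE)
  lev <- round(v * 255)
  if (min(lev) == max(lev)) {
    out <- matrix(FALSE, nrow(v), ncol(v))
    attr(out, "threshold") <- NA_integer_
  } else {
    t_star <- otsu_threshold(tabulate(lev + 1L, 256L))
    out <- lev > t_star
    attr(out, "threshold") <- t_star
  }
  attr(out, "provenance") <- technique
  out
}

## Between-class variance maximization over thresholds 0..255 on a 256-bin
## histogram; smallest threshold wins ties (within floating slack).
otsu_threshold <- function(counts) {
  n <- sum(counts)
  levels <- 0:255
  cum_n <- cumsum(counts)
  cum_s <- cumsum(counts * levels)
  mu <- cum_s[256L] / n
  w0 <- cum_n / n
  sigma_b <- numeric(256L)
  valid <- w0 > 0 & w0 < 1
  mu0 <- cum_s[valid] / cum_n[valid]
  w0v <- w0[valid]
  sigma_b[valid] <- w0v / (1 - w0v) * (mu0 - mu)^2
  best <- max(sigma_b)
  which(sigma_b >= best - 1e-12)[1L] - 1L
}

#' Ensemble-CAM majority fusion of five binarized maps
#'
#' Fuses the Otsu-binarized maps of the five techniques: a pixel is
#' foreground when at least three of the five maps agree. Equivalently, the
#' five binary maps are summed and thresholded at three.
#'
#' @param masks List of exactly five logical matrices of identical shape.
#' @return Logical matrix with attribute `provenance = "ensemble"`.
#' @export
ensemble_cam <- function(masks) {
  if (!is.list(masks) || length(masks) != 5L)
    stop("ensemble fusion needs exactly 5 binary masks", call. = FALSE)
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L)
    stop("ensemble masks must share one shape", call. = FALSE)
  total <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  out <- total >= 3L
  attr(out, "provenance") <- "ensemble"
  out
}

cam_techniques <- c(gradcam = "grad_cam", gradcampp = "grad_cam_pp",
                    scorecam = "score_cam", ablationcam = "ablation_cam",
                    selfmatching = "self_matching_cam")

#' Compute a heat map by technique name
#'
#' @inheritParams grad_cam
#' @param technique One of `"gradcam"`, `"gradcampp"`, `"scorecam"`,
#'   `"ablationcam"`, `"selfmatching"`.
#' @return A [heatmap()].
#' @export
compute_cam <- function(model, image, technique, target_class = 2L) {
  technique <- match.arg(technique, names(cam_techniques))
  fn <- get(cam_techniques[[technique]], mode = "function")
  fn(model, image, target_class)
}

#' Binarized CAM mask by technique name, including ensemble fusion
#'
#' Computes the heat map(s) for `technique` and Otsu-binarizes; for
#' `"ensemble"` all five techniques are binarized and fused by the 3-of-5
#' majority rule.
#'
#' @inheritParams compute_cam
#' @param technique A single technique name or `"ensemble"`.
#' @return Logical matrix at the analysis resolution.
#' @export
cam_binary_mask <- function(model, image, technique, target_class = 2L) {
  if (identical(technique, "ensemble")) {
    masks <- lapply(names(cam_techniques), function(tn)
      otsu_binarize(compute_cam(model, image, tn, target_class)))
    ensemble_cam(masks)
  } else {
    otsu_binarize(compute_cam(model, image, technique, target_class))
  }
}
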