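## Shared image helpers. Pixel conventions used across the package:
## images are numeric matrices (rows x cols) with intensities in [0, 255];
## masks are logical matrices; heat maps are numeric matrices in [0, 1].

#' @useDynLib fluidcam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Bilinear resize of a matrix (or each plane of an H x W x C array).
resize_bilinear <- function(x, h, w) {
  out <- EBImage::resize(x, w = h, h = w, filter = "bilinear")
  r <- EBImage::imageData(out)
  if (is.matrix(x)) r <- matrix(r, nrow = h, ncol = w)
  r
}

## Nearest-neighbour resize (used for masks, after binarization).
resize_nearest <- function(x, h, w) {
  storage <- is.logical(x)
  if (storage) x <- x * 1
  out <- EBImage::resize(x, w = h, h = w, filter = "none")
  r <- matrix(EBImage::imageData(out), nrow = h, ncol = w)
  if (storage) r <- r > 0.5
  r
}

## Min-max normalization to [0, 1] with an all-constant guard: a flat map
## (including all-zero) maps to all-zero.
minmax01 <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo <= 0) return(array(0, dim = dim(x)))
  (x - lo) / (hi - lo)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Nearest-neighbour resize of a binary mask
#'
#' Used to carry binarized CAM maps from the analysis resolution back to the
#' original B-scan resolution before pixel counting; resizing after
#' binarization keeps the mask strictly binary.
#'
#' @param mask Logical matrix.
#' @param height,width Target size in pixels.
#' @return Logical matrix of the requested size.
#' @export
resize_mask <- function(mask, height, width) {
  if (!is_binary_mask(mask)) stop("mask must be a logical matrix", call. = FALSE)
  resize_nearest(mask, height, width)
}

is_binary_mask <- function(m) is.logical(m) && is.matrix(m)

stopifnot_mask_pair <- function(a, b) {
  if (!is_binary_mask(a) || !is_binary_mask(b))
    stop("masks must be logical matrices", call. = FALSE)
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

## Grayscale matrix -> replicated 3-channel array scaled to [-1, 1] (the
## usual Inception-family input convention), resized to the model input
## resolution.
prep_image <- function(image, input_size) {
  x <- resize_bilinear(image / 255, input_size, input_size)
  array(rep(clip01(x) * 2 - 1, 3L), dim = c(input_size, input_size, 3L))
}
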