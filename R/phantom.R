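## Synthetic OCT phantom generator.
##
## Real spectral-domain OCT B-scans of exudative maculopathy show a stack of
## bright retinal bands over a hyper-reflective retinal pigment epithelium
## (RPE) line, with fluid pockets appearing as dark regions: intraretinal
## fluid (IRF) inside the neurosensory bands, subretinal fluid (SRF) between
## the bands and the RPE, and pigmented epithelial detachment (PED) as a dome
## lifting the RPE. The phantom emulates exactly those contrast relations --
## bright layered bands, a bright RPE, a mid-bright choroid, and dark
## elliptical lesions whose interiors sit in a configurable low-intensity
## band -- plus multiplicative gamma-distributed speckle. It makes every
## downstream stage testable without clinical data; it is not a physical
## OCT simulation.

#' Specification for a synthetic OCT C-scan phantom
#'
#' @param height,width B-scan size in pixels.
#' @param n_slices Number of B-scans in the C-scan.
#' @param lesion_counts Named vector/list with entries `IRF`, `SRF`, `PED`:
#'   number of lesions of each pathology placed on every slice (0 = none).
#' @param lesion_intensity_range Two-element `c(lo, hi)` grayscale band from
#'   which lesion interior intensities are drawn. The default `c(25, 50)` is
#'   the low-intensity band that fluid regions occupy in 8-bit OCT B-scans
#'   and that selective thresholding exploits.
#' @param background_band_intensities Mean gray levels of the retinal
#'   sub-bands, top to bottom.
#' @param speckle_shape,speckle_scale Gamma shape k and scale theta of the
#'   per-pixel multiplicative speckle field. The defaults (k = 40,
#'   theta = 1/40) give a mean-one, mildly speckled render emulating B-scans
#'   after acquisition-side despeckling; pass e.g. k = 4, theta = 1/4 for
#'   heavy raw speckle.
#' @param seed Integer RNG seed; the phantom is fully determined by it.
#' @param scan_id Identifier stored in the generated C-scan.
#' @param lesion_semi_axes Optional `c(a, b)`: fixed row/column semi-axes of
#'   every lesion ellipse in pixels. By default axes are drawn relative to
#'   the image size. Lesions that cannot fit the retinal band geometry raise
#'   a generation error.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 256L, n_slices = 32L,
                         lesion_counts = c(IRF = 1L, SRF = 1L, PED = 1L),
                         lesion_intensity_range = c(25, 50),
                         background_band_intensities = c(150, 115, 170, 135),
                         speckle_shape = 40, speckle_scale = 1 / 40,
                         seed = 1L, scan_id = "phantom",
                         lesion_semi_axes = NULL) {
  lesion_counts <- unlist(lesion_counts)
  missing <- setdiff(c("IRF", "SRF", "PED"), names(lesion_counts))
  lesion_counts[missing] <- 0L
  lesion_counts <- lesion_counts[c("IRF", "SRF", "PED")]
  r <- lesion_intensity_range
  if (height < 1 || width < 1 || n_slices < 1)
    stop("height, width and n_slices must all be >= 1", call. = FALSE)
  if (length(r) != 2 || r[1] < 0 || r[2] > 255 || r[1] > r[2])
    stop("lesion_intensity_range must satisfy 0 <= lo <= hi <= 255", call. = FALSE)
  if (speckle_shape <= 0 || speckle_scale <= 0)
    stop("speckle_shape and speckle_scale must be positive", call. = FALSE)
  if (any(lesion_counts < 0))
    stop("lesion counts must be non-negative", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_slices = as.integer(n_slices),
                 lesion_counts = lesion_counts,
                 lesion_intensity_range = r,
                 background_band_intensities = background_band_intensities,
                 speckle_shape = speckle_shape, speckle_scale = speckle_scale,
                 seed = as.integer(seed), scan_id = scan_id,
                 lesion_semi_axes = lesion_semi_axes),
            class = "phantom_spec")
}

## Unseeded speckle kernel shared by apply_speckle() and generate_cscan().
speckle_field <- function(image, shape, scale, clip = TRUE, quantize = FALSE) {
  g <- array(stats::rgamma(length(image), shape = shape, scale = scale),
             dim = dim(image))
  out <- image * g
  if (clip) out <- clip255(out)
  if (quantize) out <- round(out)
  out
}

#' Apply multiplicative gamma-distributed speckle to an image
#'
#' Multiplies every pixel by an i.i.d. gamma(k, theta) draw, the standard
#' model for coherent-imaging speckle used throughout this package. With
#' theta = 1/k the field has unit mean and the expected brightness is
#' preserved.
#'
#' @param image Numeric matrix with values in \[0, 255\].
#' @param shape,scale Gamma shape k > 0 and scale theta > 0.
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   output.
#' @param clip Clip the result to \[0, 255\] (default). Disable to study the
#'   unclipped noise statistics.
#' @param quantize Round to integer gray levels (off by default; the phantom
#'   generator rounds, matching 8-bit image I/O).
#' @return Speckled image, same shape as `image`.
#' @export
apply_speckle <- function(image, shape, scale, seed,
                          clip = TRUE, quantize = FALSE) {
  if (!is.numeric(shape) || !is.numeric(scale) || shape <= 0 || scale <= 0)
    stop("speckle shape and scale must be positive", call. = FALSE)
  withr::with_seed(as.integer(seed),
                   speckle_field(image, shape, scale, clip, quantize))
}

## Fills an elliptical interior; returns a logical matrix.
ellipse_mask <- function(h, w, cr, cc, a, b) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rows - cr) / a)^2 + ((cols - cc) / b)^2 <= 1
}

## Draws lesion interior intensities: a per-lesion base level in the central
## part of the configured band plus small per-pixel jitter, clamped so that
## every noise-free interior pixel stays inside [lo, hi].
lesion_fill <- function(n, range) {
  lo <- range[1]
  hi <- range[2]
  span <- hi - lo
  base <- stats::runif(1, lo + 0.2 * span, hi - 0.3 * span)
  pmin(pmax(base + stats::rnorm(n, 0, 0.08 * span), lo), hi)
}

## Renders one noise-free B-scan plus per-pathology lesion masks.
render_slice <- function(spec) {
  h <- spec$height
  w <- spec$width
  img <- matrix(10, h, w)                       # vitreous
  bands <- spec$background_band_intensities
  phase <- stats::runif(1, 0, 2 * pi)
  amp <- 0.04 * h
  top <- round(0.22 * h + amp * sin(2 * pi * seq_len(w) / w + phase))
  top <- pmax(2L, pmin(as.integer(top), max(2L, h %/% 2L)))
  stack_thick <- max(length(bands), round(0.34 * h))
  rpe_thick <- max(2L, round(0.05 * h))
  sub <- max(1L, stack_thick %/% length(bands))
  for (x in seq_len(w)) {
    r0 <- top[x]
    for (bi in seq_along(bands)) {
      a <- r0 + (bi - 1L) * sub
      b <- min(h, if (bi == length(bands)) r0 + stack_thick - 1L else a + sub - 1L)
      if (a <= h) img[a:min(b, h), x] <- bands[bi]
    }
    ra <- min(h, r0 + stack_thick)
    rb <- min(h, ra + rpe_thick - 1L)
    img[ra:rb, x] <- 205                         # RPE line
    if (rb < h) img[(rb + 1L):h, x] <- 90        # choroid
  }
  rpe_top <- top + stack_thick

  masks <- list(IRF = matrix(FALSE, h, w), SRF = matrix(FALSE, h, w),
                PED = matrix(FALSE, h, w))
  place <- function(pathology) {
    if (!is.null(spec$lesion_semi_axes)) {
      a <- spec$lesion_semi_axes[1]
      b <- spec$lesion_semi_axes[2]
    } else {
      a <- stats::runif(1, 0.045, 0.075) * h     # semi-axis, rows
      b <- stats::runif(1, 0.04, 0.08) * w       # semi-axis, cols
    }
    if (2 * a + 4 > stack_thick + rpe_thick || 2 * b + 4 > w)
      stop("lesion too large to fit the phantom image", call. = FALSE)
    cc <- stats::runif(1, b + 2, w - b - 2)
    ccol <- as.integer(round(cc))
    cr <- switch(pathology,
      IRF = top[ccol] + stats::runif(1, a + 1, stack_thick - a - 1),
      SRF = rpe_top[ccol] - a - 1,               # pocket resting on the RPE
      PED = rpe_top[ccol] + a * 0.3)             # dome lifting the RPE
    cr <- min(max(cr, a + 1), h - a - 1)
    m <- ellipse_mask(h, w, cr, cc, a, b)
    img[m] <<- lesion_fill(sum(m), spec$lesion_intensity_range)
    if (pathology == "PED") {
      ## lifted RPE membrane: a bright arc over the dome, never drawn over
      ## an already placed lesion interior
      taken <- masks$IRF | masks$SRF | masks$PED | m
      for (x in which(colSums(m) > 0)) {
        e <- which(m[, x])[1L]
        if (e > 1L) {
          arc <- max(1L, e - 3L):(e - 1L)
          arc <- arc[!taken[arc, x]]
          img[arc, x] <<- 205
        }
      }
    }
    masks[[pathology]] <<- masks[[pathology]] | m
  }
  for (p in c("IRF", "SRF", "PED"))
    for (k in seq_len(spec$lesion_counts[[p]])) place(p)
  list(image = img, masks = masks)
}

#' Generate a synthetic OCT C-scan with ground truth
#'
#' Renders `n_slices` noise-free B-scans (bright retinal bands, RPE and
#' choroid, dark elliptical IRF/SRF/PED lesions), applies multiplicative
#' gamma speckle, and returns the speckled stack together with the clean
#' render, exact per-pathology lesion masks and per-slice binary labels.
#' Output is fully determined by `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_output`: a list with elements
#'   `cscan` (a [cscan()] holding the speckled 8-bit stack), `clean`
#'   (noise-free array, same shape), `masks` (list of logical
#'   height x width x n_slices arrays named IRF/SRF/PED) and `labels`
#'   (data frame with columns scan_id, slice_index, IRF, SRF, PED).
#' @export
generate_cscan <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    h <- spec$height; w <- spec$width; n <- spec$n_slices
    clean <- array(0, dim = c(h, w, n))
    masks <- list(IRF = array(FALSE, dim = c(h, w, n)),
                  SRF = array(FALSE, dim = c(h, w, n)),
                  PED = array(FALSE, dim = c(h, w, n)))
    for (s in seq_len(n)) {
      r <- render_slice(spec)
      clean[, , s] <- r$image
      for (p in names(masks)) masks[[p]][, , s] <- r$masks[[p]]
    }
    noisy <- array(speckle_field(clean, spec$speckle_shape, spec$speckle_scale,
                                 clip = TRUE, quantize = TRUE),
                   dim = dim(clean))
    labels <- data.frame(
      scan_id = spec$scan_id,
      slice_index = seq_len(n) - 1L,
      IRF = as.integer(apply(masks$IRF, 3L, any)),
      SRF = as.integer(apply(masks$SRF, 3L, any)),
      PED = as.integer(apply(masks$PED, 3L, any)))
    structure(list(cscan = cscan(noisy, scan_id = spec$scan_id),
                   clean = clean, masks = masks, labels = labels),
              class = "phantom_output")
  })
}
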