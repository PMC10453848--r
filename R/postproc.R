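## CAM mask refinement: seeded region growing and selective thresholding.
##
## Both methods target the dark, low-intensity appearance of retinal fluid:
## region growing re-expands from contour centroids of the binarized CAM
## through similar-intensity pixels, while selective thresholding keeps only
## CAM-masked pixels inside a fixed low gray-level band. Neither is suited
## to PED, where the feature of interest is a lifted bright layer rather
## than a fluid pocket; for PED the raw binarized CAM mask is used instead.

## Vectorized neighbour lookup on the pixel grid. `idx` are 1-based linear
## indices (column-major); returns the in-bounds neighbours under the given
## connectivity, with the originating index alongside.
neighbor_pairs <- function(idx, h, w, connectivity = 8L) {
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  offsets <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    offsets <- c(offsets, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  from <- integer(0)
  to <- integer(0)
  for (o in offsets) {
    nr <- r + o[1L]
    nc <- c + o[2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    from <- c(from, idx[ok])
    to <- c(to, (nc[ok] - 1L) * h + nr[ok])
  }
  list(from = from, to = to)
}

## Connected-component labelling by frontier BFS (default 8-connectivity,
## matching the region-growing default).
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask)
  w <- ncol(mask)
  labels <- matrix(0L, h, w)
  current <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    labels[start] <- current
    frontier <- start
    while (length(frontier) > 0L) {
      nb <- unique(neighbor_pairs(frontier, h, w, connectivity)$to)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- current
      frontier <- nb
    }
  }
  labels
}

#' Extract region-growing seed points from a binary mask
#'
#' One seed per connected component (contour) of the mask: the centroid of
#' the component's pixel set, rounded to the nearest pixel and, when the
#' rounded centroid falls outside a non-convex component, snapped to the
#' nearest component pixel.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default) neighbourhood for the component
#'   extraction.
#' @return Data frame with columns `row`, `col`, `source_contour_id`; empty
#'   (zero rows) for an empty mask.
#' @export
extract_seeds <- function(mask, connectivity = 8L) {
  if (!is_binary_mask(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  labels <- label_components(mask, connectivity)
  ids <- seq_len(max(labels))
  rows <- integer(0)
  cols <- integer(0)
  for (id in ids) {
    pix <- which(labels == id)
    pr <- ((pix - 1L) %% nrow(mask)) + 1L
    pc <- ((pix - 1L) %/% nrow(mask)) + 1L
    cr <- as.integer(round(mean(pr)))
    cc <- as.integer(round(mean(pc)))
    if (!mask[cr, cc]) {
      k <- which.min((pr - cr)^2 + (pc - cc)^2)
      cr <- pr[k]
      cc <- pc[k]
    }
    rows <- c(rows, cr)
    cols <- c(cols, cc)
  }
  data.frame(row = rows, col = cols, source_contour_id = ids)
}

#' Seeded region growing
#'
#' Breadth-first expansion from each seed: a frontier neighbour joins the
#' region iff its absolute intensity difference to the reference pixel is
#' strictly below `intensity_threshold`. The reference is the originating
#' seed by default; `reference = "neighbor"` compares against the adjoining
#' region pixel instead (chained similarity). Regions from multiple seeds
#' are unioned. Deterministic for a fixed configuration.
#'
#' @param image Numeric matrix of gray levels.
#' @param seeds Data frame with `row`/`col` columns (as produced by
#'   [extract_seeds()]), or a 2-column matrix.
#' @param intensity_threshold Non-negative inclusion threshold (default 15
#'   gray levels). A threshold of 0 grows nothing: only the seeds remain.
#' @param connectivity 4 or 8 (default) neighbourhood.
#' @param reference `"seed"` (default) or `"neighbor"`.
#' @return Logical matrix marking the grown regions.
#' @export
region_grow <- function(image, seeds, intensity_threshold = 15,
                        connectivity = 8L,
                        reference = c("seed", "neighbor")) {
  reference <- match.arg(reference)
  if (intensity_threshold < 0)
    stop("intensity_threshold must be >= 0", call. = FALSE)
  if (!(connectivity %in% c(4L, 8L)))
    stop("connectivity must be 4 or 8", call. = FALSE)
  if (is.matrix(seeds)) seeds <- data.frame(row = seeds[, 1L], col = seeds[, 2L])
  h <- nrow(image)
  w <- ncol(image)
  out <- matrix(FALSE, h, w)
  if (nrow(seeds) == 0L) return(out)
  if (any(seeds$row < 1L | seeds$row > h | seeds$col < 1L | seeds$col > w))
    stop("seed out of image bounds", call. = FALSE)
  for (i in seq_len(nrow(seeds))) {
    start <- (seeds$col[i] - 1L) * h + seeds$row[i]
    ref_val <- image[start]
    region <- matrix(FALSE, h, w)
    region[start] <- TRUE
    frontier <- start
    while (length(frontier) > 0L) {
      np <- neighbor_pairs(frontier, h, w, connectivity)
      keep <- !region[np$to]
      cand <- np$to[keep]
      from <- np$from[keep]
      ok <- if (reference == "seed") {
        abs(image[cand] - ref_val) < intensity_threshold
      } else {
        abs(image[cand] - image[from]) < intensity_threshold
      }
      nxt <- unique(cand[ok])
      region[nxt] <- TRUE
      frontier <- nxt
    }
    out <- out | region
  }
  out
}

#' Selective thresholding of a CAM-masked image
#'
#' Takes the pixel-wise product of the image with the binarized CAM mask and
#' keeps only pixels whose gray level falls in the configured low-intensity
#' fluid band: the band applied is 20 to 50 (inclusive), chosen from the
#' histogram spike that fluid interiors produce at gray levels 25-50.
#'
#' @param image Numeric matrix of gray levels in \[0, 255\].
#' @param cam_mask Logical matrix, same shape.
#' @param band_low,band_high Band endpoints (defaults 20 and 50), with
#'   `0 <= band_low <= band_high <= 255`.
#' @param inclusive Include the endpoints (default) or compare strictly.
#' @return Logical matrix; always a subset of `cam_mask`.
#' @export
selective_threshold <- function(image, cam_mask, band_low = 20,
                                band_high = 50, inclusive = TRUE) {
  if (!is_binary_mask(cam_mask))
    stop("cam_mask must be a logical matrix", call. = FALSE)
  if (!identical(dim(image), dim(cam_mask)))
    stop("image and cam_mask shapes differ", call. = FALSE)
  if (band_low < 0 || band_high > 255 || band_low > band_high)
    stop("band must satisfy 0 <= low <= high <= 255", call. = FALSE)
  roi <- image * cam_mask
  inside <- if (inclusive) roi >= band_low & roi <= band_high
            else roi > band_low & roi < band_high
  cam_mask & inside
}

#' Gray-level histogram of a CAM region of interest
#'
#' 256-bin histogram (gray levels 0-255, zero-count bins included) over the
#' mask-true pixels only; intensities are rounded to the nearest level.
#'
#' @param image Numeric matrix in \[0, 255\].
#' @param cam_mask Logical matrix, same shape.
#' @return Integer vector of length 256, named by gray level `0:255`; its
#'   sum equals the number of mask-true pixels.
#' @export
roi_histogram <- function(image, cam_mask) {
  if (!is_binary_mask(cam_mask))
    stop("cam_mask must be a logical matrix", call. = FALSE)
  if (!identical(dim(image), dim(cam_mask)))
    stop("image and cam_mask shapes differ", call. = FALSE)
  vals <- round(image[cam_mask])
  counts <- tabulate(vals + 1L, nbins = 256L)
  names(counts) <- 0:255
  counts
}
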