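## C-scan container and plain-format I/O: multipage 8-bit grayscale TIFF or
## per-slice PNG directories for stacks and masks, CSV for labels, YAML for
## configs, JSON for run manifests. Slice indices are 0-based on disk; pixel
## coordinates are (row, col), 1-based inside R as usual.

#' OCT C-scan container
#'
#' An ordered stack of equally shaped 8-bit grayscale B-scans plus the
#' scanner voxel geometry used for volume computation.
#'
#' @param slices A height x width x n numeric array, a single matrix, or a
#'   list of matrices with intensities in \[0, 255\].
#' @param scan_id Identifier string.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `cscan` with elements `scan_id`, `slices`
#'   (3-D array) and `geometry`.
#' @export
cscan <- function(slices, scan_id = "scan", geometry = voxel_geometry()) {
  if (is.list(slices)) {
    dims <- unique(lapply(slices, dim))
    if (length(dims) != 1L)
      stop("all slices must have the same shape", call. = FALSE)
    slices <- array(unlist(slices), dim = c(dims[[1L]], length(slices)))
  }
  if (is.matrix(slices)) slices <- array(slices, dim = c(dim(slices), 1L))
  if (length(dim(slices)) != 3L || dim(slices)[3L] < 1L)
    stop("a C-scan needs at least one 2-D slice", call. = FALSE)
  if (min(slices) < 0 || max(slices) > 255)
    stop("slice intensities must lie in [0, 255]", call. = FALSE)
  stopifnot(inherits(geometry, "voxel_geometry"))
  structure(list(scan_id = scan_id, slices = slices, geometry = geometry),
            class = "cscan")
}

#' @export
print.cscan <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<cscan '%s': %d slices of %d x %d, voxel %.1f x %.1f x %.1f um>\n",
              x$scan_id, d[3L], d[1L], d[2L],
              x$geometry$dx, x$geometry$dy, x$geometry$dz))
  invisible(x)
}

n_slices <- function(x) dim(x$slices)[3L]

#' Read a C-scan from a multipage TIFF or a PNG slice directory
#'
#' Directories are read in lexicographic filename order; only 8-bit
#' grayscale input is accepted.
#'
#' @param path A `.tif`/`.tiff` file or a directory of `.png` slices.
#' @param scan_id Identifier (defaults to the file/directory name).
#' @param geometry A [voxel_geometry()] attached to the scan.
#' @return A [cscan()].
#' @export
read_cscan <- function(path, scan_id = NULL,
                       geometry = voxel_geometry()) {
  if (is.null(scan_id))
    scan_id <- sub("\\.[^.]*$", "", basename(path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no .png slices in ", path, call. = FALSE)
    slices <- lapply(files, read_gray_png)
  } else {
    if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    slices <- lapply(pages, function(p) {
      bits <- attr(p, "bits.per.sample")
      if (!is.null(bits) && bits != 8L)
        stop("only 8-bit grayscale TIFF input is supported (got ",
             bits, "-bit)", call. = FALSE)
      flatten_gray(p) * 255
    })
  }
  cscan(lapply(slices, round), scan_id = scan_id, geometry = geometry)
}

## Collapses an RGB(A) plane to grayscale; [0,1] scale in and out.
flatten_gray <- function(p) {
  if (length(dim(p)) == 3L) p <- p[, , 1L]
  p
}

read_gray_png <- function(file) {
  p <- png::readPNG(file, info = TRUE)
  info <- attr(p, "info")
  if (!is.null(info$bit.depth) && info$bit.depth != 8L)
    stop("only 8-bit PNG input is supported (got ", info$bit.depth,
         "-bit): ", file, call. = FALSE)
  flatten_gray(p) * 255
}

#' Write a C-scan as a multipage TIFF or a PNG slice directory
#'
#' @param x A [cscan()].
#' @param path Destination: a `.tif`/`.tiff` filename for a multipage stack,
#'   anything else is treated as a directory receiving zero-padded
#'   `000.png`, `001.png`, ... slices.
#' @return `path`, invisibly. The round trip through [read_cscan()] is
#'   lossless on pixel data and slice order.
#' @export
write_cscan <- function(x, path) {
  stopifnot(inherits(x, "cscan"))
  n <- n_slices(x)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(n), function(s) x$slices[, , s] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (s in seq_len(n))
      png::writePNG(x$slices[, , s] / 255,
                    file.path(path, sprintf("%03d.png", s - 1L)))
  }
  invisible(path)
}

#' Write / read a stack of binary masks as 0/255 PNG slices
#'
#' @param masks Logical height x width x n array (or matrix).
#' @param path Directory for the PNG slices.
#' @return `write_masks` returns `path` invisibly; `read_masks` returns a
#'   logical array.
#' @export
write_masks <- function(masks, path) {
  if (is.matrix(masks)) masks <- array(masks, dim = c(dim(masks), 1L))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_len(dim(masks)[3L]))
    png::writePNG((masks[, , s]) * 1,
                  file.path(path, sprintf("%03d.png", s - 1L)))
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no .png masks in ", path, call. = FALSE)
  slices <- lapply(files, function(f) read_gray_png(f) > 127)
  array(unlist(slices), dim = c(dim(slices[[1L]]), length(slices)))
}

#' Read a per-slice pathology label table
#'
#' @param path CSV file with header `scan_id, slice_index, IRF, SRF, PED`
#'   and 0/1 values.
#' @return Data frame with those columns, pathology columns as integers.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("scan_id", "slice_index", "IRF", "SRF", "PED")
  if (!identical(names(df), want))
    stop("label file must have header: ", paste(want, collapse = ", "),
         call. = FALSE)
  key <- paste(df$scan_id, df$slice_index)
  if (anyDuplicated(key)) {
    stop("duplicate (scan_id, slice_index) row at line ",
         which(duplicated(key))[1L] + 1L, call. = FALSE)
  }
  for (p in c("IRF", "SRF", "PED")) {
    bad <- !(df[[p]] %in% c(0L, 1L))
    if (any(bad))
      stop("label values must be 0 or 1; bad value in column ", p,
           " at line ", which(bad)[1L] + 1L, call. = FALSE)
    df[[p]] <- as.integer(df[[p]])
  }
  df
}

#' @rdname read_labels
#' @param labels Label data frame as returned by [generate_cscan()].
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Blue -> cyan -> yellow ramp: yellow marks the most relevant regions.
heat_rgb <- function(heat) {
  ramp <- grDevices::colorRamp(c("#00004c", "#0080ff", "#00e5e5", "#ffff33"))
  rgb <- ramp(as.vector(clip01(heat))) / 255
  array(rgb, dim = c(dim(heat), 3L))
}

gray_rgb <- function(img) array(rep(img / 255, 3L), dim = c(dim(img), 3L))

#' Render a per-slice report panel
#'
#' Writes the functional replacement of an interactive review screen: the
#' input B-scan, the CAM heat-map overlay, the binary map, and (when
#' available) the ground truth, side by side in one PNG.
#'
#' @param image Grayscale B-scan matrix in \[0, 255\].
#' @param heatmap A [heatmap] object or matrix in \[0, 1\] at any
#'   resolution (resized to the B-scan).
#' @param mask Logical matrix, the binary map at B-scan resolution.
#' @param gt_mask Optional logical ground-truth matrix; when missing a
#'   3-panel variant is written.
#' @param path Output PNG path.
#' @param volume_mm3 Optional volume annotated in the filename.
#' @return The path written, invisibly.
#' @export
render_report <- function(image, heatmap, mask, gt_mask = NULL, path,
                          volume_mm3 = NULL) {
  h <- nrow(image)
  w <- ncol(image)
  hm <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  hm <- resize_bilinear(hm, h, w)
  overlay <- 0.55 * gray_rgb(image) + 0.45 * heat_rgb(hm)
  panels <- list(gray_rgb(image), overlay, gray_rgb(mask * 255))
  if (!is.null(gt_mask)) panels <- c(panels, list(gray_rgb(gt_mask * 255)))
  sep <- array(1, dim = c(h, 2L, 3L))
  strip <- panels[[1L]]
  for (p in panels[-1L]) {
    tmp <- array(0, dim = c(h, dim(strip)[2L] + 2L + w, 3L))
    tmp[, seq_len(dim(strip)[2L]), ] <- strip
    tmp[, dim(strip)[2L] + 1:2, ] <- sep
    tmp[, (dim(strip)[2L] + 3L):dim(tmp)[2L], ] <- p
    strip <- tmp
  }
  if (!is.null(volume_mm3))
    path <- sub("\\.png$", sprintf("_vol%.5fmm3.png", volume_mm3), path)
  png::writePNG(clip01(strip), path)
  invisible(path)
}

#' Write a reproducibility manifest for a pipeline run
#'
#' @param config Named list of run parameters (paths, seed, technique, ...).
#' @param path JSON output path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
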