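## Overlap metrics, confusion-matrix metrics, voxel geometry and per-scan
## fluid volume computation.

#' Jaccard index (intersection over union) of two binary masks
#'
#' @param a,b Logical arrays of identical shape (2-D masks or stacked 3-D
#'   volumes).
#' @param empty_value Value returned when both masks are empty (default 1:
#'   two empty segmentations agree perfectly; set 0 for the stricter
#'   convention).
#' @return Scalar in \[0, 1\].
#' @export
jaccard <- function(a, b, empty_value = 1) {
  check_mask_pair(a, b)
  u <- sum(a | b)
  if (u == 0) return(empty_value)
  sum(a & b) / u
}

#' Dice (Sorensen) coefficient of two binary masks
#'
#' @inheritParams jaccard
#' @return Scalar in \[0, 1\]; algebraically `2 * J / (1 + J)` with `J` the
#'   Jaccard index.
#' @export
dice <- function(a, b, empty_value = 1) {
  check_mask_pair(a, b)
  s <- sum(a) + sum(b)
  if (s == 0) return(empty_value)
  2 * sum(a & b) / s
}

check_mask_pair <- function(a, b) {
  if (!is.logical(a) || !is.logical(b))
    stop("masks must be logical", call. = FALSE)
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  invisible(TRUE)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, sensitivity (recall), specificity and F1 from
#' TP/FP/TN/FN tallies. A metric whose denominator is zero is undefined and
#' reported as `NA`.
#'
#' @param tp,fp,tn,fn Non-negative integer counts; their total must be
#'   positive.
#' @return List of class `classification_metrics` with elements `accuracy`,
#'   `precision`, `sensitivity`, `specificity`, `f1` (full precision; round
#'   for display).
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("all confusion counts are zero; metrics undefined", call. = FALSE)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = div(tp, tp + fp),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    f1 = div(2 * tp, 2 * tp + fp + fn)),
    class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, digits = 4, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s: %s", names(v),
                    formatC(round(v, digits), format = "f", digits = digits)),
            collapse = "  "), "\n")
  invisible(x)
}

#' Scanner voxel geometry
#'
#' Physical size of one image pixel extended along the slice spacing: each
#' mask pixel is treated as a dx x dy x dz cuboid. The defaults are the
#' spectral-domain OCT scanner values 11.7 x 47.2 x 2.0 um.
#'
#' @param dx,dy,dz Cuboid edge lengths in micrometres; all positive.
#' @return Object of class `voxel_geometry`.
#' @export
voxel_geometry <- function(dx = 11.7, dy = 47.2, dz = 2.0) {
  if (any(c(dx, dy, dz) <= 0))
    stop("voxel dimensions must be positive", call. = FALSE)
  structure(list(dx = dx, dy = dy, dz = dz), class = "voxel_geometry")
}

#' Volume of one voxel in cubic micrometres
#'
#' @param g A [voxel_geometry()].
#' @return `dx * dy * dz` in um^3 (1104.48 for the default geometry).
#' @export
pixel_volume <- function(g = voxel_geometry()) {
  stopifnot(inherits(g, "voxel_geometry"))
  g$dx * g$dy * g$dz
}

UM3_PER_MM3 <- 1e9

## Pixel count -> mm^3 under a geometry.
pixels_to_mm3 <- function(n_pixels, g) n_pixels * pixel_volume(g) / UM3_PER_MM3

#' Fluid volume and overlap metrics from per-slice masks
#'
#' The measurement core shared by [cscan_volume()] and by evaluation
#' harnesses that supply externally derived masks: sums mask pixels over the
#' stack, converts to mm^3 via the voxel geometry, and (when ground truth is
#' given) computes volumetric IoU/Dice over the stacked 3-D masks.
#'
#' @param x A [cscan()] (used for scan id, shape and geometry).
#' @param pred_masks Logical height x width x n array of final per-slice
#'   fluid masks at B-scan resolution.
#' @param gt_masks Optional logical array of the same shape with the
#'   ground-truth masks.
#' @param pathology,technique,postproc_method Annotations carried into the
#'   report row.
#' @param geometry Voxel geometry; defaults to the scan's.
#' @return One-row data frame (a volume report): scan_id, pathology,
#'   technique, postproc_method, predicted_volume_mm3,
#'   ground_truth_volume_mm3, volumetric_iou, volumetric_dice,
#'   n_positive_slices.
#' @export
volume_from_masks <- function(x, pred_masks, gt_masks = NULL,
                              pathology = NA_character_,
                              technique = NA_character_,
                              postproc_method = NA_character_,
                              geometry = NULL) {
  stopifnot(inherits(x, "cscan"))
  if (is.null(geometry)) geometry <- x$geometry
  if (!identical(dim(pred_masks), dim(x$slices)))
    stop("pred_masks shape must match the C-scan", call. = FALSE)
  gt_vol <- NA_real_
  iou <- NA_real_
  dc <- NA_real_
  if (!is.null(gt_masks)) {
    if (!identical(dim(gt_masks), dim(x$slices)))
      stop("gt_masks shape must match the C-scan", call. = FALSE)
    gt_vol <- pixels_to_mm3(sum(gt_masks), geometry)
    iou <- jaccard(pred_masks, gt_masks)
    dc <- dice(pred_masks, gt_masks)
  }
  data.frame(
    scan_id = x$scan_id, pathology = pathology, technique = technique,
    postproc_method = postproc_method,
    predicted_volume_mm3 = pixels_to_mm3(sum(pred_masks), geometry),
    ground_truth_volume_mm3 = gt_vol,
    volumetric_iou = iou, volumetric_dice = dc,
    n_positive_slices = sum(apply(pred_masks, 3L, any)),
    stringsAsFactors = FALSE)
}

#' Per-C-scan fluid volume through the full visualization pipeline
#'
#' For every slice whose positive prediction score exceeds the gate
#' (strictly), computes the CAM heat map for the requested technique,
#' binarizes it by Otsu thresholding, resizes the binary map back to B-scan
#' resolution (nearest neighbour, after binarization), refines it with the
#' chosen post-processing method on the original intensities, and sums mask
#' pixels times the voxel volume over the stack.
#'
#' @param x A [cscan()].
#' @param model A trained classifier from [build_classifier()] /
#'   [train_classifier()] for the requested pathology, or `NULL` when
#'   `cam_masks` supplies externally derived masks.
#' @param pathology One of `"IRF"`, `"SRF"`, `"PED"`.
#' @param technique `"gradcam"`, `"gradcampp"`, `"scorecam"`,
#'   `"ablationcam"`, `"selfmatching"` or `"ensemble"` (majority fusion of
#'   all five).
#' @param postproc_method `"selective"`, `"region_grow"` or `"none"`. The
#'   refinement methods target dark fluid; for PED (layer detachment) use
#'   `"none"`, i.e. the raw binarized CAM.
#' @param gate Prediction-score gate in (0, 1); a slice enters the
#'   visualization stage only if its positive score is strictly greater.
#' @param geometry Voxel geometry; defaults to the scan's.
#' @param gt_masks Optional ground-truth logical array for volumetric
#'   IoU/Dice and ground-truth volume.
#' @param gt_labels Optional 0/1 vector of per-slice ground-truth labels.
#'   Required by `restrict_to_true_positives`; if `gate_on_labels` is set it
#'   replaces the classifier gate entirely (evaluation harness mode).
#' @param gate_on_labels Gate slices on `gt_labels` instead of prediction
#'   scores.
#' @param restrict_to_true_positives Only slices that are classification
#'   true positives (score passes the gate AND the label is positive)
#'   contribute masks -- an evaluation mode; deployment gates on scores
#'   alone.
#' @param cam_masks Optional list (length = slices) of logical masks at
#'   B-scan resolution standing in for the binarized CAM output, e.g.
#'   oracle masks when benchmarking the post-processing chain.
#' @param denoiser Optional despeckling model from [build_denoiser()]:
#'   slices are denoised before classification, visualization and
#'   refinement. `NULL` bypasses denoising and the pipeline consumes the
#'   raw images unchanged.
#' @param region_config,selective_config Parameter lists forwarded to
#'   [region_grow()] / [selective_threshold()].
#' @return A one-row volume report; see [volume_from_masks()].
#' @export
cscan_volume <- function(x, model = NULL, pathology = "IRF",
                         technique = "gradcam",
                         postproc_method = c("selective", "region_grow", "none"),
                         gate = 0.5, geometry = NULL, gt_masks = NULL,
                         gt_labels = NULL, gate_on_labels = FALSE,
                         restrict_to_true_positives = FALSE,
                         cam_masks = NULL, denoiser = NULL,
                         region_config = list(), selective_config = list()) {
  stopifnot(inherits(x, "cscan"))
  postproc_method <- match.arg(postproc_method)
  n <- n_slices(x)
  d <- dim(x$slices)
  if (is.null(model) && is.null(cam_masks))
    stop("either a classifier model or cam_masks must be supplied", call. = FALSE)
  if (!is.null(model) && !is.null(model$pathology) &&
      model$pathology != pathology)
    stop("model was trained for pathology '", model$pathology,
         "', not '", pathology, "'", call. = FALSE)
  if ((gate_on_labels || restrict_to_true_positives) && is.null(gt_labels))
    stop("gt_labels required for label gating / true-positive restriction",
         call. = FALSE)
  pred <- array(FALSE, dim = d)
  for (s in seq_len(n)) {
    image <- x$slices[, , s]
    if (!is.null(denoiser)) image <- denoise(denoiser, image)
    pass <- if (gate_on_labels) {
      gt_labels[s] == 1L
    } else {
      score <- predict(model, image)$positive_score
      ok <- score > gate
      if (restrict_to_true_positives) ok <- ok && gt_labels[s] == 1L
      ok
    }
    if (!pass) next
    m <- if (!is.null(cam_masks)) {
      cam_masks[[s]]
    } else {
      resize_nearest(cam_binary_mask(model, image, technique), d[1L], d[2L])
    }
    m <- switch(postproc_method,
      none = m,
      selective = do.call(selective_threshold,
                          c(list(image = image, cam_mask = m), selective_config)),
      region_grow = do.call(region_grow,
                            c(list(image = image, seeds = extract_seeds(m)),
                              region_config)))
    pred[, , s] <- m
  }
  volume_from_masks(x, pred, gt_masks = gt_masks, pathology = pathology,
                    technique = technique, postproc_method = postproc_method,
                    geometry = geometry)
}

#' Cohort summary of volume reports
#'
#' Mean and population standard deviation of IoU, Dice, predicted and
#' ground-truth volume per (pathology, technique, postproc_method) group --
#' the cohort-level layout used to compare visualization techniques.
#'
#' @param reports Data frame of one-row volume reports (row-bound).
#' @return Data frame with one row per group.
#' @export
cohort_summary <- function(reports) {
  if (!is.data.frame(reports) || nrow(reports) == 0L)
    stop("reports must be a non-empty data frame", call. = FALSE)
  pop_sd <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_real_)
    sqrt(mean((v - mean(v))^2))
  }
  key <- interaction(reports$pathology, reports$technique,
                     reports$postproc_method, drop = TRUE)
  rows <- lapply(split(reports, key), function(g) {
    data.frame(
      pathology = g$pathology[1L], technique = g$technique[1L],
      postproc_method = g$postproc_method[1L], n_scans = nrow(g),
      iou_mean = mean(g$volumetric_iou, na.rm = TRUE),
      iou_sd = pop_sd(g$volumetric_iou),
      dice_mean = mean(g$volumetric_dice, na.rm = TRUE),
      dice_sd = pop_sd(g$volumetric_dice),
      predicted_vol_mean = mean(g$predicted_volume_mm3, na.rm = TRUE),
      predicted_vol_sd = pop_sd(g$predicted_volume_mm3),
      ground_truth_vol_mean = mean(g$ground_truth_volume_mm3, na.rm = TRUE),
      ground_truth_vol_sd = pop_sd(g$ground_truth_volume_mm3),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Anti-VEGF treatment response category from fluid volumes
#'
#' A patient is a Responder when the post-treatment fluid volume has
#' decreased by strictly more than 10% of the pre-treatment volume;
#' increases, unchanged volumes and reductions of 10% or less are
#' Nonresponders.
#'
#' @param pre_volume,post_volume Fluid volumes (same units, e.g. mm^3);
#'   `pre_volume` must be positive.
#' @return `"Responder"` or `"Nonresponder"`.
#' @export
responder_status <- function(pre_volume, post_volume) {
  if (!is.finite(pre_volume) || pre_volume <= 0)
    stop("pre-treatment volume must be positive", call. = FALSE)
  if ((pre_volume - post_volume) / pre_volume > 0.10) "Responder"
  else "Nonresponder"
}
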