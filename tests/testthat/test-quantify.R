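test_that("Jaccard and Dice match hand-enumerated overlaps", {
  a <- matrix(FALSE, 2, 2); a[1, 1] <- a[1, 2] <- TRUE
  b <- matrix(FALSE, 2, 2); b[1, 2] <- b[2, 2] <- TRUE
  expect_equal(jaccard(a, b), 1 / 3)
  expect_equal(dice(a, b), 0.5)
  expect_equal(jaccard(a, a), 1)
  expect_equal(dice(a, a), 1)
  disj <- matrix(FALSE, 2, 2); disj[2, 1] <- TRUE
  expect_equal(jaccard(a, disj), 0)
  expect_equal(dice(a, disj), 0)
  empty <- matrix(FALSE, 2, 2)
  expect_equal(jaccard(empty, empty), 1)       # documented convention
  expect_equal(jaccard(empty, empty, empty_value = 0), 0)
  expect_error(jaccard(a, matrix(FALSE, 3, 3)), "shapes")
  expect_error(dice(a, matrix(1, 2, 2)), "logical")
})

test_that("Dice is 2J/(1+J) and bounded by Jaccard on random pairs", {
  set.seed(27)
  for (trial in 1:1000) {
    a <- random_mask(6, 6)
    b <- random_mask(6, 6)
    j <- jaccard(a, b)
    d <- dice(a, b)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_true(j <= d || abs(j - d) < 1e-12)
    expect_true(j >= 0 && d <= 1)
  }
})

test_that("degenerate confusion counts give NA metrics, not errors", {
  m <- classification_metrics(tp = 0, fp = 0, tn = 10, fn = 0)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
  expect_error(classification_metrics(0, 0, 0, 0), "zero")
  expect_error(classification_metrics(-1, 0, 5, 0), "non-negative")
})

test_that("voxel volume arithmetic follows the scanner geometry", {
  expect_equal(pixel_volume(voxel_geometry()), 11.7 * 47.2 * 2.0)
  expect_equal(pixel_volume(voxel_geometry(1, 1, 1)), 1)
  expect_error(voxel_geometry(dx = 0), "positive")
  ## linearity: an N-pixel mask weighs N voxel volumes
  masks <- array(FALSE, dim = c(10, 10, 3))
  masks[1:5, , 2] <- TRUE
  cs <- cscan(array(0, dim = c(10, 10, 3)))
  rep <- volume_from_masks(cs, masks)
  expect_equal(rep$predicted_volume_mm3, 50 * pixel_volume() / 1e9)
  expect_equal(rep$n_positive_slices, 1L)
})

test_that("volume is invariant to slice ordering", {
  set.seed(28)
  imgs <- array(runif(8 * 8 * 4, 0, 255), dim = c(8, 8, 4))
  masks <- array(runif(8 * 8 * 4) < 0.3, dim = c(8, 8, 4))
  v1 <- volume_from_masks(cscan(imgs), masks)$predicted_volume_mm3
  perm <- c(3, 1, 4, 2)
  v2 <- volume_from_masks(cscan(imgs[, , perm]),
                          masks[, , perm])$predicted_volume_mm3
  expect_equal(v1, v2)
})

test_that("feeding ground truth as prediction gives perfect overlap", {
  ph <- generate_cscan(phantom_spec(height = 48, width = 64, n_slices = 3,
                                    seed = 44))
  rep <- volume_from_masks(ph$cscan, ph$masks$SRF, gt_masks = ph$masks$SRF,
                           pathology = "SRF")
  expect_equal(rep$volumetric_iou, 1)
  expect_equal(rep$volumetric_dice, 1)
  expect_equal(rep$predicted_volume_mm3, rep$ground_truth_volume_mm3)
  ## report identity: dice = 2*iou/(1+iou)
  expect_equal(rep$volumetric_dice,
               2 * rep$volumetric_iou / (1 + rep$volumetric_iou),
               tolerance = 1e-9)
})

test_that("true-positive restriction and label gating control slice entry", {
  ph <- generate_cscan(phantom_spec(height = 32, width = 48, n_slices = 4,
                                    lesion_counts = c(IRF = 1, SRF = 0, PED = 0),
                                    seed = 46))
  full <- lapply(1:4, function(s) matrix(TRUE, 32, 48))
  labels <- c(1L, 0L, 1L, 0L)
  rep <- cscan_volume(ph$cscan, cam_masks = full, postproc_method = "none",
                      gt_labels = labels, gate_on_labels = TRUE)
  expect_equal(rep$n_positive_slices, 2L)
  expect_equal(rep$predicted_volume_mm3,
               2 * 32 * 48 * pixel_volume() / 1e9)
  expect_error(cscan_volume(ph$cscan, cam_masks = full,
                            postproc_method = "none", gate_on_labels = TRUE),
               "gt_labels")
  expect_error(cscan_volume(ph$cscan, postproc_method = "none"),
               "model or cam_masks")
})

test_that("a model trained for one pathology refuses another", {
  model <- structure(list(pathology = "SRF"), class = "fluidcam_model")
  cs <- cscan(array(0, dim = c(8, 8, 1)))
  expect_error(cscan_volume(cs, model, pathology = "IRF"), "SRF")
})

test_that("cohort summaries aggregate with population deviation", {
  r1 <- data.frame(scan_id = "a", pathology = "IRF", technique = "gradcam",
                   postproc_method = "selective", predicted_volume_mm3 = 0.3,
                   ground_truth_volume_mm3 = 0.2, volumetric_iou = 0.2,
                   volumetric_dice = 2 * 0.2 / 1.2, n_positive_slices = 3L)
  single <- cohort_summary(r1)
  expect_equal(single$iou_sd, 0)
  r2 <- r1
  r2$scan_id <- "b"
  r2$volumetric_iou <- 0.4
  two <- cohort_summary(rbind(r1, r2))
  expect_equal(two$iou_mean, 0.3)
  expect_equal(two$iou_sd, 0.1)                # population, not sample, sd
  r3 <- r1
  r3$technique <- "scorecam"
  out <- cohort_summary(rbind(r1, r2, r3))
  expect_equal(nrow(out), 2L)                  # one row per distinct triple
  expect_error(cohort_summary(data.frame()), "non-empty")
})

test_that("responder categorization uses a strict 10% reduction rule", {
  expect_equal(responder_status(1.0, 0.85), "Responder")
  expect_equal(responder_status(1.0, 0.90), "Nonresponder")   # exactly 10%
  expect_equal(responder_status(1.0, 1.20), "Nonresponder")   # increase
  expect_equal(responder_status(1.0, 1.00), "Nonresponder")   # unchanged
  expect_error(responder_status(0, 0.5), "positive")
})
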