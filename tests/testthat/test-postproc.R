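test_that("seed extraction returns component centroids", {
  mask <- matrix(FALSE, 10, 10)
  mask[3:7, 3:7] <- TRUE                       # filled 5x5 square
  seeds <- extract_seeds(mask)
  expect_equal(nrow(seeds), 1L)
  expect_equal(c(seeds$row, seeds$col), c(5L, 5L))

  mask[1, 10] <- TRUE                          # second, disjoint blob
  seeds2 <- extract_seeds(mask)
  expect_equal(nrow(seeds2), 2L)
  for (i in 1:2) expect_true(mask[seeds2$row[i], seeds2$col[i]])

  expect_equal(nrow(extract_seeds(matrix(FALSE, 4, 4))), 0L)
  expect_error(extract_seeds(matrix(1, 3, 3)), "logical")
})

test_that("a centroid outside a non-convex component snaps onto it", {
  mask <- matrix(FALSE, 9, 9)
  mask[1:9, 1] <- TRUE                         # C shape: centroid in the gap
  mask[1, 1:9] <- TRUE
  mask[9, 1:9] <- TRUE
  seeds <- extract_seeds(mask)
  expect_equal(nrow(seeds), 1L)
  expect_true(mask[seeds$row[1], seeds$col[1]])
})

test_that("region growing matches direct expectations", {
  img <- matrix(77, 5, 5)
  expect_equal(sum(region_grow(img, data.frame(row = 2, col = 4), 15)), 25L)

  img <- matrix(200, 9, 9)
  img[4:6, 4:6] <- 30                          # dark block on bright field
  grown <- region_grow(img, data.frame(row = 5, col = 5), 15)
  expect_equal(unname(which(grown)), unname(which(img == 30)))

  expect_equal(sum(region_grow(img, data.frame(row = 5, col = 5), 0)), 1L)
  expect_error(region_grow(img, data.frame(row = 0, col = 5), 15), "bounds")
  expect_error(region_grow(img, data.frame(row = 1, col = 1), -1), ">= 0")
})

test_that("region growing equals a breadth-first oracle on random images", {
  set.seed(23)
  for (trial in 1:100) {
    img <- matrix(sample(seq(0, 90, by = 10), 256, replace = TRUE), 16, 16)
    seeds <- data.frame(row = sample(16, 2), col = sample(16, 2))
    thr <- sample(c(5, 15, 25), 1)
    conn <- sample(c(4L, 8L), 1)
    expect_identical(region_grow(img, seeds, thr, connectivity = conn),
                     oracle_region_grow(img, seeds, thr, conn))
  }
})

test_that("region growing is monotone in the intensity threshold", {
  set.seed(24)
  for (trial in 1:20) {
    img <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
    seeds <- data.frame(row = sample(12, 1), col = sample(12, 1))
    small <- region_grow(img, seeds, 10)
    large <- region_grow(img, seeds, 40)
    expect_true(all(large[small]))
  }
})

test_that("neighbor-referenced growth chains along gradual ramps", {
  img <- matrix(rep(seq(0, 190, by = 10), each = 5), 5, 20)
  seeds <- data.frame(row = 3, col = 1)
  chained <- region_grow(img, seeds, 15, reference = "neighbor")
  expect_equal(sum(chained), 100L)             # 10-step ramp floods fully
  anchored <- region_grow(img, seeds, 15, reference = "seed")
  expect_equal(sum(anchored), 10L)             # |I - seed| < 15: two columns
})

test_that("selective thresholding keeps exactly the configured band", {
  img <- matrix(0:255, 16, 16)
  kept <- selective_threshold(img, matrix(TRUE, 16, 16))
  expect_equal(sum(kept), 31L)                 # integers 20..50 inclusive
  expect_equal(range(img[kept]), c(20, 50))

  m <- matrix(TRUE, 2, 2)
  expect_true(selective_threshold(matrix(35, 2, 2), m)[1, 1])
  expect_false(selective_threshold(matrix(60, 2, 2), m)[1, 1])
  expect_false(any(selective_threshold(img, matrix(FALSE, 16, 16))))
  expect_error(selective_threshold(img, matrix(TRUE, 2, 2)), "shapes")
  expect_error(selective_threshold(img, matrix(TRUE, 16, 16),
                                   band_low = 60, band_high = 50), "low <= high")
})

test_that("selective output is always a subset of the CAM mask", {
  set.seed(25)
  for (trial in 1:20) {
    img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    cam <- random_mask(10, 10)
    out <- selective_threshold(img, cam)
    expect_true(all(cam[out]))
  }
})

test_that("ROI histograms conserve counts and find the fluid spike", {
  img <- matrix(0, 6, 6)
  cam <- matrix(FALSE, 6, 6)
  cam[1:2, 1:5] <- TRUE
  img[cam] <- 42
  h <- roi_histogram(img, cam)
  expect_length(h, 256L)
  expect_equal(unname(h[as.character(42)]), 10L)
  expect_equal(sum(h), sum(cam))

  set.seed(26)
  img2 <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  cam2 <- random_mask(20, 20)
  expect_equal(sum(roi_histogram(img2, cam2)), sum(cam2))

  ## phantom lesion region: modal gray level inside the configured band
  ph <- generate_cscan(phantom_spec(height = 64, width = 96, n_slices = 1,
                                    seed = 33))
  hist_roi <- roi_histogram(ph$cscan$slices[, , 1], ph$masks$IRF[, , 1])
  modal <- as.integer(names(which.max(hist_roi)))
  expect_gte(modal, 25 * 0.6)                  # speckled tail allowance
  expect_lte(modal, 50 * 1.4)
})
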