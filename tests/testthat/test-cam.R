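img16 <- matrix(runif(256, 0, 255), 16, 16)

test_that("Grad-CAM reduces to the analytic map for a linear head", {
  set.seed(42)
  A <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  Wc <- matrix(rnorm(6), 3, 2)
  toy <- toy_cam_iface(A, Wc)
  hm <- grad_cam(toy, img16)
  ## constant gradient Wc[k, 2] / (h*w) -> channel weights Wc[, 2] / 16
  map <- pmax(matrix(matrix(A, 16, 3) %*% (Wc[, 2] / 16), 4, 4), 0)
  ref <- fluidcam:::minmax01(pmax(fluidcam:::resize_bilinear(map, 16, 16), 0))
  expect_equal(hm$values, ref, tolerance = 1e-12)
  expect_true(min(hm$values) >= 0 && max(hm$values) <= 1)
})

test_that("Grad-CAM on y = mean(A) is the normalized rectified activation", {
  set.seed(7)
  A1 <- array(rnorm(16), c(4, 4, 1))
  toy <- toy_cam_iface(A1, matrix(c(0, 1), 1, 2))  # y_2 = mean(A)
  hm <- grad_cam(toy, img16)
  ref <- fluidcam:::minmax01(pmax(
    fluidcam:::resize_bilinear(pmax(A1[, , 1], 0), 16, 16), 0))
  expect_equal(hm$values, ref, tolerance = 1e-12)
})

test_that("exposed gradients agree with finite differences of the head score", {
  model <- build_classifier(model_config("tiny", input_size = 32L), seed = 9)
  iface <- model_cam_interface(model)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  A <- iface$activations(img)
  G <- iface$head_grad(A, 2L)
  eps <- 1e-4
  idx <- sample(length(A), 12)
  for (i in idx) {
    Ap <- A; Ap[i] <- A[i] + eps
    Am <- A; Am[i] <- A[i] - eps
    fd <- (iface$head_score(Ap, 2L) - iface$head_score(Am, 2L)) / (2 * eps)
    expect_lt(abs(fd - G[i]), 1e-3)
  }
})

test_that("Grad-CAM++ matches a per-pixel loop oracle on a 4x4 map", {
  set.seed(11)
  for (trial in 1:5) {
    A <- array(rnorm(16, sd = 2), c(4, 4, 1))
    Wc <- matrix(rnorm(2), 1, 2)
    toy <- toy_cam_iface(A, Wc)
    hm <- grad_cam_pp(toy, img16)
    G <- toy$head_grad(A, 2L)
    S <- sum(A)
    w <- 0
    for (i in 1:4) for (j in 1:4) {          # scalar per-pixel oracle
      g <- G[i, j, 1]
      denom <- 2 * g^2 + S * g^3
      alpha <- if (abs(denom) < 1e-12) 0 else g^2 / denom
      w <- w + alpha * max(g, 0)
    }
    ref <- fluidcam:::minmax01(pmax(
      fluidcam:::resize_bilinear(pmax(A[, , 1] * w, 0), 16, 16), 0))
    expect_equal(hm$values, ref, tolerance = 1e-6)
  }
})

test_that("Grad-CAM++ with all-negative gradients yields an all-zero map", {
  set.seed(12)
  A <- array(abs(rnorm(16)), c(4, 4, 1))
  toy <- toy_cam_iface(A, matrix(c(0, -1), 1, 2))  # gradient -1/16 everywhere
  expect_true(all(grad_cam_pp(toy, img16)$values == 0))
})

test_that("Grad-CAM++ is proportional to Grad-CAM for a single positive-gradient channel", {
  set.seed(13)
  A <- array(rnorm(16), c(4, 4, 1))
  toy <- toy_cam_iface(A, matrix(c(0, 1), 1, 2))
  expect_equal(grad_cam_pp(toy, img16)$values, grad_cam(toy, img16)$values,
               tolerance = 1e-9)
})

test_that("Score-CAM matches a naive loop oracle and its degenerate cases", {
  set.seed(14)
  A <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  Wc <- matrix(rnorm(6), 3, 2)
  toy <- toy_cam_iface(A, Wc)
  got <- score_cam(toy, img16)
  base <- toy$forward_score(img16 * 0, 2L)
  scores <- numeric(3)
  for (k in 1:3) {                            # naive per-channel loop
    u <- fluidcam:::minmax01(fluidcam:::resize_bilinear(A[, , k], 16, 16))
    scores[k] <- toy$forward_score(img16 * u, 2L) - base
  }
  w <- exp(scores - max(scores)); w <- w / sum(w)
  ref <- fluidcam:::minmax01(pmax(fluidcam:::resize_bilinear(
    pmax(matrix(matrix(A, 16, 3) %*% w, 4, 4), 0), 16, 16), 0))
  expect_equal(got$values, ref, tolerance = 1e-6)

  ## constant logits -> uniform weights
  const <- cam_interface(activations = function(image) A,
                         head_score = function(Aa, cls) 1,
                         analysis_size = c(16L, 16L))
  refu <- fluidcam:::minmax01(pmax(fluidcam:::resize_bilinear(
    pmax(matrix(matrix(A, 16, 3) %*% rep(1 / 3, 3), 4, 4), 0), 16, 16), 0))
  expect_equal(score_cam(const, img16)$values, refu, tolerance = 1e-12)

  ## single channel -> softmax of a singleton is weight 1
  A1 <- array(rnorm(16), c(4, 4, 1))
  toy1 <- toy_cam_iface(A1, matrix(c(0, 1), 1, 2))
  ref1 <- fluidcam:::minmax01(pmax(
    fluidcam:::resize_bilinear(pmax(A1[, , 1], 0), 16, 16), 0))
  expect_equal(score_cam(toy1, img16)$values, ref1, tolerance = 1e-12)
})

test_that("Ablation-CAM weights equal the relative score drops", {
  set.seed(15)
  A <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  Wc <- matrix(rnorm(6), 3, 2)
  Wc[3, 2] <- 0                               # channel 3 cannot move the score
  toy <- toy_cam_iface(A, Wc)
  y <- toy$head_score(A, 2L)
  w <- numeric(3)
  for (k in 1:3) {                            # forward-pass loop oracle
    Ak <- A
    Ak[, , k] <- 0
    w[k] <- (y - toy$head_score(Ak, 2L)) / y
  }
  expect_equal(w[3], 0)
  ref <- fluidcam:::minmax01(pmax(fluidcam:::resize_bilinear(
    pmax(matrix(matrix(A, 16, 3) %*% w, 4, 4), 0), 16, 16), 0))
  expect_equal(ablation_cam(toy, img16)$values, ref, tolerance = 1e-12)

  ## a channel whose ablation halves the score gets weight 0.5
  Ah <- array(1, c(2, 2, 2))
  half <- toy_cam_iface(Ah, matrix(c(0, 0, 1, 1), 2, 2))
  yh <- half$head_score(Ah, 2L)
  A0 <- Ah; A0[, , 1] <- 0
  expect_equal(half$head_score(A0, 2L) / yh, 0.5)
})

test_that("Self-Matching-CAM obeys the heat-map contract and finds lesions", {
  set.seed(16)
  A <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  toy <- toy_cam_iface(A, matrix(rnorm(6), 3, 2))
  h1 <- self_matching_cam(toy, img16)
  expect_identical(dim(h1$values), c(16L, 16L))
  expect_true(min(h1$values) >= 0 && max(h1$values) <= 1)
  expect_equal(self_matching_cam(toy, img16)$values, h1$values)  # deterministic

  model <- trained_tiny_model()
  ds <- phantom_training_set(2L, seed = 61L)
  slice <- ds$pos$cscan$slices[, , 1]
  lesion <- ds$pos$masks$IRF[, , 1]
  hm <- self_matching_cam(model, slice)
  mask <- resize_mask(otsu_binarize(hm), nrow(slice), ncol(slice))
  expect_gt(jaccard(mask, lesion, empty_value = 0), 0)
})

test_that("Otsu binarization agrees with exhaustive threshold search", {
  m <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  bm <- otsu_binarize(m)
  expect_equal(unclass(bm)[, ], m > 0.5, ignore_attr = TRUE)
  expect_false(any(otsu_binarize(matrix(0.42, 6, 6))))   # constant map
  set.seed(18)
  for (trial in 1:100) {
    v <- matrix(runif(64)^sample(c(0.5, 1, 2), 1), 8, 8)
    bm <- otsu_binarize(v)
    t_star <- oracle_otsu_threshold(round(v * 255))
    expect_identical(attr(bm, "threshold"), t_star)
    expect_equal(unclass(bm)[, ], round(v * 255) > t_star, ignore_attr = TRUE)
  }
})

test_that("heat-map normalization is idempotent", {
  set.seed(19)
  v <- fluidcam:::minmax01(matrix(rnorm(64), 8, 8))
  expect_equal(fluidcam:::minmax01(v), v)
})

test_that("Ensemble-CAM is an exact 3-of-5 pixelwise majority", {
  base <- matrix(FALSE, 3, 3)
  m3 <- lapply(1:5, function(i) {m <- base; if (i <= 3) m[2, 2] <- TRUE; m})
  expect_true(ensemble_cam(m3)[2, 2])
  m2 <- lapply(1:5, function(i) {m <- base; if (i <= 2) m[2, 2] <- TRUE; m})
  expect_false(ensemble_cam(m2)[2, 2])
  expect_error(ensemble_cam(m2[1:4]), "exactly 5")
  expect_error(ensemble_cam(c(m2[1:4], list(matrix(FALSE, 2, 2)))), "shape")

  set.seed(20)
  for (trial in 1:100) {
    ms <- lapply(1:5, function(i) random_mask(6, 6))
    fused <- ensemble_cam(ms)
    counts <- Reduce(`+`, lapply(ms, function(m) m * 1L))
    expect_equal(unclass(fused)[, ], counts >= 3L, ignore_attr = TRUE)
    ## permutation invariance
    perm <- sample(5)
    expect_equal(unclass(ensemble_cam(ms[perm]))[, ], unclass(fused)[, ],
                 ignore_attr = TRUE)
    ## monotonicity: adding true pixels never removes output pixels
    ms2 <- ms
    ms2[[1]] <- ms[[1]] | random_mask(6, 6, 0.3)
    expect_true(all(ensemble_cam(ms2)[fused]))
  }
})
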