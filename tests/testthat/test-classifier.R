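test_that("presets carry the published block counts", {
  small <- model_config("small")
  expect_equal(c(small$n_blocks_a, small$n_blocks_b, small$n_blocks_c),
               c(8L, 7L, 4L))
  standard <- model_config("standard")
  expect_equal(c(standard$n_blocks_a, standard$n_blocks_b, standard$n_blocks_c),
               c(10L, 20L, 10L))
  tiny <- model_config("tiny")
  expect_equal(c(tiny$n_blocks_a, tiny$n_blocks_b, tiny$n_blocks_c),
               c(1L, 1L, 1L))
  expect_error(model_config(n_blocks_a = 0), ">= 1")
  expect_error(model_config(n_classes = 3), "fixed at 2")
})

test_that("parameter counts decrease strictly from standard to small to tiny", {
  p_std <- model_param_count(build_classifier(model_config("standard",
                                                           input_size = 48L)))
  p_small <- model_param_count(build_classifier(model_config("small",
                                                             input_size = 48L)))
  p_tiny <- model_param_count(build_classifier(model_config("tiny",
                                                            input_size = 48L)))
  expect_gt(p_std, p_small)
  expect_gt(p_small, p_tiny)
})

test_that("categorical cross-entropy matches direct evaluation", {
  expect_equal(cce_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(cce_loss(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(cce_loss(c(0, 1), c(0.9, 0.1)), -log(0.1))
  ## clamping keeps a hard zero finite
  expect_true(is.finite(cce_loss(c(1, 0), c(0, 1))))
  expect_gte(cce_loss(c(1, 0), c(0, 1)), 0)
  expect_error(cce_loss(c(1, 0, 0), c(0.5, 0.5)), "lengths")
  expect_error(cce_loss(c(1, 1), c(0.5, 0.5)), "one-hot")
})

test_that("predictions are softmax-normalized", {
  model <- build_classifier(model_config("tiny", input_size = 32L), seed = 3)
  img <- matrix(runif(32 * 48, 0, 255), 32, 48)
  p <- predict(model, img)
  expect_equal(sum(p$y_hat), 1, tolerance = 1e-6)
  expect_true(all(p$y_hat >= 0 & p$y_hat <= 1))
  expect_equal(p$positive_score, p$y_hat[2])
  expect_error(predict(model, 1:10), "2-D")
})

test_that("training is seeded, logged, and a no-op for zero epochs", {
  ds <- phantom_training_set(8L, height = 48L, width = 64L, seed = 41L)
  cfg <- model_config("tiny", input_size = 32L, learning_rate = 3e-3)
  m0 <- build_classifier(cfg, seed = 2)
  expect_identical(train_classifier(m0, ds$images, ds$labels, epochs = 0L), m0)
  m1 <- train_classifier(m0, ds$images, ds$labels, epochs = 3L, seed = 5,
                         batch_size = 4L)
  m2 <- train_classifier(m0, ds$images, ds$labels, epochs = 3L, seed = 5,
                         batch_size = 4L)
  expect_identical(m1$log, m2$log)
  expect_identical(fluidcam:::model_all_params(m1),
                   fluidcam:::model_all_params(m2))
  expect_equal(nrow(m1$log), 3L)
  ## the separable phantom task: loss must move downwards
  expect_lt(m1$log$loss[3], m1$log$loss[1])
  expect_error(train_classifier(m0, list(), integer(0), epochs = 1L), "empty")
})

test_that("the prediction gate is strict: only scores above it pass", {
  sp <- phantom_spec(height = 32, width = 48, n_slices = 2,
                     lesion_counts = c(IRF = 1, SRF = 0, PED = 0), seed = 3)
  ph <- generate_cscan(sp)
  fake <- structure(list(pathology = NULL, score = 0.5), class = "fixed_score_model")
  assign("predict.fixed_score_model",
         function(object, image, ...) list(positive_score = object$score),
         envir = globalenv())
  withr::defer(rm("predict.fixed_score_model", envir = globalenv()))
  full <- lapply(1:2, function(s) matrix(TRUE, 32, 48))
  at_gate <- cscan_volume(ph$cscan, fake, cam_masks = full,
                          postproc_method = "none", gate = 0.5)
  expect_equal(at_gate$predicted_volume_mm3, 0)   # exactly 0.5 does not pass
  fake$score <- 0.6
  above <- cscan_volume(ph$cscan, fake, cam_masks = full,
                        postproc_method = "none", gate = 0.5)
  expect_gt(above$predicted_volume_mm3, 0)        # 0.6 enters the CAM stage
})
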