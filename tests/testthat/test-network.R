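# The three-branch classifier: forward-pass contracts, training determinism,
# checkpointing, and a sanity fit on separable data.

test_that("a zeroed fusion layer predicts exactly 0.5 and outputs stay in (0,1)", {
  tf <- tiny_fit()
  fit <- tf$fit
  p0 <- fit$params
  p0$final$W[] <- 0; p0$final$b <- 0
  probs <- gazedistill:::nn_predict_probs(p0, fit$tensors, 1:10, fit$config)
  expect_equal(probs, rep(0.5, 10))
  probs <- predict(fit)
  expect_true(all(probs > 0 & probs < 1))
})

test_that("training checkpoints one parameter snapshot per epoch", {
  tf <- tiny_fit()
  expect_length(tf$fit$checkpoints, tf$fit$config$epochs)
  cp <- checkpoint_set(tf$fit)
  expect_equal(length(cp$theta), tf$fit$config$epochs)
  expect_true(all(cp$etas > 0))
  expect_equal(cp$etas, rep(tf$fit$config$learning_rate, tf$fit$config$epochs))
  # the reference configuration trains 16 epochs by default
  expect_equal(gaze_config()$epochs, 16L)
})

test_that("training is exactly reproducible given the seed", {
  corp <- tiny_corpus(seed = 19L)
  cfg <- tiny_config(epochs = 2L)
  f1 <- gaze_classifier(corp$records, cfg, seed = 5L, split_seed = 2L)
  f2 <- gaze_classifier(corp$records, cfg, seed = 5L, split_seed = 2L)
  expect_identical(gazedistill:::nn_flatten(f1$params),
                   gazedistill:::nn_flatten(f2$params))
  expect_identical(f1$history, f2$history)
  f3 <- gaze_classifier(corp$records, cfg, seed = 6L, split_seed = 2L)
  expect_false(identical(gazedistill:::nn_flatten(f1$params),
                         gazedistill:::nn_flatten(f3$params)))
})

test_that("the forward pass is permutation-equivariant across the batch", {
  tf <- tiny_fit()
  fit <- tf$fit
  idx <- 1:12
  perm <- c(7, 1, 12, 3, 9, 2, 11, 4, 10, 5, 8, 6)
  b1 <- gazedistill:::slice_tensors(fit$tensors, idx)
  b2 <- gazedistill:::slice_tensors(fit$tensors, idx[perm])
  o1 <- gazedistill:::nn_forward(fit$params, b1, fit$config)$p
  o2 <- gazedistill:::nn_forward(fit$params, b2, fit$config)$p
  expect_equal(o2, o1[perm], tolerance = 1e-12)
})

test_that("replaying a checkpoint reproduces that epoch's validation metrics", {
  tf <- tiny_fit()
  fit <- tf$fit
  for (ep in c(1L, fit$config$epochs)) {
    params <- gazedistill:::nn_unflatten(fit$checkpoints[[ep]]$theta, fit$skeleton)
    pv <- gazedistill:::nn_predict_probs(params, fit$tensors, fit$split$val,
                                         fit$config)
    acc <- mean((pv >= 0.5) == (fit$labels[fit$split$val] == 1L))
    expect_equal(acc, fit$history$val_acc[ep])
  }
})

test_that("checkpoint archives round-trip through disk", {
  tf <- tiny_fit()
  cp <- checkpoint_set(tf$fit)
  dir <- withr::local_tempdir()
  save_checkpoints(cp, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- load_checkpoints(dir)
  expect_equal(back$theta, cp$theta)
  expect_equal(back$etas, cp$etas)
  expect_equal(back$epochs, cp$epochs)
})

test_that("degenerate training inputs are rejected or warned about", {
  corp <- tiny_corpus(seed = 23L)
  cfg <- tiny_config(epochs = 1L)
  expect_error(gaze_classifier(list(), cfg), "empty")
  only_td <- which(vapply(corp$records, function(r) r$label, integer(1)) == 0)
  split <- list(train = only_td[1:6], val = only_td[7:8], test = only_td[9:10])
  expect_warning(gaze_classifier(corp$records, cfg, split = split),
                 "single-class")
})

test_that("the classifier fits a separable synthetic set", {
  # class-coded stimulus brightness: the image branch alone separates
  set.seed(41)
  recs <- lapply(1:60, function(i) {
    lab <- i %% 2L
    px <- matrix(runif(32 * 32, min = 0.55 * lab, max = 0.45 + 0.55 * lab), 32, 32)
    im <- stimulus_image(px, sprintf("sep%02d", i))
    sp <- random_scanpath(image_id = im$image_id, W = 32, H = 32,
                          group = if (lab == 1) "ASD" else "TD")
    sample_record(im, sp, fixmap_radius = 3)
  })
  cfg <- tiny_config(epochs = 16L, learning_rate = 3e-3)
  fit <- gaze_classifier(recs, cfg, seed = 2L,
                         split = list(train = 1:60, val = integer(0),
                                      test = integer(0)))
  expect_gte(evaluate_split(fit, 1:60)$accuracy, 0.9)
})

test_that("the fitted object honours the standard modelling interface", {
  tf <- tiny_fit()
  fit <- tf$fit
  expect_named(coef(fit), c("o_img", "o_fix", "o_scnpts", "(Intercept)"))
  expect_equal(residuals(fit), fit$labels - fitted(fit))
  sim <- simulate(fit, nsim = 3)
  expect_equal(dim(sim), c(length(fit$labels), 3))
  expect_true(all(unlist(sim) %in% 0:1))
  expect_output(print(fit), "gaze_classifier")
  s <- summary(fit)
  expect_s3_class(s$test, "gaze_metrics")
  # predict on fresh records matches the stored corpus predictions
  p_new <- predict(fit, newdata = tf$corpus$records[1:4])
  expect_equal(unname(p_new), fit$fitted_probs[1:4], tolerance = 1e-10)
  cls <- predict(fit, type = "class")
  expect_true(all(cls %in% 0:1))
})
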