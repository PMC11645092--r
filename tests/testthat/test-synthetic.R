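# The synthetic gaze generator: determinism, planted effect, bookkeeping.

test_that("the same spec and seed reproduce the corpus byte-for-byte", {
  spec <- synthetic_gaze_spec(n_images = 4, n_participants_per_group = 2,
                              label_noise_rate = 0.25, seed = 8)
  c1 <- build_synthetic_corpus(spec, dir = withr::local_tempdir())
  c2 <- build_synthetic_corpus(spec, dir = withr::local_tempdir())
  f1 <- list.files(c1$dir, recursive = TRUE)
  expect_setequal(f1, list.files(c2$dir, recursive = TRUE))
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(c1$dir, f))),
                 unname(tools::md5sum(file.path(c2$dir, f))),
                 label = f)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$records, `[[`, "label"),
                   lapply(c2$records, `[[`, "label"))
})

test_that("stimuli are deterministic per index with category-dependent regions", {
  spec <- synthetic_gaze_spec(seed = 3)
  s1 <- generate_stimulus(spec, 7, category = "people")
  s2 <- generate_stimulus(spec, 7, category = "people")
  expect_identical(s1$pixels, s2$pixels)
  expect_false(is.null(attr(s1, "social_region")))
  land <- generate_stimulus(spec, 2, category = "landscapes")
  expect_null(attr(land, "social_region"))
  obj <- generate_stimulus(spec, 3, category = "objects")
  expect_null(attr(obj, "social_region"))
  expect_true(all(s1$pixels >= 0 & s1$pixels <= 1))
})

test_that("category draws stay within multinomial bounds at the default mix", {
  spec <- synthetic_gaze_spec(n_images = 30, seed = 12)
  cats <- vapply(seq_len(30), function(j)
    generate_stimulus(spec, j)$category, character(1))
  counts <- table(factor(cats, c("people", "objects", "landscapes")))
  # exact multinomial 99% bounds per category at p = 1/3, n = 30
  lo <- qbinom(0.005, 30, 1/3); hi <- qbinom(0.995, 30, 1/3)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("the in-region probability is honoured at its extremes and mean", {
  spec <- synthetic_gaze_spec(p_social_td = 1, p_social_asd = 0, seed = 5,
                              fixation_range = c(10L, 10L))
  im <- generate_stimulus(spec, 1, category = "people")
  region <- attr(im, "social_region")
  withr::with_seed(2, {
    td <- generate_scanpath(spec, im, "TD")
    asd <- generate_scanpath(spec, im, "ASD")
  })
  infix <- function(s) gazedistill:::in_social_region(s$fixations$x,
                                                      s$fixations$y, region)
  expect_true(all(infix(td)))
  expect_false(any(infix(asd)))

  # 100 TD scanpaths x 10 fixations at p = 0.7: binomial 99% interval
  spec7 <- synthetic_gaze_spec(seed = 5, fixation_range = c(10L, 10L))
  hits <- withr::with_seed(4, {
    sum(vapply(1:100, function(i)
      sum(infix(generate_scanpath(spec7, im, "TD"))), numeric(1)))
  })
  expect_gte(hits, qbinom(0.005, 1000, 0.7))
  expect_lte(hits, qbinom(0.995, 1000, 0.7))
  expect_true(all(td$fixations$duration > 0))
  expect_true(nrow(td$fixations) == 10)
})

test_that("the corpus crosses participants with images and flips exactly", {
  corp <- tiny_corpus(n_images = 10, npp = 5, seed = 6, noise = 0.1)
  expect_length(corp$records, 100)           # 10 images x 2 groups x 5
  expect_equal(sum(corp$truth$flipped), 10)  # round(0.1 * 100)
  expect_equal(corp$truth$observed_label[corp$truth$flipped],
               1L - corp$truth$true_label[corp$truth$flipped])
  labs <- vapply(corp$records, `[[`, integer(1), "label")
  expect_equal(labs, corp$truth$observed_label)
  # zero noise: no flips recorded
  clean <- tiny_corpus(n_images = 3, npp = 2, seed = 6)
  expect_equal(sum(clean$truth$flipped), 0)
  # flip ids reproducible
  corp2 <- tiny_corpus(n_images = 10, npp = 5, seed = 6, noise = 0.1)
  expect_identical(corp$truth$flipped, corp2$truth$flipped)
})

test_that("the planted effect is recoverable by the trivial region classifier", {
  corp <- tiny_corpus(n_images = 12, npp = 6, seed = 14, image_size = c(64L, 64L))
  sf <- social_fixation_fraction(corp)
  ppl <- sf[sf$category == "people", ]
  expect_gte(nrow(ppl), 10)
  acc <- mean((ppl$in_region_fraction < 0.5) == (ppl$true_label == 1))
  expect_gte(acc, 0.75)
  expect_true(all(is.na(sf$in_region_fraction[sf$category != "people"])))
})
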