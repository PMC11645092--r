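# Duration rescaling, duration-proportional replication with jitter, and
# fixation-map rasterization.

test_that("durations rescale linearly onto [1, 100] with half-up rounding", {
  expect_equal(rescale_durations(c(100, 300, 500)), c(1L, 51L, 100L))
  expect_equal(rescale_durations(250), 50L)
  expect_equal(rescale_durations(c(80, 80, 80)), c(50L, 50L, 50L))
  expect_error(rescale_durations(numeric(0)), "empty")
})

test_that("rescaled durations are bounded, anchored and order-preserving", {
  set.seed(21)
  for (rep in 1:50) {
    d <- stats::rlnorm(sample(2:30, 1), log(250), 1)
    s <- rescale_durations(d)
    expect_true(all(s >= 1 & s <= 100))
    expect_equal(s[which.min(d)], 1L)
    expect_equal(s[which.max(d)], 100L)
    expect_true(all(diff(s[order(d)]) >= 0))
    # per-scanpath min/max make the map unit-invariant (ms vs s)
    expect_identical(s, rescale_durations(d / 1000))
  }
})

test_that("replication count equals the scaled duration, replicas stay local", {
  one <- scanpath(data.frame(x = 40, y = 30, duration = 123), image_id = "a")
  # single fixation: degenerate range maps to 50 replicas
  set.seed(4)
  aug <- replicate_and_jitter(one, c(80, 100), jitter_radius = 10)
  expect_equal(length(aug), 50L)
  expect_true(all(abs(aug$fixations$x - 40) <= 10))
  expect_true(all(abs(aug$fixations$y - 30) <= 10))

  sp <- scanpath(data.frame(x = c(5, 50, 95), y = c(5, 40, 75),
                            duration = c(100, 300, 500)), image_id = "a")
  set.seed(9)
  aug <- replicate_and_jitter(sp, c(80, 100), jitter_radius = 10)
  scaled <- rescale_durations(sp)
  expect_equal(length(aug), sum(scaled))
  # replicas preserve source order and the L-infinity bound before clipping
  src <- rep(seq_len(3), times = scaled)
  expect_true(all(abs(aug$fixations$x - sp$fixations$x[src]) <= 10 |
                    aug$fixations$x %in% c(0, 99)))
  expect_true(all(aug$fixations$x >= 0 & aug$fixations$x <= 99))
  expect_true(all(aug$fixations$y >= 0 & aug$fixations$y <= 79))
  expect_true(all(diff(src) >= 0))

  # zero jitter reproduces source coordinates exactly
  aug0 <- replicate_and_jitter(sp, c(80, 100), jitter_radius = 0)
  expect_equal(aug0$fixations$x, sp$fixations$x[src])
  expect_equal(aug0$fixations$y, sp$fixations$y[src])

  expect_error(replicate_and_jitter(sp, NULL), "image_size")
})

test_that("augmentation is reproducible bit-exactly under a fixed seed", {
  set.seed(2)
  sp <- random_scanpath(n = 5)
  a1 <- withr::with_seed(77, replicate_and_jitter(sp, c(80, 100)))
  a2 <- withr::with_seed(77, replicate_and_jitter(sp, c(80, 100)))
  expect_identical(a1, a2)
})

test_that("fixation maps are exact union-of-disks rasters", {
  one <- scanpath(data.frame(x = 50, y = 50, duration = 1), image_id = "a")
  m <- render_fixation_map(one, c(101, 101), radius = 10)
  expect_equal(sum(m), brute_disk_count(50, 50, 10, 101, 101))
  expect_true(all(m %in% c(0, 1)))

  # radius 0 marks exactly the fixation pixels
  two <- scanpath(data.frame(x = c(3, 7), y = c(4, 9), duration = c(1, 1)),
                  image_id = "a")
  m0 <- render_fixation_map(two, c(12, 12), radius = 0)
  expect_equal(sum(m0), 2)
  expect_equal(m0[5, 4], 1)  # (x=3, y=4) -> row y+1, col x+1
  expect_equal(m0[10, 8], 1)

  # overlapping disks: union strictly smaller than twice a single disk
  near <- scanpath(data.frame(x = c(50, 51), y = c(50, 50), duration = c(1, 1)),
                   image_id = "a")
  mu <- render_fixation_map(near, c(101, 101), radius = 10)
  expect_lt(sum(mu), 2 * sum(m))
  # count mode accumulates per-fixation coverage
  mc <- render_fixation_map(near, c(101, 101), radius = 10, mode = "count")
  expect_equal(sum(mc), 2 * sum(m))
  expect_equal(max(mc), 2)

  # permutation invariance in fixation order
  perm <- scanpath(near$fixations[2:1, ], image_id = "a")
  expect_identical(render_fixation_map(perm, c(101, 101), radius = 10), mu)

  # disks are clipped at the raster boundary
  edge <- scanpath(data.frame(x = 0, y = 0, duration = 1), image_id = "a")
  me <- render_fixation_map(edge, c(30, 30), radius = 10)
  expect_equal(sum(me), brute_disk_count(0, 0, 10, 30, 30))
})
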