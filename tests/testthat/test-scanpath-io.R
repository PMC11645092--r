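# Reading, decomposing and writing the aggregated scanpath dialect.

test_that("aggregated files decompose into maximal runs starting at index 0", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 10 20 100", "1 30 40 200", "2 50 60 300",
               "0 11 21 150", "1 31 41 250",
               "0 12 22 120"), path)
  sp <- read_scanpaths(path, group_label = "ASD", image_id = "im1")
  expect_length(sp, 3)
  expect_equal(vapply(sp, length, integer(1)), c(3L, 2L, 1L))
  expect_equal(vapply(sp, function(s) s$participant_index, integer(1)), 1:3)
  expect_true(all(vapply(sp, function(s) s$group_label, character(1)) == "ASD"))
  expect_equal(sp[[2]]$fixations$x, c(11, 31))
  rep <- attr(sp, "parse_report")
  expect_equal(rep$n_scanpaths, 3)
  expect_equal(rep$delimiter, "whitespace")

  # minimal case: a single index-0 row
  writeLines("0 5 6 70", path)
  sp1 <- read_scanpaths(path, image_id = "im1")
  expect_length(sp1, 1)
  expect_equal(length(sp1[[1]]), 1L)
})

test_that("comma and tab delimiters are auto-detected", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0,10,20,100", "1,30,40,200"), path)
  sp <- read_scanpaths(path)
  expect_equal(attr(sp, "parse_report")$delimiter, "comma")
  expect_equal(sp[[1]]$fixations$duration, c(100, 200))
  writeLines(c("0\t10\t20\t100", "1\t30\t40\t200"), path)
  sp <- read_scanpaths(path)
  expect_equal(attr(sp, "parse_report")$delimiter, "tab")
  expect_equal(sp[[1]]$fixations$y, c(20, 40))
})

test_that("malformed files raise informative errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 10 20 100", "2 30 40 200"), path)
  expect_error(read_scanpaths(path), "index 0")
  writeLines(c("0 10 20 100", "1 30 oops 200"), path)
  expect_error(read_scanpaths(path), "line 2")
  writeLines(character(0), path)
  expect_error(read_scanpaths(path), "empty")
  writeLines(c("0 10 20 100", "1 30 40"), path)
  expect_error(read_scanpaths(path), "column")
})

test_that("out-of-bounds fixations are kept but flagged", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 10 20 100", "1 500 40 200"), path)
  sp <- read_scanpaths(path, image_size = c(100, 100))
  expect_equal(length(sp[[1]]), 2L)  # kept
  oob <- attr(sp, "parse_report")$out_of_bounds
  expect_equal(oob$row, 2L)
})

test_that("decompose-then-concatenate round-trips random aggregated files", {
  path <- withr::local_tempfile(fileext = ".txt")
  set.seed(31)
  for (rep in 1:25) {
    n_sp <- sample(1:8, 1)
    sps <- lapply(seq_len(n_sp), function(p) random_scanpath(participant = p))
    write_scanpaths_aggregated(sps, path)
    raw <- readLines(path)
    got <- read_scanpaths(path)
    expect_length(got, n_sp)
    expect_equal(length(got), sum(vapply(strsplit(raw, "\t"),
                                         function(r) r[1] == "0", logical(1))))
    orig <- do.call(rbind, lapply(sps, function(s) s$fixations))
    back <- do.call(rbind, lapply(got, function(s) s$fixations))
    expect_equal(back, orig, ignore_attr = TRUE)
  }
})

test_that("individual scanpath write/read round-trips and is byte-stable", {
  set.seed(7)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  for (rep in 1:20) {
    sp <- random_scanpath()
    write_scanpath(sp, p1)
    got <- read_scanpaths(p1, image_id = sp$image_id)
    expect_length(got, 1)
    expect_equal(got[[1]]$fixations, sp$fixations, ignore_attr = TRUE)
    write_scanpath(got[[1]], p2)
    expect_identical(readLines(p1), readLines(p2))
  }
  # a 2-fixation scanpath writes exactly 2 data rows
  write_scanpath(random_scanpath(n = 2), p1)
  expect_length(readLines(p1), 2)
})

test_that("pairing attaches stimuli without touching fixations", {
  set.seed(13)
  im7 <- stimulus_image(matrix(runif(50 * 60), 50, 60), "img_7", "people")
  im8 <- stimulus_image(matrix(runif(50 * 60), 50, 60), "img_8", "objects")
  sps <- c(lapply(1:3, function(p) random_scanpath(participant = p,
                                                   image_id = "img_7",
                                                   W = 60, H = 50)),
           lapply(1:2, function(p) random_scanpath(participant = p,
                                                   image_id = "img_8",
                                                   W = 60, H = 50)))
  recs <- pair_with_stimuli(sps, list(im7, im8))
  expect_length(recs, 5)
  expect_equal(sum(vapply(recs, function(r) r$image_id, character(1)) == "img_7"), 3)
  for (i in seq_along(recs)) {
    expect_equal(recs[[i]]$scanpath$fixations, sps[[i]]$fixations)
    expect_equal(dim(recs[[i]]$fixation_map), dim(recs[[i]]$image$pixels))
  }
  expect_length(pair_with_stimuli(list(), list(im7)), 0)
  bad <- random_scanpath(image_id = "img_missing")
  expect_error(pair_with_stimuli(list(bad), list(im7)), "img_missing")
})
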