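# Synthetic desk-scale gaze corpus with a planted social-attention effect:
# on "people" images, typically-developing viewers fixate the social region
# (the face-like blob) with higher probability than ASD-like viewers; on
# other categories both groups share the same spatial law, so category
# attribution has a recoverable ground truth. The generator emits the same
# aggregated scanpath text dialect, PNG stimuli and manifest CSV the readers
# consume, so the whole pipeline is exercised through the real file formats.

#' Specification of a synthetic gaze corpus
#'
#' Defaults emulate a small free-viewing study: every participant in each
#' group views every image for a handful of fixations (2-20, matching how
#' sparse real per-participant scanpaths are), fixation durations are
#' log-normal around ~250 ms, and a third of the stimuli are "people" images
#' carrying the planted group effect (in-region fixation probability 0.7 for
#' TD vs 0.3 for ASD).
#'
#' @param n_images number of stimuli.
#' @param n_participants_per_group participants per group (each views every
#'   image).
#' @param image_size `c(height, width)` in pixels.
#' @param category_mix named probabilities over
#'   `c("people", "objects", "landscapes")`.
#' @param p_social_td,p_social_asd probability that a fixation lands inside
#'   the social region on a people image, per group; the planted effect
#'   requires `p_social_td > p_social_asd`.
#' @param fixation_range inclusive range of fixations per scanpath (min 2).
#' @param duration_meanlog,duration_sdlog log-normal duration parameters
#'   (milliseconds).
#' @param label_noise_rate fraction of records whose observed label is
#'   flipped (`round(rate * N)` flips, exactly).
#' @param seed corpus seed; (spec, seed) fully determine every byte.
#' @return List of class `"synthetic_gaze_spec"`.
#' @export
synthetic_gaze_spec <- function(n_images = 30L, n_participants_per_group = 5L,
                                image_size = c(128L, 128L),
                                category_mix = c(people = 1/3, objects = 1/3,
                                                 landscapes = 1/3),
                                p_social_td = 0.7, p_social_asd = 0.3,
                                fixation_range = c(2L, 20L),
                                duration_meanlog = log(250),
                                duration_sdlog = 0.5,
                                label_noise_rate = 0, seed = 1L) {
  stopifnot(p_social_td >= 0, p_social_td <= 1, p_social_asd >= 0,
            p_social_asd <= 1, p_social_td > p_social_asd,
            fixation_range[1] >= 2, label_noise_rate >= 0, label_noise_rate <= 1,
            all(image_size >= 8))
  category_mix <- category_mix / sum(category_mix)
  structure(list(n_images = as.integer(n_images),
                 n_participants_per_group = as.integer(n_participants_per_group),
                 image_size = as.integer(image_size),
                 category_mix = category_mix,
                 p_social_td = p_social_td, p_social_asd = p_social_asd,
                 fixation_range = as.integer(fixation_range),
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog,
                 label_noise_rate = label_noise_rate,
                 seed = as.integer(seed)),
            class = "synthetic_gaze_spec")
}

# Smooth low-frequency texture in [0, 1].
synth_texture <- function(H, W) {
  fy <- stats::runif(2, 0.5, 2); fx <- stats::runif(2, 0.5, 2)
  ph <- stats::runif(4, 0, 2 * pi)
  m <- outer(sin(fy[1] * 2 * pi * seq_len(H) / H + ph[1]),
             sin(fx[1] * 2 * pi * seq_len(W) / W + ph[2])) +
    outer(cos(fy[2] * 2 * pi * seq_len(H) / H + ph[3]),
          cos(fx[2] * 2 * pi * seq_len(W) / W + ph[4]))
  m <- m + matrix(stats::rnorm(H * W, sd = 0.15), H, W)
  (m - min(m)) / (max(m) - min(m) + 1e-12)
}

#' Generate one synthetic stimulus image
#'
#' Deterministic given `(spec$seed, image_index)`. People images carry a
#' bright disk (the face-like social region) whose centre is jittered around
#' the image centre, emulating the central placement of faces in
#' photographs; its position and radius are returned for the ground-truth
#' manifest. Objects images show high-contrast rectangles, landscapes a
#' vertical gradient; landscapes and objects have no social region.
#'
#' @param spec a [synthetic_gaze_spec()].
#' @param image_index 1-based stimulus index.
#' @param category category tag; drawn from `spec$category_mix` when `NULL`.
#' @return A [stimulus_image] with attribute `"social_region"`
#'   (`list(cx, cy, r)` in 0-based pixel coordinates, or `NULL`).
#' @export
generate_stimulus <- function(spec, image_index, category = NULL) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  with_seed(derive_seed(spec$seed, image_index), {
    if (is.null(category))
      category <- sample(names(spec$category_mix), 1, prob = spec$category_mix)
    px <- synth_texture(H, W)
    region <- NULL
    if (category == "landscapes") {
      px <- 0.3 * px + 0.7 * matrix(rep(seq(0.9, 0.1, length.out = H), W), H, W)
    } else if (category == "objects") {
      px <- 0.5 * px
      for (k in seq_len(sample(3:6, 1))) {
        rw <- sample.int(max(2L, W %/% 4), 1); rh <- sample.int(max(2L, H %/% 4), 1)
        rx <- sample.int(W - rw, 1); ry <- sample.int(H - rh, 1)
        px[ry:(ry + rh - 1), rx:(rx + rw - 1)] <- stats::runif(1, 0.6, 1)
      }
    } else if (category == "people") {
      px <- 0.4 * px
      r <- max(3, round(0.2 * min(H, W)))
      cx <- (W - 1) / 2 + stats::runif(1, -0.1, 0.1) * W
      cy <- (H - 1) / 2 + stats::runif(1, -0.1, 0.1) * H
      dd <- outer((seq_len(H) - 1 - cy)^2, (seq_len(W) - 1 - cx)^2, `+`)
      px[dd <= r^2] <- 0.95
      px[dd > r^2 & dd <= (r + 1.5)^2] <- 0.75
      region <- list(cx = cx, cy = cy, r = r)
    }
    im <- stimulus_image(pmin(pmax(px, 0), 1), sprintf("img%03d", image_index),
                         category)
    attr(im, "social_region") <- region
    im
  })
}

in_social_region <- function(x, y, region)
  (x - region$cx)^2 + (y - region$cy)^2 <= region$r^2

#' Generate one synthetic scanpath
#'
#' Fixation count is uniform over `spec$fixation_range`. On people images
#' each fixation independently lands inside the social region with the
#' group's probability (uniform within the disk) and uniformly outside it
#' otherwise; on other categories both groups fixate uniformly (no planted
#' signal). Durations are i.i.d. log-normal milliseconds. Coordinates are
#' integer pixels, 0-based.
#'
#' @param spec a [synthetic_gaze_spec()].
#' @param image a [generate_stimulus()] output (carries the social region).
#' @param group_label `"TD"` or `"ASD"`.
#' @param participant_index ordinal recorded on the scanpath.
#' @return A [scanpath].
#' @export
generate_scanpath <- function(spec, image, group_label = c("TD", "ASD"),
                              participant_index = 1L) {
  group_label <- match.arg(group_label)
  H <- nrow(image$pixels); W <- ncol(image$pixels)
  region <- attr(image, "social_region")
  # sample.int keeps the degenerate range (e.g. exactly 10 fixations) honest
  n <- spec$fixation_range[1] +
    sample.int(spec$fixation_range[2] - spec$fixation_range[1] + 1L, 1) - 1L
  p_in <- if (group_label == "TD") spec$p_social_td else spec$p_social_asd
  x <- integer(n); y <- integer(n)
  for (k in seq_len(n)) {
    if (!is.null(region) && identical(image$category, "people") &&
        stats::runif(1) < p_in) {
      # uniform in the disk, kept strictly inside so integer rounding stays in
      rr <- (region$r - 1) * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      x[k] <- round(region$cx + rr * cos(th))
      y[k] <- round(region$cy + rr * sin(th))
    } else {
      repeat {
        x[k] <- sample.int(W, 1) - 1L
        y[k] <- sample.int(H, 1) - 1L
        if (is.null(region) || !in_social_region(x[k], y[k], region)) break
      }
    }
  }
  dur <- round(stats::rlnorm(n, spec$duration_meanlog, spec$duration_sdlog), 2)
  scanpath(data.frame(x = pmin(pmax(x, 0L), W - 1L),
                      y = pmin(pmax(y, 0L), H - 1L), duration = dur),
           participant_index = participant_index,
           image_id = image$image_id, group_label = group_label)
}

#' Build a synthetic corpus on disk and load it through the real readers
#'
#' Generates the full cross of participants x images per group, writes PNG
#' stimuli, one aggregated four-column scanpath file per image per group and
#' a manifest CSV, then loads everything back via [load_corpus()] — the
#' generator output is exercised through the same file formats real corpora
#' use. Label noise flips the observed label of `round(rate * N)` uniformly
#' chosen records; the ground-truth table records true and observed labels,
#' the flipped ids, and each image's social region.
#'
#' @param spec a [synthetic_gaze_spec()].
#' @param dir output directory (created; a fresh temporary directory by
#'   default).
#' @param fixmap_radius fixation-map radius for the loaded records.
#' @return List of class `"gaze_corpus"`: `records` (observed labels already
#'   applied), `truth` (per-record ground-truth data.frame), `images`,
#'   `manifest_path`, `dir`, `spec`.
#' @export
build_synthetic_corpus <- function(spec, dir = tempfile("gazecorpus"),
                                   fixmap_radius = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(dir, "images"); sp_dir <- file.path(dir, "scanpaths")
  dir.create(img_dir, showWarnings = FALSE); dir.create(sp_dir, showWarnings = FALSE)
  npp <- spec$n_participants_per_group
  images <- vector("list", spec$n_images)
  man <- data.frame()
  truth <- data.frame()
  for (j in seq_len(spec$n_images)) {
    im <- generate_stimulus(spec, j)
    images[[j]] <- im
    png::writePNG(im$pixels, file.path(img_dir, paste0(im$image_id, ".png")))
    region <- attr(im, "social_region")
    for (grp in c("TD", "ASD")) {
      sps <- with_seed(derive_seed(spec$seed, 10000L + 2L * j + (grp == "ASD")),
                       lapply(seq_len(npp), function(p)
                         generate_scanpath(spec, im, grp, p)))
      fn <- sprintf("%s_%s.txt", im$image_id, tolower(grp))
      write_scanpaths_aggregated(sps, file.path(sp_dir, fn))
      truth <- rbind(truth, data.frame(
        sample_id = sprintf("%s_%s_p%02d", im$image_id, tolower(grp), seq_len(npp)),
        image_id = im$image_id, category = im$category, group = grp,
        true_label = as.integer(grp == "ASD"),
        social_cx = if (is.null(region)) NA_real_ else region$cx,
        social_cy = if (is.null(region)) NA_real_ else region$cy,
        social_r = if (is.null(region)) NA_real_ else region$r))
    }
    man <- rbind(man, data.frame(
      image_id = im$image_id,
      image_path = file.path("images", paste0(im$image_id, ".png")),
      category = im$category,
      asd_scanpaths = file.path("scanpaths", sprintf("%s_asd.txt", im$image_id)),
      td_scanpaths = file.path("scanpaths", sprintf("%s_td.txt", im$image_id))))
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest_path, row.names = FALSE)
  records <- load_corpus(manifest_path, fixmap_radius = fixmap_radius)
  ids <- vapply(records, function(r) r$sample_id, character(1))
  records <- records[match(truth$sample_id, ids)]
  stopifnot(!anyNA(match(truth$sample_id, ids)))
  # label noise: exactly round(rate * N) flips, reproducible by seed
  N <- nrow(truth)
  n_flip <- round_half_up(spec$label_noise_rate * N)
  flip_idx <- if (n_flip > 0)
    with_seed(derive_seed(spec$seed, 999983L), sample.int(N, n_flip)) else integer(0)
  truth$observed_label <- truth$true_label
  truth$flipped <- FALSE
  if (n_flip > 0) {
    truth$observed_label[flip_idx] <- 1L - truth$observed_label[flip_idx]
    truth$flipped[flip_idx] <- TRUE
    for (i in flip_idx) records[[i]]$label <- truth$observed_label[i]
  }
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  structure(list(records = records, truth = truth, images = images,
                 manifest_path = manifest_path, dir = dir, spec = spec),
            class = "gaze_corpus")
}

#' @export
print.gaze_corpus <- function(x, ...) {
  cat(sprintf("<gaze_corpus> %d records (%d images x 2 groups x %d participants), %d flipped labels\n",
              nrow(x$truth), x$spec$n_images, x$spec$n_participants_per_group,
              sum(x$truth$flipped)))
  cat(sprintf("  categories: %s | dir: %s\n",
              paste(sprintf("%s=%d", names(table(x$truth$category)),
                            table(x$truth$category) / (2 * x$spec$n_participants_per_group)),
                    collapse = " "), x$dir))
  invisible(x)
}

#' Fraction of fixations inside the social region, per record
#'
#' The trivial reference classifier for the planted effect: on people
#' images, thresholding this fraction separates the groups well above
#' chance at the default effect sizes.
#'
#' @param corpus a [build_synthetic_corpus()] result.
#' @return data.frame with `sample_id`, `category`, `true_label`,
#'   `in_region_fraction` (NA for images without a social region).
#' @export
social_fixation_fraction <- function(corpus) {
  out <- corpus$truth[, c("sample_id", "category", "true_label")]
  out$in_region_fraction <- vapply(seq_along(corpus$records), function(i) {
    r <- corpus$records[[i]]
    tr <- corpus$truth[i, ]
    if (is.na(tr$social_r)) return(NA_real_)
    region <- list(cx = tr$social_cx, cy = tr$social_cy, r = tr$social_r)
    fx <- r$scanpath$fixations
    mean(in_social_region(fx$x, fx$y, region))
  }, numeric(1))
  out
}
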