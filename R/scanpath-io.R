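# Readers and writers for the aggregated scanpath text dialect used by gaze
# free-viewing corpora: rows of (fixation index, x, y, duration), one block
# per participant, a new participant starting at each index 0. Plus pairing
# of decomposed scanpaths with their stimulus images into sample records.

#' Construct a scanpath
#'
#' A scanpath is the ordered fixation sequence one participant produced on
#' one stimulus image: columns `x`, `y` (0-based pixel coordinates, origin
#' top-left, y increasing downward) and `duration` (milliseconds, positive).
#'
#' @param fixations data.frame with numeric columns `x`, `y`, `duration`.
#' @param participant_index ordinal of the participant within the aggregated
#'   file it was decomposed from (order of appearance; not assumed consistent
#'   across files).
#' @param image_id stimulus identifier.
#' @param group_label `"ASD"` or `"TD"`.
#' @return An object of class `"scanpath"`.
#' @export
scanpath <- function(fixations, participant_index = 1L, image_id = NA_character_,
                     group_label = c("TD", "ASD")) {
  group_label <- match.arg(group_label)
  stopifnot(is.data.frame(fixations),
            all(c("x", "y", "duration") %in% names(fixations)),
            nrow(fixations) >= 1)
  if (any(!is.finite(fixations$x)) || any(!is.finite(fixations$y)))
    stop("fixation coordinates must be finite")
  if (any(fixations$duration <= 0))
    stop("fixation durations must be positive")
  structure(list(fixations = fixations[, c("x", "y", "duration")],
                 participant_index = as.integer(participant_index),
                 image_id = image_id, group_label = group_label),
            class = "scanpath")
}

#' @export
print.scanpath <- function(x, ...) {
  cat(sprintf("<scanpath> %d fixations | image %s | participant %d | %s\n",
              nrow(x$fixations), x$image_id, x$participant_index, x$group_label))
  invisible(x)
}

#' @export
length.scanpath <- function(x) nrow(x$fixations)

detect_delimiter <- function(lines) {
  probe <- lines[nzchar(trimws(lines))][1]
  if (grepl(",", probe, fixed = TRUE)) "," else if (grepl("\t", probe, fixed = TRUE)) "\t" else ""
}

#' Read an aggregated scanpath file and decompose it into individual scanpaths
#'
#' Aggregated files hold the fixations of every participant who viewed one
#' stimulus, with four columns (index, x, y, duration); the within-participant
#' index restarts at 0 for each participant, so the file splits into maximal
#' runs beginning at index 0. Three-column files (x, y, duration) are read as
#' a single scanpath. The delimiter is auto-detected among comma, tab and
#' whitespace and recorded in the parse report. Fixations outside the image
#' bounds (when `image_size` is supplied) are kept but flagged.
#'
#' @param path path to the scanpath text file.
#' @param group_label class of the participants in this file (`"TD"`/`"ASD"`).
#' @param image_id stimulus identifier to attach.
#' @param image_size optional `c(height, width)` used to flag out-of-bounds
#'   fixations in the parse report.
#' @return A list of [scanpath] objects with attribute `"parse_report"`
#'   (delimiter, row/scanpath counts, out-of-bounds flags).
#' @export
read_scanpaths <- function(path, group_label = c("TD", "ASD"),
                           image_id = NA_character_, image_size = NULL) {
  group_label <- match.arg(group_label)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty scanpath file: ", path)
  line_no <- which(keep)
  lines <- lines[keep]
  delim <- detect_delimiter(lines)
  split_one <- function(s) {
    if (delim == "") strsplit(trimws(s), "[[:space:]]+")[[1]]
    else trimws(strsplit(s, delim, fixed = TRUE)[[1]])
  }
  cells <- lapply(lines, split_one)
  ncols <- unique(lengths(cells))
  if (length(ncols) != 1 || !(ncols %in% c(3L, 4L)))
    stop("expected 3 or 4 columns throughout, got row widths: ",
         paste(sort(unique(lengths(cells))), collapse = ", "))
  vals <- suppressWarnings(vapply(cells, as.numeric, numeric(ncols)))
  bad <- which(colSums(is.na(vals)) > 0)
  if (length(bad))
    stop(sprintf("non-numeric value on line %d of %s", line_no[bad[1]], path))
  vals <- t(vals)
  if (ncols == 4L) {
    idx <- vals[, 1]
    if (any(idx < 0) || any(idx != floor(idx)))
      stop("fixation index column must contain non-negative integers")
    if (idx[1] != 0)
      stop("malformed aggregated scanpath file: first row must have index 0")
    starts <- which(idx == 0)
    dat <- data.frame(x = vals[, 2], y = vals[, 3], duration = vals[, 4])
  } else {
    starts <- 1L
    dat <- data.frame(x = vals[, 1], y = vals[, 2], duration = vals[, 3])
  }
  ends <- c(starts[-1] - 1L, nrow(dat))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    out[[k]] <- scanpath(dat[starts[k]:ends[k], , drop = FALSE],
                         participant_index = k, image_id = image_id,
                         group_label = group_label)
  }
  oob <- NULL
  if (!is.null(image_size)) {
    bad_xy <- dat$x < 0 | dat$x > image_size[2] - 1 |
      dat$y < 0 | dat$y > image_size[1] - 1
    if (any(bad_xy)) oob <- data.frame(row = which(bad_xy),
                                       x = dat$x[bad_xy], y = dat$y[bad_xy])
  }
  attr(out, "parse_report") <- list(
    path = path,
    delimiter = if (delim == "") "whitespace" else if (delim == ",") "comma" else "tab",
    n_rows = nrow(dat), n_columns = ncols, n_scanpaths = length(starts),
    out_of_bounds = oob)
  out
}

#' Write a single scanpath as a three-column (x, y, duration) text file
#'
#' The written file round-trips through [read_scanpaths()] as exactly one
#' scanpath with identical fixations, and rewriting the re-read scanpath is
#' byte-stable.
#'
#' @param x a [scanpath] or [sample_record] (its scanpath is written).
#' @param path output path.
#' @export
write_scanpath <- function(x, path) {
  if (inherits(x, "sample_record")) x <- x$scanpath
  stopifnot(inherits(x, "scanpath"))
  fx <- x$fixations
  writeLines(paste(fx$x, fx$y, fx$duration, sep = "\t"), path)
  invisible(path)
}

#' Write a list of scanpaths as one aggregated four-column file
#'
#' The within-participant fixation index (first column) restarts at 0 for
#' each scanpath, the convention [read_scanpaths()] decomposes on.
#'
#' @param scanpaths list of [scanpath] objects.
#' @param path output path.
#' @export
write_scanpaths_aggregated <- function(scanpaths, path) {
  stopifnot(length(scanpaths) >= 1)
  rows <- unlist(lapply(scanpaths, function(s) {
    fx <- s$fixations
    paste(seq_len(nrow(fx)) - 1L, fx$x, fx$y, fx$duration, sep = "\t")
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Construct a stimulus image
#'
#' @param pixels numeric matrix (grayscale, values in \[0, 1\]) with rows = y.
#' @param image_id stimulus identifier.
#' @param category optional category tag (`"people"`, `"objects"`,
#'   `"landscapes"`, `"other"`).
#' @return An object of class `"stimulus_image"`.
#' @export
stimulus_image <- function(pixels, image_id, category = NULL) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1, ncol(pixels) >= 1)
  if (!is.null(category))
    category <- match.arg(category, c("people", "objects", "landscapes", "other"))
  structure(list(pixels = pixels, image_id = image_id, category = category),
            class = "stimulus_image")
}

#' Read a PNG/JPEG stimulus as a grayscale stimulus image
#'
#' Multi-channel rasters are averaged to grayscale.
#'
#' @param path image path (PNG).
#' @param image_id stimulus identifier (defaults to the file name).
#' @param category optional category tag.
#' @export
read_stimulus <- function(path, image_id = NULL, category = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- apply(px[, , 1:min(3, dim(px)[3]), drop = FALSE],
                                        c(1, 2), mean)
  stimulus_image(px, image_id %||% sub("\\.[^.]+$", "", basename(path)), category)
}

#' Construct a sample record (one classification unit)
#'
#' A sample record pairs one decomposed scanpath with its stimulus image, the
#' fixation map rendered from the scanpath, and the binary class label
#' (ASD = 1, TD = 0).
#'
#' @param image a [stimulus_image].
#' @param scanpath a [scanpath] on that image.
#' @param fixation_map raster with the same height/width as the image (see
#'   [render_fixation_map()]); rendered automatically when `NULL`.
#' @param label 0/1 class label; defaults to the scanpath's group label.
#' @param fixmap_radius radius (pixels) used when rendering the map.
#' @return An object of class `"sample_record"`.
#' @export
sample_record <- function(image, scanpath, fixation_map = NULL, label = NULL,
                          fixmap_radius = 10) {
  stopifnot(inherits(image, "stimulus_image"), inherits(scanpath, "scanpath"))
  if (is.null(fixation_map))
    fixation_map <- render_fixation_map(scanpath, dim(image$pixels),
                                        radius = fixmap_radius)
  stopifnot(identical(dim(fixation_map), dim(image$pixels)))
  if (is.null(label)) label <- if (scanpath$group_label == "ASD") 1L else 0L
  stopifnot(label %in% c(0L, 1L))
  structure(list(image = image, fixation_map = fixation_map,
                 scanpath = scanpath, label = as.integer(label),
                 participant_index = scanpath$participant_index,
                 image_id = image$image_id,
                 sample_id = sprintf("%s_%s_p%02d", image$image_id,
                                     tolower(scanpath$group_label),
                                     scanpath$participant_index)),
            class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record> %s | label %d | %d fixations | image %dx%d\n",
              x$sample_id, x$label, nrow(x$scanpath$fixations),
              nrow(x$image$pixels), ncol(x$image$pixels)))
  invisible(x)
}

#' Pair decomposed scanpaths with their stimulus images
#'
#' Produces one [sample_record] per scanpath; fixation content is never
#' modified, only references attached. The record count per image therefore
#' equals the number of participants who viewed it.
#'
#' @param scanpaths list of [scanpath] objects.
#' @param images named list of [stimulus_image] objects (names = image ids),
#'   or an unnamed list (names taken from each image's `image_id`).
#' @param fixmap_radius radius in pixels for the rendered fixation maps.
#' @return List of [sample_record] objects.
#' @export
pair_with_stimuli <- function(scanpaths, images, fixmap_radius = 10) {
  if (is.null(names(images)))
    names(images) <- vapply(images, function(im) im$image_id, character(1))
  lapply(scanpaths, function(s) {
    im <- images[[s$image_id]]
    if (is.null(im)) stop("no stimulus image for image_id '", s$image_id, "'")
    sample_record(im, s, fixmap_radius = fixmap_radius)
  })
}

#' Load a corpus from a manifest file
#'
#' The manifest is a CSV with columns `image_id`, `image_path`, `category`,
#' `asd_scanpaths`, `td_scanpaths`; paths are resolved relative to the
#' manifest's directory. Each scanpath file is decomposed and paired with its
#' stimulus.
#'
#' @param manifest_path path to the manifest CSV.
#' @param fixmap_radius fixation-map radius in pixels.
#' @return List of [sample_record] objects.
#' @export
load_corpus <- function(manifest_path, fixmap_radius = 10) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("image_id", "image_path", "category", "asd_scanpaths", "td_scanpaths")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  root <- dirname(manifest_path)
  records <- list()
  for (r in seq_len(nrow(man))) {
    im <- read_stimulus(file.path(root, man$image_path[r]), man$image_id[r],
                        man$category[r])
    for (grp in c("TD", "ASD")) {
      col <- if (grp == "ASD") "asd_scanpaths" else "td_scanpaths"
      sp <- read_scanpaths(file.path(root, man[[col]][r]), group_label = grp,
                           image_id = man$image_id[r],
                           image_size = dim(im$pixels))
      recs <- pair_with_stimuli(sp, stats::setNames(list(im), man$image_id[r]),
                                fixmap_radius = fixmap_radius)
      records <- c(records, recs)
    }
  }
  records
}
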