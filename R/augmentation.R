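# Scanpath augmentation: per-scanpath duration rescaling to [1, 100],
# duration-proportional replication with uniform integer jitter, and
# fixation-map rasterization at a fixed radius.

#' Rescale fixation durations to the 1..100 range
#'
#' Each duration is mapped linearly over the scanpath's own range,
#' `d' = round(1 + 99 * (d - d_min) / (d_max - d_min))` with half-up rounding,
#' so the shortest fixation maps to 1 and the longest to 100. The map uses the
#' scanpath's own min/max, so it is invariant to the unit the durations are
#' expressed in. When all durations are equal the map is undefined; every
#' fixation then receives the midpoint value 50.
#'
#' @param x a [scanpath] or a numeric vector of positive durations.
#' @return Integer vector of scaled durations in `[1, 100]`, monotone
#'   non-decreasing in the input durations.
#' @export
rescale_durations <- function(x) {
  d <- if (inherits(x, "scanpath")) x$fixations$duration else x
  if (length(d) == 0) stop("empty scanpath: no durations to rescale")
  stopifnot(all(d > 0))
  rng <- range(d)
  if (rng[1] == rng[2]) return(rep(50L, length(d)))
  as.integer(round_half_up(1 + 99 * (d - rng[1]) / (rng[2] - rng[1])))
}

#' Replicate fixations by scaled duration and apply spatial jitter
#'
#' Fixation i yields `d'_i` replicas (its rescaled duration), each shifted by
#' an independent uniform integer offset in `[-jitter_radius, jitter_radius]`
#' on both axes and then clipped to the image bounds. Replicas keep the
#' original temporal order (all replicas of fixation i precede those of
#' i + 1), so the augmented sequence length is the sum of the scaled
#' durations. Duration-proportional replication densifies short scanpaths
#' while preserving their temporal structure; the jitter broadens the spatial
#' area each fixation covers.
#'
#' @param scanpath a [scanpath].
#' @param image_size `c(height, width)` of the paired image, used for
#'   clipping.
#' @param jitter_radius half-width of the uniform integer shift, in pixels.
#' @return A [scanpath] whose fixations are the jittered replicas; replica
#'   durations carry the scaled duration of their source fixation.
#' @export
replicate_and_jitter <- function(scanpath, image_size, jitter_radius = 10) {
  stopifnot(inherits(scanpath, "scanpath"), jitter_radius >= 0)
  if (is.null(image_size) || length(image_size) < 2 || any(!is.finite(image_size[1:2])))
    stop("image_size (height, width) is required for clipping")
  scaled <- rescale_durations(scanpath)
  fx <- scanpath$fixations
  n_out <- sum(scaled)
  src <- rep(seq_len(nrow(fx)), times = scaled)
  dx <- sample.int(2L * jitter_radius + 1L, n_out, replace = TRUE) - jitter_radius - 1L
  dy <- sample.int(2L * jitter_radius + 1L, n_out, replace = TRUE) - jitter_radius - 1L
  x <- pmin(pmax(fx$x[src] + dx, 0), image_size[2] - 1)
  y <- pmin(pmax(fx$y[src] + dy, 0), image_size[1] - 1)
  scanpath(data.frame(x = x, y = y, duration = scaled[src]),
           participant_index = scanpath$participant_index,
           image_id = scanpath$image_id, group_label = scanpath$group_label)
}

#' Render the fixation map of a scanpath
#'
#' Marks every pixel within `radius` (Euclidean) of any original fixation:
#' pixel (u, v) is set iff some fixation (x_i, y_i) satisfies
#' `(u - x_i)^2 + (v - y_i)^2 <= radius^2`. Rendering uses the original,
#' pre-jitter fixations; the map is binary by default (`mode = "count"`
#' instead accumulates the number of covering fixations per pixel).
#'
#' @param scanpath a [scanpath].
#' @param image_size `c(height, width)` of the raster.
#' @param radius disk radius in pixels.
#' @param mode `"binary"` (region-of-interest mask) or `"count"`.
#' @return Numeric `height x width` matrix.
#' @export
render_fixation_map <- function(scanpath, image_size, radius = 10,
                                mode = c("binary", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scanpath, "scanpath"), radius >= 0)
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  if (is.na(H) || is.na(W) || H < 1 || W < 1) stop("invalid image_size")
  map <- matrix(0, H, W)
  r2 <- radius^2
  ri <- floor(radius)
  for (k in seq_len(nrow(scanpath$fixations))) {
    x0 <- scanpath$fixations$x[k]; y0 <- scanpath$fixations$y[k]
    if (x0 + ri < 0 || x0 - ri > W - 1 || y0 + ri < 0 || y0 - ri > H - 1) next
    us <- max(0, ceiling(x0 - ri)):min(W - 1, floor(x0 + ri))
    vs <- max(0, ceiling(y0 - ri)):min(H - 1, floor(y0 + ri))
    dd <- outer((vs - y0)^2, (us - x0)^2, `+`)
    hit <- dd <= r2
    sub <- map[vs + 1, us + 1, drop = FALSE]
    sub[hit] <- sub[hit] + 1
    map[vs + 1, us + 1] <- sub
  }
  if (mode == "binary") map <- (map > 0) + 0
  map
}

#' Write a fixation map as a PNG (0/255)
#'
#' @param map matrix from [render_fixation_map()].
#' @param path output path.
#' @export
write_fixation_map <- function(map, path) {
  png::writePNG(pmin(map, 1), path)
  invisible(path)
}
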