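# Model/training configuration and data splitting.

#' Classifier configuration
#'
#' Defaults follow the reference three-branch architecture: two convolutional
#' branches (4 layers, 3x3 kernels, ReLU, filters 32/64/128/256, 2x2
#' max-pooling after the first three layers and global average pooling after
#' the fourth) over the stimulus image and the fixation map, and a 2-layer
#' LSTM (hidden size 1024, dropout 0.3 between layers, input size 2 then
#' 1024) over the fixation coordinate sequence; one linear head per branch
#' reduces each to a scalar, a final linear layer over the concatenated
#' 3-vector feeds a sigmoid, and training minimises binary cross-entropy with
#' Adam for 16 epochs, checkpointing parameters after every epoch.
#'
#' `profile = "desk"` selects a reduced model for laptop-scale experiments:
#' 32x32 inputs, filters 4/8/16/32, LSTM hidden 16, batch size 8, 8 epochs,
#' learning rate 1.5e-3, and the LSTM consumes the original (unreplicated)
#' fixation sequence.
#' At full scale the LSTM consumes the duration-replicated, jittered sequence
#' (`lstm_input = "augmented"`).
#'
#' @param profile `"full"` (reference scale) or `"desk"` (reduced); explicit
#'   arguments override the profile.
#' @param input_size side of the square network input in pixels (stimuli and
#'   fixation maps are resized to it); must be divisible by
#'   `2^(length(conv_filters) - 1)`.
#' @param conv_filters filter counts of the convolutional layers.
#' @param kernel_size convolution kernel side (3).
#' @param lstm_hidden LSTM hidden size (both layers).
#' @param lstm_dropout dropout rate applied to first-layer LSTM outputs
#'   during training.
#' @param lstm_input `"augmented"` (replicated + jittered sequence) or
#'   `"original"`.
#' @param epochs training epochs (one checkpoint per epoch).
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate (constant across epochs; it is the
#'   checkpoint learning rate used in influence replay).
#' @param scale_range duration rescale bounds, `c(1, 100)`.
#' @param jitter_radius spatial jitter half-width in pixels.
#' @param fixmap_radius fixation-map disk radius in pixels.
#' @param fixmap_mode `"binary"` or `"count"` fixation maps.
#' @param gradient_mode default parameter subset for influence gradients:
#'   `"last_layer"` (final fusion layer) or `"full"`.
#' @param split train/validation/test fractions (record-level, stratified by
#'   label).
#' @param split_mode `"record"` or `"participant"` (participant-disjoint).
#' @param threshold hard-label decision threshold on the ASD probability.
#' @return A list of class `"gaze_config"`.
#' @export
gaze_config <- function(profile = c("full", "desk"),
                        input_size = NULL, conv_filters = NULL,
                        kernel_size = 3L, lstm_hidden = NULL, lstm_dropout = 0.3,
                        lstm_input = NULL, epochs = NULL, batch_size = NULL,
                        learning_rate = NULL, scale_range = c(1, 100),
                        jitter_radius = 10, fixmap_radius = 10,
                        fixmap_mode = c("binary", "count"),
                        gradient_mode = c("last_layer", "full"),
                        split = c(train = 0.8, val = 0.1, test = 0.1),
                        split_mode = c("record", "participant"),
                        threshold = 0.5) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  cfg <- list(
    profile = profile,
    input_size = as.integer(input_size %||% if (desk) 32L else 128L),
    conv_filters = as.integer(conv_filters %||%
                                if (desk) c(4L, 8L, 16L, 32L) else c(32L, 64L, 128L, 256L)),
    kernel_size = as.integer(kernel_size),
    lstm_hidden = as.integer(lstm_hidden %||% if (desk) 16L else 1024L),
    lstm_dropout = lstm_dropout,
    lstm_input = match.arg(lstm_input %||% if (desk) "original" else "augmented",
                           c("augmented", "original")),
    epochs = as.integer(epochs %||% if (desk) 8L else 16L),
    batch_size = as.integer(batch_size %||% if (desk) 8L else 32L),
    learning_rate = learning_rate %||% if (desk) 1.5e-3 else 1e-4,
    scale_range = scale_range,
    jitter_radius = jitter_radius,
    fixmap_radius = fixmap_radius,
    fixmap_mode = match.arg(fixmap_mode),
    gradient_mode = match.arg(gradient_mode),
    split = split,
    split_mode = match.arg(split_mode),
    threshold = threshold)
  if (cfg$kernel_size != 3L)
    stop("only 3x3 kernels are supported")
  if (length(cfg$conv_filters) < 1)
    stop("at least one convolutional layer is required")
  down <- 2L^(length(cfg$conv_filters) - 1L)
  if (cfg$input_size %% down != 0)
    stop("input_size must be divisible by ", down,
         " (one 2x2 pooling per conv layer except the last)")
  if (abs(sum(cfg$split) - 1) > 1e-8 || any(cfg$split <= 0 & names(cfg$split) == "train"))
    stop("split fractions must sum to 1")
  structure(cfg, class = "gaze_config")
}

#' @export
print.gaze_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<gaze_config> profile=%s input=%dx%d filters=[%s] lstm=%d x2 (dropout %.1f, %s input)\n",
    "  epochs=%d batch=%d lr=%g fixmap radius=%g jitter=%g gradient_mode=%s\n"),
    x$profile, x$input_size, x$input_size,
    paste(x$conv_filters, collapse = ","), x$lstm_hidden, x$lstm_dropout,
    x$lstm_input, x$epochs, x$batch_size, x$learning_rate, x$fixmap_radius,
    x$jitter_radius, x$gradient_mode))
  invisible(x)
}

#' Stratified train/validation/test split
#'
#' Record-level stratification by label, or participant-disjoint assignment
#' (`mode = "participant"`) where all records of one participant land in the
#' same partition, stratified by group.
#'
#' @param records list of [sample_record] objects.
#' @param fractions named fractions `c(train=, val=, test=)` summing to 1.
#' @param seed RNG seed; the split is reproducible given it.
#' @param mode `"record"` or `"participant"`.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(records, fractions = c(train = 0.8, val = 0.1, test = 0.1),
                             seed = 1L, mode = c("record", "participant")) {
  mode <- match.arg(mode)
  labels <- vapply(records, function(r) r$label, integer(1))
  with_seed(seed, {
    if (mode == "record") {
      parts <- list(train = integer(0), val = integer(0), test = integer(0))
      for (lab in unique(labels)) {
        idx <- sample(which(labels == lab))
        n <- length(idx)
        n_tr <- round_half_up(fractions[["train"]] * n)
        n_va <- round_half_up(fractions[["val"]] * n)
        parts$train <- c(parts$train, idx[seq_len(n_tr)])
        parts$val <- c(parts$val, idx[n_tr + seq_len(min(n_va, n - n_tr))])
        if (n > n_tr + n_va) parts$test <- c(parts$test, idx[(n_tr + n_va + 1):n])
      }
    } else {
      key <- vapply(records, function(r)
        paste0(r$scanpath$group_label, "_", r$participant_index), character(1))
      parts <- list(train = integer(0), val = integer(0), test = integer(0))
      for (grp in unique(sub("_.*", "", key))) {
        ids <- sample(unique(key[startsWith(key, grp)]))
        n <- length(ids)
        n_tr <- max(1L, round_half_up(fractions[["train"]] * n))
        n_va <- round_half_up(fractions[["val"]] * n)
        asg <- rep("test", n)
        asg[seq_len(n_tr)] <- "train"
        asg[n_tr + seq_len(min(n_va, n - n_tr))] <- "val"
        for (p in c("train", "val", "test"))
          parts[[p]] <- c(parts[[p]], which(key %in% ids[asg == p]))
      }
    }
    lapply(parts, sort)
  })
}
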