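# The gaze classifier: preprocessing of sample records into network tensors,
# the training loop with per-epoch checkpointing, and the S3 methods of the
# fitted object.

# Records -> network tensors. Images and fixation maps are resized to the
# configured input side; LSTM coordinates are normalised to (0, 1) by the
# original image dimensions. Augmented LSTM input (duration-replicated +
# jittered) is drawn once, deterministically from `seed`.
prep_tensors <- function(records, config, seed = 1L) {
  n <- length(records)
  if (n == 0) stop("empty dataset")
  S <- config$input_size
  img <- array(0, c(S, S, 1L, n))
  fix <- array(0, c(S, S, 1L, n))
  seqs <- vector("list", n)
  y <- integer(n)
  ids <- character(n)
  for (i in seq_len(n)) {
    r <- records[[i]]
    px <- r$image$pixels
    img[, , 1L, i] <- resize_bilinear(px, S, S)
    fix[, , 1L, i] <- resize_bilinear(r$fixation_map, S, S)
    sp <- r$scanpath
    if (config$lstm_input == "augmented")
      sp <- with_seed(derive_seed(seed, 70000L + i),
                      replicate_and_jitter(sp, dim(px), config$jitter_radius))
    # coordinates normalised to [-1, 1] (mean-centred) by the original image
    # dimensions, so the LSTM input scale is stimulus-size invariant
    seqs[[i]] <- cbind(2 * (sp$fixations$x + 0.5) / ncol(px) - 1,
                       2 * (sp$fixations$y + 0.5) / nrow(px) - 1)
    y[i] <- r$label
    ids[i] <- r$sample_id
  }
  list(img = img, fix = fix, seqs = seqs, y = y, ids = ids, n = n)
}

slice_tensors <- function(tensors, idx) {
  list(img = tensors$img[, , , idx, drop = FALSE],
       fix = tensors$fix[, , , idx, drop = FALSE],
       seqs = tensors$seqs[idx], y = tensors$y[idx], ids = tensors$ids[idx],
       n = length(idx))
}

# Eval-mode forward over an index set, in minibatches; returns probabilities.
nn_predict_probs <- function(params, tensors, idx, config) {
  p <- numeric(length(idx))
  bs <- config$batch_size
  for (start in seq(1L, length(idx), by = bs)) {
    take <- idx[start:min(start + bs - 1L, length(idx))]
    fwd <- nn_forward(params, slice_tensors(tensors, take), config, train = FALSE)
    p[start:(start + length(take) - 1L)] <- fwd$p
  }
  p
}

#' Fit the three-branch gaze classifier
#'
#' Trains the image-CNN / fixation-map-CNN / scanpath-LSTM classifier on
#' sample records with Adam on binary cross-entropy, snapshotting the full
#' parameter vector (with its learning rate) after every epoch. Each branch
#' is reduced to a scalar by its linear head; the concatenated 3-vector
#' passes through a final linear layer and a sigmoid, giving the ASD
#' probability. Training is fully reproducible given `seed`.
#'
#' @param records list of [sample_record] objects (the whole corpus).
#' @param config a [gaze_config()].
#' @param seed integer seed governing initialisation, shuffling, dropout and
#'   (when used) input augmentation.
#' @param split optional list of index vectors `train`, `val`, `test` into
#'   `records`; computed by [stratified_split()] with `split_seed` otherwise.
#'   Only `train` is trained on; `val` drives the per-epoch history.
#' @param split_seed seed for the automatic split (kept separate from `seed`
#'   so reruns with new training seeds share one test set).
#' @param verbose print one line per epoch.
#' @return Object of class `"gaze_classifier"`: trained parameters, per-epoch
#'   `checkpoints`, training `history`, the `split`, fitted probabilities and
#'   the configuration. Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `simulate` and `plot`.
#' @export
gaze_classifier <- function(records, config = gaze_config(), seed = 1L,
                            split = NULL, split_seed = 1L, verbose = FALSE) {
  if (length(records) == 0) stop("empty dataset: nothing to train on")
  if (is.null(split))
    split <- stratified_split(records, config$split, seed = split_seed,
                              mode = config$split_mode)
  tr <- split$train
  if (length(tr) == 0) stop("empty training split")
  labs <- vapply(records[tr], function(r) r$label, integer(1))
  if (length(unique(labs)) < 2)
    warning("single-class training set; the loss is still defined but the ",
            "classifier cannot learn a decision boundary")
  tensors <- prep_tensors(records, config, seed = seed)
  n_tr <- length(tr)
  with_seed(seed, {
    params <- nn_init_params(config)
    skeleton <- params
    theta <- nn_flatten(params)
    adam <- adam_init(length(theta))
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          train_acc = numeric(0), val_loss = numeric(0),
                          val_acc = numeric(0))
    checkpoints <- vector("list", config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        batch <- slice_tensors(tensors, take)
        fwd <- nn_forward(params, batch, config, train = TRUE)
        grads <- nn_backward(params, fwd, batch, config, scale = 1 / batch$n)
        upd <- adam_step(theta, nn_flatten(grads), adam, config$learning_rate)
        theta <- upd$theta; adam <- upd$state
        params <- nn_unflatten(theta, skeleton)
        ep_loss <- ep_loss + sum(bce_from_logit(fwd$z, batch$y))
        ep_correct <- ep_correct + sum((fwd$p >= config$threshold) == (batch$y == 1L))
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (length(split$val)) {
        pv <- nn_predict_probs(params, tensors, split$val, config)
        yv <- tensors$y[split$val]
        val_loss <- mean(-(yv * log(pmax(pv, 1e-12)) +
                             (1 - yv) * log(pmax(1 - pv, 1e-12))))
        val_acc <- mean((pv >= config$threshold) == (yv == 1L))
      }
      history[ep, ] <- list(ep, ep_loss / n_tr, ep_correct / n_tr, val_loss, val_acc)
      checkpoints[[ep]] <- list(theta = theta, eta = config$learning_rate,
                                epoch = ep)
      if (verbose)
        message(sprintf("epoch %2d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        ep, history$train_loss[ep], history$train_acc[ep],
                        val_loss, val_acc))
    }
    fitted_probs <- nn_predict_probs(params, tensors, seq_len(tensors$n), config)
    structure(list(params = params, skeleton = skeleton,
                   checkpoints = checkpoints, history = history,
                   config = config, split = split, seed = seed,
                   tensors = tensors, fitted_probs = fitted_probs,
                   sample_ids = tensors$ids, labels = tensors$y),
              class = "gaze_classifier")
  })
}

#' Extract the checkpoint set of a fitted classifier
#'
#' @param fit a fitted [gaze_classifier()].
#' @param subsample keep every `subsample`-th epoch checkpoint (1 = all).
#' @return Object of class `"checkpoint_set"`: flattened parameter snapshots
#'   `theta`, learning rates `etas`, epoch numbers, plus the parameter
#'   skeleton and configuration needed to replay gradients.
#' @export
checkpoint_set <- function(fit, subsample = 1L) {
  stopifnot(inherits(fit, "gaze_classifier"))
  keep <- seq(subsample, length(fit$checkpoints), by = subsample)
  structure(list(theta = lapply(fit$checkpoints[keep], `[[`, "theta"),
                 etas = vapply(fit$checkpoints[keep], `[[`, numeric(1), "eta"),
                 epochs = vapply(fit$checkpoints[keep], `[[`, integer(1), "epoch"),
                 skeleton = fit$skeleton, config = fit$config, seed = fit$seed),
            class = "checkpoint_set")
}

#' @export
print.checkpoint_set <- function(x, ...) {
  cat(sprintf("<checkpoint_set> k=%d checkpoints (epochs %s), %d parameters\n",
              length(x$theta), paste(range(x$epochs), collapse = "-"),
              length(x$theta[[1]])))
  invisible(x)
}

#' Save / load a checkpoint archive
#'
#' One serialized parameter snapshot per epoch plus a `manifest.csv` holding
#' the epoch number, learning rate, training seed and file name.
#'
#' @param cpts a [checkpoint_set()].
#' @param dir archive directory (created if needed).
#' @rdname checkpoint_archive
#' @export
save_checkpoints <- function(cpts, dir) {
  stopifnot(inherits(cpts, "checkpoint_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("checkpoint_%03d.rds", cpts$epochs)
  for (i in seq_along(cpts$theta))
    saveRDS(cpts$theta[[i]], file.path(dir, files[i]))
  saveRDS(list(skeleton = cpts$skeleton, config = cpts$config), file.path(dir, "model.rds"))
  utils::write.csv(data.frame(epoch = cpts$epochs, eta = cpts$etas,
                              seed = cpts$seed, file = files),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname checkpoint_archive
#' @export
load_checkpoints <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  model <- readRDS(file.path(dir, "model.rds"))
  structure(list(theta = lapply(file.path(dir, man$file), readRDS),
                 etas = man$eta, epochs = man$epoch,
                 skeleton = model$skeleton, config = model$config,
                 seed = man$seed[1]),
            class = "checkpoint_set")
}

#' @export
predict.gaze_classifier <- function(object, newdata = NULL,
                                    type = c("prob", "class", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    p <- object$fitted_probs
  } else {
    tensors <- prep_tensors(newdata, object$config,
                            seed = derive_seed(object$seed, 90001L))
    p <- nn_predict_probs(object$params, tensors, seq_len(tensors$n), object$config)
    names(p) <- tensors$ids
  }
  switch(type,
         prob = p,
         class = as.integer(p >= object$config$threshold),
         link = log(p / (1 - p)))
}

#' Evaluate a fitted classifier on a subset of its corpus
#'
#' @param fit fitted [gaze_classifier()].
#' @param idx record indices (defaults to the test split).
#' @return A [classification_metrics()] report.
#' @export
evaluate_split <- function(fit, idx = fit$split$test) {
  stopifnot(length(idx) > 0)
  p <- nn_predict_probs(fit$params, fit$tensors, idx, fit$config)
  classification_metrics(fit$labels[idx], p, fit$config$threshold)
}

#' @export
fitted.gaze_classifier <- function(object, ...) object$fitted_probs

#' @export
residuals.gaze_classifier <- function(object, ...)
  object$labels - object$fitted_probs

#' @export
coef.gaze_classifier <- function(object, ...) {
  w <- object$params$final
  stats::setNames(c(as.vector(w$W), w$b),
                  c("o_img", "o_fix", "o_scnpts", "(Intercept)"))
}

#' @export
simulate.gaze_classifier <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$fitted_probs
  sim <- with_seed(seed %||% derive_seed(object$seed, 555L),
                   replicate(nsim, stats::rbinom(length(p), 1L, p)))
  out <- as.data.frame(sim)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$sample_ids
  out
}

#' @export
print.gaze_classifier <- function(x, ...) {
  cat(sprintf("<gaze_classifier> %d records (train %d / val %d / test %d), %d epochs, seed %d\n",
              x$tensors$n, length(x$split$train), length(x$split$val),
              length(x$split$test), x$config$epochs, x$seed))
  cat(sprintf("  fusion coefficients: %s\n",
              paste(sprintf("%s=%.3f", names(coef(x)), coef(x)), collapse = "  ")))
  invisible(x)
}

#' @export
summary.gaze_classifier <- function(object, ...) {
  out <- list(fit = object,
              train = evaluate_split(object, object$split$train),
              val = if (length(object$split$val)) evaluate_split(object, object$split$val),
              test = if (length(object$split$test)) evaluate_split(object, object$split$test))
  class(out) <- "summary.gaze_classifier"
  out
}

#' @export
print.summary.gaze_classifier <- function(x, ...) {
  print(x$fit)
  print(x$fit$config)
  for (part in c("train", "val", "test")) {
    if (is.null(x[[part]])) next
    cat(sprintf("%-5s ", part)); print(x[[part]])
  }
  invisible(x)
}

#' Plot training and validation curves
#'
#' Loss and accuracy per epoch, the standard training-trajectory view.
#'
#' @param x fitted [gaze_classifier()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gaze_classifier <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = c(1, 2), lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "BCE loss", main = "Loss", ...)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                   col = c("black", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "b",
                    pch = c(1, 2), lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "accuracy", main = "Accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), pch = c(1, 2),
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
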