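# Checkpoint-replay training-data attribution. The influence of a training
# sample x on a test sample x' is the learning-rate-weighted sum, over the
# saved checkpoints, of the inner product of their per-sample loss gradients:
#   Influence(x, x')    = sum_i eta_i <grad l(w_i, x), grad l(w_i, x')>
#   Self-Influence(x)   = Influence(x, x) = sum_i eta_i ||grad l(w_i, x)||^2
# Gradients are taken in evaluation mode (no dropout) over either the final
# fusion layer ("last_layer", the scalable default) or all parameters
# ("full", used by the oracle tests).

resolve_attr_input <- function(object, records = NULL, idx = NULL) {
  if (inherits(object, "gaze_classifier")) {
    cpts <- checkpoint_set(object)
    tensors <- object$tensors
    idx <- idx %||% object$split$train
  } else if (inherits(object, "checkpoint_set")) {
    cpts <- object
    if (is.null(records)) stop("`records` is required with a checkpoint_set")
    tensors <- prep_tensors(records, cpts$config, seed = cpts$seed)
    idx <- idx %||% seq_len(tensors$n)
  } else stop("expected a gaze_classifier or checkpoint_set")
  if (length(cpts$theta) < 1) stop("empty checkpoint set")
  list(cpts = cpts, tensors = tensors, idx = idx)
}

# Per-sample gradient matrix (rows = samples in `idx`) at one checkpoint.
# last_layer mode is closed-form and batched: with sigmoid + BCE the logit
# gradient is (p - y), so the fusion-layer gradient is (p - y) * [feats, 1].
# full mode backpropagates one sample at a time.
tracin_gradient_matrix <- function(cpts, tensors, idx, checkpoint,
                                   mode = c("last_layer", "full")) {
  mode <- match.arg(mode)
  params <- nn_unflatten(cpts$theta[[checkpoint]], cpts$skeleton)
  config <- cpts$config
  if (mode == "last_layer") {
    G <- matrix(0, length(idx), 4L)
    bs <- config$batch_size
    for (start in seq(1L, length(idx), by = bs)) {
      take <- idx[start:min(start + bs - 1L, length(idx))]
      batch <- slice_tensors(tensors, take)
      fwd <- nn_forward(params, batch, config, train = FALSE)
      dz <- fwd$p - batch$y
      G[start:(start + length(take) - 1L), ] <- cbind(fwd$feats * dz, dz)
    }
    colnames(G) <- c("final.W1", "final.W2", "final.W3", "final.b")
  } else {
    G <- NULL
    for (j in seq_along(idx)) {
      batch <- slice_tensors(tensors, idx[j])
      fwd <- nn_forward(params, batch, config, train = FALSE)
      g <- nn_flatten(nn_backward(params, fwd, batch, config, scale = 1))
      if (is.null(G)) G <- matrix(0, length(idx), length(g))
      G[j, ] <- g
    }
  }
  G
}

#' Per-sample loss gradient at a checkpoint
#'
#' Gradient of the (unreduced) binary cross-entropy of one sample with
#' respect to the selected parameter subset, flattened in the fixed
#' parameter-vector order, evaluated at the stored checkpoint parameters in
#' evaluation mode.
#'
#' @param object fitted [gaze_classifier()] or [checkpoint_set()].
#' @param idx index of the sample within the fit's corpus (or within
#'   `records`).
#' @param checkpoint which checkpoint (1-based position in the set).
#' @param mode `"last_layer"` (final fusion layer: 4 values) or `"full"`.
#' @param records sample records, required when `object` is a checkpoint set.
#' @return Named numeric gradient vector.
#' @export
per_sample_gradient <- function(object, idx, checkpoint = 1L,
                                mode = c("last_layer", "full"), records = NULL) {
  mode <- match.arg(mode)
  inp <- resolve_attr_input(object, records, idx)
  G <- tracin_gradient_matrix(inp$cpts, inp$tensors, inp$idx[1], checkpoint, mode)
  g <- G[1, ]
  if (mode == "full")
    names(g) <- nn_param_names(inp$cpts$skeleton)
  g
}

#' Accumulate influence scores from explicit gradients
#'
#' Low-level kernel of the attribution machinery:
#' `sum_i etas[i] * G_train[[i]] %*% t(G_test[[i]])`. Exposed so the
#' accumulation rule can be exercised directly on hand-constructed gradients.
#'
#' @param etas learning rates, one per checkpoint.
#' @param grads_train,grads_test lists (one element per checkpoint) of
#'   gradient matrices, rows = samples; `grads_test = grads_train` gives the
#'   self-influence Gram matrix.
#' @return Influence matrix (train x test).
#' @export
tracin_score <- function(etas, grads_train, grads_test = grads_train) {
  stopifnot(length(etas) == length(grads_train),
            length(grads_train) == length(grads_test))
  out <- 0
  for (i in seq_along(etas))
    out <- out + etas[i] * tcrossprod(grads_train[[i]], grads_test[[i]])
  out
}

#' Self-influence scores
#'
#' `Self-Influence(x) = sum_i eta_i ||grad l(w_i, x)||^2`, accumulated over
#' the checkpoint set. Non-negative by construction; high scores flag
#' outliers, mislabeled or otherwise conflicting training samples.
#'
#' @inheritParams per_sample_gradient
#' @param idx sample indices to score (defaults to the training split).
#' @return Named non-negative numeric vector (names = sample ids).
#' @export
tracin_self_influence <- function(object, idx = NULL,
                                  mode = c("last_layer", "full"),
                                  records = NULL) {
  mode <- match.arg(mode)
  inp <- resolve_attr_input(object, records, idx)
  score <- numeric(length(inp$idx))
  for (i in seq_along(inp$cpts$theta)) {
    G <- tracin_gradient_matrix(inp$cpts, inp$tensors, inp$idx, i, mode)
    score <- score + inp$cpts$etas[i] * rowSums(G * G)
  }
  stats::setNames(score, inp$tensors$ids[inp$idx])
}

#' Pairwise train-by-test influence scores
#'
#' `Influence(x, x') = sum_i eta_i <grad l(w_i, x), grad l(w_i, x')>`.
#' Symmetric in its two sample arguments; `Influence(x, x)` equals the
#' self-influence of x.
#'
#' @inheritParams per_sample_gradient
#' @param train_idx,test_idx sample indices (defaults: training and test
#'   splits of the fit).
#' @return Matrix of influence scores, rows = training samples, columns =
#'   test samples, dimnames = sample ids.
#' @export
tracin_influence <- function(object, train_idx = NULL, test_idx = NULL,
                             mode = c("last_layer", "full"), records = NULL) {
  mode <- match.arg(mode)
  if (inherits(object, "gaze_classifier")) {
    train_idx <- train_idx %||% object$split$train
    test_idx <- test_idx %||% object$split$test
  }
  inp <- resolve_attr_input(object, records, train_idx)
  test_idx <- test_idx %||% inp$idx
  out <- 0
  for (i in seq_along(inp$cpts$theta)) {
    Gtr <- tracin_gradient_matrix(inp$cpts, inp$tensors, inp$idx, i, mode)
    Gte <- tracin_gradient_matrix(inp$cpts, inp$tensors, test_idx, i, mode)
    out <- out + inp$cpts$etas[i] * tcrossprod(Gtr, Gte)
  }
  dimnames(out) <- list(inp$tensors$ids[inp$idx], inp$tensors$ids[test_idx])
  out
}

#' Rank samples by self-influence
#'
#' Descending score order, ties broken by sample id for determinism; the
#' head of the ranking is what influence-guided filtering removes.
#'
#' @inheritParams tracin_self_influence
#' @return data.frame with columns `sample_id`, `idx`, `score`, ordered by
#'   decreasing score.
#' @export
rank_self_influence <- function(object, idx = NULL,
                                mode = c("last_layer", "full"),
                                records = NULL) {
  mode <- match.arg(mode)
  inp <- resolve_attr_input(object, records, idx)
  if (length(inp$idx) == 0) stop("empty dataset")
  score <- tracin_self_influence(object, inp$idx, mode, records)
  ord <- order(-score, names(score))
  data.frame(sample_id = names(score)[ord], idx = inp$idx[ord],
             score = unname(score[ord]), row.names = NULL)
}

#' Proponents and opponents of a test sample
#'
#' The training samples with the highest (proponents) and lowest, most
#' negative (opponents) influence on a given test sample; proponents support
#' its correct classification, opponents conflict with it. Ties break by
#' sample id.
#'
#' @inheritParams tracin_influence
#' @param test_idx index of one test sample.
#' @param top_k how many of each to return (at most the training-set size).
#' @return List with data.frames `proponents` and `opponents`
#'   (`sample_id`, `idx`, `score`).
#' @export
proponents_opponents <- function(object, test_idx, train_idx = NULL, top_k = 5L,
                                 mode = c("last_layer", "full"), records = NULL) {
  mode <- match.arg(mode)
  inf <- tracin_influence(object, train_idx, test_idx[1], mode, records)
  score <- inf[, 1]
  ids <- rownames(inf)
  stopifnot(top_k <= length(score))
  up <- order(-score, ids)[seq_len(top_k)]
  dn <- order(score, ids)[seq_len(top_k)]
  inp <- resolve_attr_input(object, records, train_idx)
  list(proponents = data.frame(sample_id = ids[up], idx = inp$idx[up],
                               score = unname(score[up]), row.names = NULL),
       opponents = data.frame(sample_id = ids[dn], idx = inp$idx[dn],
                              score = unname(score[dn]), row.names = NULL))
}
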