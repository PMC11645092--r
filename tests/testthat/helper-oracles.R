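# Independent oracles: naive per-sample/per-checkpoint influence
# accumulation and central finite differences, kept free of the vectorised
# production code paths they check.

# Naive self-influence: explicit double loop over checkpoints and samples,
# gradients taken by full backpropagation one sample at a time and (for the
# last-layer comparison) subset to the final fusion layer.
naive_self_influence <- function(fit, idx, mode = "last_layer") {
  cpts <- checkpoint_set(fit)
  vapply(idx, function(i) {
    tot <- 0
    for (k in seq_along(cpts$theta)) {
      g <- per_sample_gradient(fit, i, checkpoint = k, mode = "full")
      if (mode == "last_layer") g <- utils::tail(g, 4L)
      tot <- tot + cpts$etas[k] * sum(g * g)
    }
    tot
  }, numeric(1))
}

naive_influence <- function(fit, i, j, mode = "last_layer") {
  cpts <- checkpoint_set(fit)
  tot <- 0
  for (k in seq_along(cpts$theta)) {
    gi <- per_sample_gradient(fit, i, checkpoint = k, mode = "full")
    gj <- per_sample_gradient(fit, j, checkpoint = k, mode = "full")
    if (mode == "last_layer") {
      gi <- utils::tail(gi, 4L); gj <- utils::tail(gj, 4L)
    }
    tot <- tot + cpts$etas[k] * sum(gi * gj)
  }
  tot
}

# Central finite-difference gradient of the per-sample BCE at a checkpoint.
fd_gradient <- function(fit, i, checkpoint = 1L, h = 1e-5) {
  cpts <- checkpoint_set(fit)
  theta <- cpts$theta[[checkpoint]]
  batch <- gazedistill:::slice_tensors(fit$tensors, i)
  lossf <- function(th) {
    pp <- gazedistill:::nn_unflatten(th, cpts$skeleton)
    f <- gazedistill:::nn_forward(pp, batch, fit$config, train = FALSE)
    sum(gazedistill:::bce_from_logit(f$z, batch$y))
  }
  fd <- numeric(length(theta))
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    fd[k] <- (lossf(tp) - lossf(tm)) / (2 * h)
  }
  fd
}

# Independent recount of the confusion counts and metrics.
naive_metrics <- function(truth, pred) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(truth)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / length(truth),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

# Brute-force lattice count of pixels within `radius` of (x0, y0).
brute_disk_count <- function(x0, y0, radius, H, W) {
  n <- 0L
  for (u in 0:(W - 1)) for (v in 0:(H - 1))
    if ((u - x0)^2 + (v - y0)^2 <= radius^2) n <- n + 1L
  n
}
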