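# Minimal neural-network engine: 3x3 same-padding convolutions via im2col,
# 2x2 max pooling, global average pooling, a 2-layer LSTM with masked
# final-state extraction, linear heads, sigmoid/BCE loss, full backprop, and
# Adam. Activations are stored as arrays dim (H, W, C, B); sequences as lists
# of T_b x 2 matrices. Everything is deterministic given R's RNG state.

.im2col_cache <- new.env(parent = emptyenv())

# Linear indices into a zero-padded (H+2, W+2, C, B) array selecting, for each
# output pixel (row-major p fastest, then batch), the 3x3xC patch centred on
# it. Column order (di, dj, c), di fastest, matching the weight matrix layout.
conv_idx <- function(H, W, C, B) {
  key <- paste(H, W, C, B, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  base_p <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, `+`))
  off_k  <- as.vector(outer(0:2, (0:2) * Hp, `+`))
  off_c  <- (seq_len(C) - 1L) * (Hp * Wp)
  off_kc <- as.vector(outer(off_k, off_c, `+`))
  off_b  <- (seq_len(B) - 1L) * (Hp * Wp * C)
  rows   <- as.vector(outer(base_p, off_b, `+`))
  idx <- outer(rows, off_kc, `+`)
  storage.mode(idx) <- "integer"
  if (length(.im2col_cache) > 24) rm(list = ls(.im2col_cache), envir = .im2col_cache)
  .im2col_cache[[key]] <- idx
  idx
}

im2col <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  Xp <- array(0, c(H + 2L, W + 2L, C, B))
  Xp[2:(H + 1L), 2:(W + 1L), , ] <- X
  idx <- conv_idx(H, W, C, B)
  out <- Xp[idx]
  dim(out) <- dim(idx)
  out
}

# W stored as array (3, 3, Cin, Cout); matrix form rows ordered (di, dj, cin).
conv_forward <- function(X, W, b) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; B <- d[4]
  Cout <- dim(W)[4]
  Wm <- matrix(W, ncol = Cout)
  Xcol <- im2col(X)
  Y <- Xcol %*% Wm
  Y <- Y + rep(b, each = nrow(Y))
  out <- array(Y, c(H, Wd, B, Cout))
  list(out = aperm(out, c(1, 2, 4, 3)), Xcol = Xcol)
}

conv_backward <- function(dOut, Xcol, W) {
  d <- dim(dOut); H <- d[1]; Wd <- d[2]; Cout <- d[3]; B <- d[4]
  Cin <- dim(W)[3]
  dYmat <- matrix(aperm(dOut, c(1, 2, 4, 3)), ncol = Cout)
  dWm <- crossprod(Xcol, dYmat)
  db <- colSums(dYmat)
  # gradient w.r.t. the input: correlation of dOut with the flipped kernel
  Wf <- aperm(W[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))  # (3,3,Cout,Cin)
  Wfm <- matrix(Wf, ncol = Cin)
  dYcol <- im2col(dOut)
  dXmat <- dYcol %*% Wfm
  dX <- aperm(array(dXmat, c(H, Wd, B, Cin)), c(1, 2, 4, 3))
  list(dW = array(dWm, dim(W)), db = db, dX = dX)
}

maxpool_forward <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]
  a <- X[seq(1L, H, 2L), , , , drop = FALSE]
  b <- X[seq(2L, H, 2L), , , , drop = FALSE]
  m1 <- pmax(a, b); mask1 <- a >= b
  c1 <- m1[, seq(1L, W, 2L), , , drop = FALSE]
  c2 <- m1[, seq(2L, W, 2L), , , drop = FALSE]
  out <- pmax(c1, c2)
  list(out = out, mask1 = mask1, mask2 = c1 >= c2, dims = d)
}

maxpool_backward <- function(dOut, pool) {
  d <- pool$dims
  dm1 <- array(0, c(d[1] / 2L, d[2], d[3], d[4]))
  dm1[, seq(1L, d[2], 2L), , ] <- dOut * pool$mask2
  dm1[, seq(2L, d[2], 2L), , ] <- dOut * !pool$mask2
  dX <- array(0, d)
  dX[seq(1L, d[1], 2L), , , ] <- dm1 * pool$mask1
  dX[seq(2L, d[1], 2L), , , ] <- dm1 * !pool$mask1
  dX
}

gap_forward <- function(X) {
  d <- dim(X)
  m <- matrix(X, nrow = d[1] * d[2])
  t(matrix(colMeans(m), nrow = d[3]))  # B x C
}

gap_backward <- function(dOut, dims) {
  # dOut: B x C -> spread uniformly over the H*W positions
  g <- t(dOut) / (dims[1] * dims[2])               # C x B
  array(rep(as.vector(g), each = dims[1] * dims[2]),
        dims[c(1, 2)] |> c(dims[3], dims[4]))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable BCE from the logit: l = softplus(z) - y*z
bce_from_logit <- function(z, y) pmax(z, 0) - y * z + log1p(exp(-abs(z)))

# ---- CNN branch ------------------------------------------------------------

cnn_branch_forward <- function(X, par) {
  nlay <- length(par$conv)
  caches <- vector("list", nlay)
  A <- X
  for (l in seq_len(nlay)) {
    cf <- conv_forward(A, par$conv[[l]]$W, par$conv[[l]]$b)
    Z <- cf$out
    R <- pmax(Z, 0)
    cache <- list(Xcol = cf$Xcol, relu = Z > 0, in_dims = dim(A))
    if (l < nlay) {
      pl <- maxpool_forward(R)
      A <- pl$out
      cache$pool <- pl
    } else {
      cache$gap_dims <- dim(R)
      A <- gap_forward(R)   # B x C
    }
    caches[[l]] <- cache
  }
  feat <- A
  o <- as.vector(feat %*% par$head$W) + par$head$b  # length B
  list(o = o, feat = feat, caches = caches)
}

cnn_branch_backward <- function(d_o, fwd, par) {
  nlay <- length(par$conv)
  grads <- list(conv = vector("list", nlay))
  grads$head <- list(W = crossprod(fwd$feat, d_o), b = sum(d_o))
  dA <- matrix(d_o) %*% t(par$head$W)     # B x C
  for (l in rev(seq_len(nlay))) {
    cache <- fwd$caches[[l]]
    if (l == nlay) dR <- gap_backward(dA, cache$gap_dims)
    else dR <- maxpool_backward(dA, cache$pool)
    dZ <- dR * cache$relu
    cb <- conv_backward(dZ, cache$Xcol, par$conv[[l]]$W)
    grads$conv[[l]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  grads
}

# ---- LSTM branch -----------------------------------------------------------
# Gate order in the 4h-wide blocks: input, forget, cell, output.

lstm_layer_forward <- function(Xs, par, B, maxT, h) {
  Hs <- vector("list", maxT + 1L); Cs <- vector("list", maxT + 1L)
  gates <- vector("list", maxT)
  Hs[[1]] <- matrix(0, B, h); Cs[[1]] <- matrix(0, B, h)
  for (t in seq_len(maxT)) {
    z <- Xs[[t]] %*% par$Wx + Hs[[t]] %*% par$Wh + rep(par$b, each = B)
    i <- sigmoid(z[, 1:h, drop = FALSE])
    f <- sigmoid(z[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigmoid(z[, (3 * h + 1):(4 * h), drop = FALSE])
    Cs[[t + 1]] <- f * Cs[[t]] + i * g
    tc <- tanh(Cs[[t + 1]])
    Hs[[t + 1]] <- o * tc
    gates[[t]] <- list(i = i, f = f, g = g, o = o, tc = tc)
  }
  list(Hs = Hs, Cs = Cs, gates = gates)
}

# dH_inject: list per t of B x h gradients arriving at that step's output
# (zero matrices where nothing arrives).
lstm_layer_backward <- function(dH_inject, fwd, Xs, par, B, maxT, h) {
  dWx <- array(0, dim(par$Wx)); dWh <- array(0, dim(par$Wh)); db <- numeric(4 * h)
  dXs <- vector("list", maxT)
  dh <- matrix(0, B, h); dc <- matrix(0, B, h)
  for (t in rev(seq_len(maxT))) {
    dh <- dh + dH_inject[[t]]
    gt <- fwd$gates[[t]]
    do_ <- dh * gt$tc
    dc <- dc + dh * gt$o * (1 - gt$tc^2)
    di <- dc * gt$g
    dg <- dc * gt$i
    df <- dc * fwd$Cs[[t]]
    dc <- dc * gt$f
    dz <- cbind(di * gt$i * (1 - gt$i),
                df * gt$f * (1 - gt$f),
                dg * (1 - gt$g^2),
                do_ * gt$o * (1 - gt$o))
    dWx <- dWx + crossprod(Xs[[t]], dz)
    dWh <- dWh + crossprod(fwd$Hs[[t]], dz)
    db <- db + colSums(dz)
    dXs[[t]] <- dz %*% t(par$Wx)
    dh <- dz %*% t(par$Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dXs = dXs)
}

lstm_branch_forward <- function(seqs, par, dropout, train) {
  B <- length(seqs)
  lens <- vapply(seqs, nrow, integer(1))
  maxT <- max(lens)
  h <- nrow(par$layers[[1]]$Wh)
  Xs <- vector("list", maxT)
  for (t in seq_len(maxT)) {
    Xt <- matrix(0, B, 2L)
    on_t <- lens >= t
    if (any(on_t)) Xt[on_t, ] <- t(vapply(which(on_t), function(b) seqs[[b]][t, ],
                                          numeric(2)))
    Xs[[t]] <- Xt
  }
  f1 <- lstm_layer_forward(Xs, par$layers[[1]], B, maxT, h)
  H1 <- f1$Hs[-1]
  masks <- NULL
  if (train && dropout > 0) {
    keep <- 1 - dropout
    masks <- lapply(seq_len(maxT), function(t)
      matrix(stats::rbinom(B * h, 1L, keep) / keep, B, h))
    H1 <- lapply(seq_len(maxT), function(t) H1[[t]] * masks[[t]])
  }
  f2 <- lstm_layer_forward(H1, par$layers[[2]], B, maxT, h)
  hT <- matrix(0, B, h)
  for (b in seq_len(B)) hT[b, ] <- f2$Hs[[lens[b] + 1L]][b, ]
  o <- as.vector(hT %*% par$head$W) + par$head$b
  list(o = o, hT = hT, f1 = f1, f2 = f2, Xs = Xs, H1 = H1, masks = masks,
       lens = lens, maxT = maxT, B = B, h = h)
}

lstm_branch_backward <- function(d_o, fwd, par) {
  B <- fwd$B; maxT <- fwd$maxT; h <- fwd$h
  gW <- crossprod(fwd$hT, d_o)
  gb <- sum(d_o)
  d_hT <- matrix(d_o) %*% t(par$head$W)     # B x h
  zero <- matrix(0, B, h)
  inj2 <- rep(list(zero), maxT)
  for (t in seq_len(maxT)) {
    at_t <- fwd$lens == t
    if (any(at_t)) {
      m <- inj2[[t]]
      m[at_t, ] <- d_hT[at_t, , drop = FALSE]
      inj2[[t]] <- m
    }
  }
  b2 <- lstm_layer_backward(inj2, fwd$f2, fwd$H1, par$layers[[2]], B, maxT, h)
  inj1 <- b2$dXs
  if (!is.null(fwd$masks))
    inj1 <- lapply(seq_len(maxT), function(t) inj1[[t]] * fwd$masks[[t]])
  b1 <- lstm_layer_backward(inj1, fwd$f1, fwd$Xs, par$layers[[1]], B, maxT, h)
  list(layers = list(list(Wx = b1$dWx, Wh = b1$dWh, b = b1$db),
                     list(Wx = b2$dWx, Wh = b2$dWh, b = b2$db)),
       head = list(W = gW, b = gb))
}

# ---- Whole model -----------------------------------------------------------

nn_init_params <- function(config) {
  filt <- config$conv_filters
  k2 <- config$kernel_size^2
  init_cnn <- function() {
    cin <- 1L
    conv <- vector("list", length(filt))
    for (l in seq_along(filt)) {
      fan_in <- k2 * cin
      conv[[l]] <- list(
        W = array(stats::rnorm(k2 * cin * filt[l], sd = sqrt(2 / fan_in)),
                  c(config$kernel_size, config$kernel_size, cin, filt[l])),
        b = numeric(filt[l]))
      cin <- filt[l]
    }
    # heads are initialised at unit scale: each branch is reduced to a single
    # scalar and then passed through a second linear layer, so two
    # small-variance layers in series would make the initial logit (and the
    # gradient flow) vanishingly small
    list(conv = conv,
         head = list(W = matrix(stats::rnorm(cin, sd = sqrt(4 / cin)), cin, 1),
                     b = 0))
  }
  h <- config$lstm_hidden
  init_lstm_layer <- function(din) {
    s <- sqrt(1 / h)
    list(Wx = matrix(stats::runif(din * 4 * h, -s, s), din, 4 * h),
         Wh = matrix(stats::runif(h * 4 * h, -s, s), h, 4 * h),
         b = numeric(4 * h))
  }
  list(img = init_cnn(),
       fix = init_cnn(),
       scn = list(layers = list(init_lstm_layer(2L), init_lstm_layer(h)),
                  head = list(W = matrix(stats::rnorm(h, sd = sqrt(4 / h)), h, 1),
                              b = 0)),
       # moderate fusion init: large enough that gradients flow into the
       # branch encoders from the first step (a zero fusion layer never
       # bootstraps), small enough that random branch mixtures do not swamp
       # the logit early on
       final = list(W = matrix(stats::rnorm(3, sd = 0.5), 3, 1), b = 0))
}

nn_flatten <- function(p) unlist(p, use.names = FALSE)

nn_unflatten <- function(vec, skel) {
  pos <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    dim(out) <- dim(s)
    out
  }
  rec(skel)
}

# Names of the flattened parameter vector, in nn_flatten() order.
nn_param_names <- function(p) names(unlist(p))

nn_forward <- function(params, batch, config, train = FALSE) {
  fi <- cnn_branch_forward(batch$img, params$img)
  ff <- cnn_branch_forward(batch$fix, params$fix)
  fs <- lstm_branch_forward(batch$seqs, params$scn, config$lstm_dropout, train)
  feats <- cbind(fi$o, ff$o, fs$o)                  # B x 3
  z <- as.vector(feats %*% params$final$W) + params$final$b
  list(z = z, p = sigmoid(z), feats = feats, img = fi, fix = ff, scn = fs)
}

# scale: multiplier on the per-sample logit gradient (1/B for a mean-loss
# training step, 1 for per-sample attribution gradients).
nn_backward <- function(params, fwd, batch, config, scale = 1) {
  dz <- (fwd$p - batch$y) * scale                   # length B
  gfinal <- list(W = crossprod(fwd$feats, dz), b = sum(dz))
  dfeat <- matrix(dz) %*% t(params$final$W)         # B x 3
  list(img = cnn_branch_backward(dfeat[, 1], fwd$img, params$img),
       fix = cnn_branch_backward(dfeat[, 2], fwd$fix, params$fix),
       scn = lstm_branch_backward(dfeat[, 3], fwd$scn, params$scn),
       final = gfinal)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
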