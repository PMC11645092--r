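# Small internal helpers shared across the package.

# Round half away from zero (base round() is half-to-even). The duration
# rescale and the retained-subset sizes are defined with this convention.
round_half_up <- function(x) floor(x + 0.5)

# Derive a 31-bit child seed from (seed, offset) so that independent
# substreams (per image, per run, per tier) are reproducible regardless of
# call order. Knuth multiplicative constant; exact in double arithmetic for
# the seed magnitudes R accepts.
derive_seed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) %% 65536) * 65536 + (abs(as.numeric(offset)) %% 65536)
  as.integer((s * 2654435761) %% 2147483647) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bilinear resampling of a numeric matrix to out_h x out_w, values clamped to
# the source range. Used to bring stimuli and fixation maps to the network
# input size.
resize_bilinear <- function(mat, out_h, out_w) {
  h <- nrow(mat); w <- ncol(mat)
  if (h == out_h && w == out_w) return(mat)
  # map output pixel centres into source coordinates
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- mat[y0, x0, drop = FALSE]; b <- mat[y0, x1, drop = FALSE]
  c_ <- mat[y1, x0, drop = FALSE]; d <- mat[y1, x1, drop = FALSE]
  top <- a * (1 - rep(fx, each = out_h)) + b * rep(fx, each = out_h)
  bot <- c_ * (1 - rep(fx, each = out_h)) + d * rep(fx, each = out_h)
  top * (1 - fy) + bot * fy
}
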