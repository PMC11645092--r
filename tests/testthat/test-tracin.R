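# Checkpoint-replay attribution: the accumulation rule, gradient contracts,
# rankings and proponents/opponents.

test_that("the influence accumulation rule evaluates hand examples exactly", {
  # one checkpoint, eta = 0.1, gradient (3, 4): 0.1 * 25 = 2.5
  g <- list(matrix(c(3, 4), 1, 2))
  expect_equal(as.numeric(tracin_score(0.1, g, g)), 2.5)
  # two checkpoints, eta = (0.1, 0.05), gradients (1,0) then (0,2)
  gs <- list(matrix(c(1, 0), 1, 2), matrix(c(0, 2), 1, 2))
  expect_equal(as.numeric(tracin_score(c(0.1, 0.05), gs, gs)), 0.3)
  # orthogonal gradients at every checkpoint give zero influence
  ga <- list(matrix(c(1, 0), 1, 2)); gb <- list(matrix(c(0, 5), 1, 2))
  expect_equal(as.numeric(tracin_score(1, ga, gb)), 0)
  # bilinearity in each gradient argument
  set.seed(3)
  A <- list(matrix(rnorm(8), 2, 4)); B <- list(matrix(rnorm(12), 3, 4))
  expect_equal(tracin_score(0.7, lapply(A, `*`, 3), B),
               3 * tracin_score(0.7, A, B))
})

test_that("per-sample gradients are deterministic and vanish at a fitted optimum", {
  tf <- tiny_fit()
  fit <- tf$fit
  g1 <- per_sample_gradient(fit, 5, checkpoint = 2, mode = "full")
  g2 <- per_sample_gradient(fit, 5, checkpoint = 2, mode = "full")
  expect_identical(g1, g2)
  expect_length(per_sample_gradient(fit, 5, mode = "last_layer"), 4L)
  # a hugely confident correct prediction has (numerically) zero gradient
  sat <- fit$params
  lab <- fit$labels[1]
  sat$final$W[] <- 0
  sat$final$b <- if (lab == 1) 50 else -50
  cp <- checkpoint_set(fit)
  cp$theta[[1]] <- gazedistill:::nn_flatten(sat)
  g <- per_sample_gradient(cp, 1, checkpoint = 1, mode = "last_layer",
                           records = tf$corpus$records)
  expect_lt(max(abs(g)), 1e-12)
})

test_that("self-influence equals influence(x, x) and is non-negative", {
  tf <- tiny_fit()
  fit <- tf$fit
  idx <- fit$split$train[1:12]
  si <- tracin_self_influence(fit, idx)
  expect_true(all(si >= 0))
  inf <- tracin_influence(fit, idx, idx)
  expect_equal(unname(diag(inf)), unname(si), tolerance = 1e-12)
  expect_equal(inf, t(inf), tolerance = 1e-12)
})

test_that("rankings are order-invariant and tie-broken by sample id", {
  tf <- tiny_fit()
  fit <- tf$fit
  idx <- fit$split$train[1:15]
  r1 <- rank_self_influence(fit, idx)
  r2 <- rank_self_influence(fit, rev(idx))
  expect_identical(r1, r2)
  expect_true(all(diff(r1$score) <= 0))
  expect_error(rank_self_influence(fit, integer(0)), "empty")
})

test_that("an exact training copy of the test sample is its top proponent", {
  tf <- tiny_fit()
  fit <- tf$fit
  cp <- checkpoint_set(fit, subsample = fit$config$epochs)  # single checkpoint
  idx <- fit$split$train
  G <- gazedistill:::tracin_gradient_matrix(cp, fit$tensors, idx, 1, "last_layer")
  # pick the training sample with the largest gradient norm as the "test"
  # sample: by Cauchy-Schwarz nothing can beat its own inner product
  star <- which.max(rowSums(G * G))
  po <- proponents_opponents(fit, test_idx = idx[star], train_idx = idx,
                             top_k = 3)
  expect_equal(po$proponents$idx[1], idx[star])
  expect_equal(nrow(po$opponents), 3)
  expect_true(all(po$proponents$score >= max(po$opponents$score)))
  expect_error(proponents_opponents(fit, idx[1], idx, top_k = length(idx) + 1))
})

test_that("Cauchy-Schwarz bounds pairwise influence at a single checkpoint", {
  tf <- tiny_fit()
  fit <- tf$fit
  cp <- checkpoint_set(fit, subsample = fit$config$epochs)
  idx <- fit$split$train[1:10]
  inf <- tracin_influence(cp, idx, idx, records = tf$corpus$records)
  si <- tracin_self_influence(cp, idx, records = tf$corpus$records)
  for (a in 1:10) for (b in 1:10)
    expect_lte(inf[a, b]^2, si[a] * si[b] * (1 + 1e-10) + 1e-300)
})

test_that("duplicated records receive identical scores, ordered by id", {
  tf <- tiny_fit()
  corp <- tf$corpus
  recs <- corp$records[1:10]
  dup <- recs[[4]]
  dup$sample_id <- "zzz_duplicate"
  recs[[11]] <- dup
  cp <- checkpoint_set(tf$fit)
  r <- rank_self_influence(cp, records = recs)
  s4 <- r$score[r$sample_id == recs[[4]]$sample_id]
  sz <- r$score[r$sample_id == "zzz_duplicate"]
  expect_equal(s4, sz)
  pos <- match(c(recs[[4]]$sample_id, "zzz_duplicate"), r$sample_id)
  expect_lt(pos[1], pos[2])  # equal scores: lexicographic id order
})
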