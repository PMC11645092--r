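# Shared fixtures: a tiny network configuration, tiny synthetic corpora, and
# small fitted models, built in code at test time.

tiny_config <- function(epochs = 4L, ...) {
  gaze_config("desk", input_size = 16L, conv_filters = c(2L, 3L),
              lstm_hidden = 4L, epochs = epochs, batch_size = 8L, ...)
}

tiny_corpus <- function(n_images = 5L, npp = 2L, seed = 5L, noise = 0,
                        image_size = c(32L, 32L), ...) {
  build_synthetic_corpus(synthetic_gaze_spec(
    n_images = n_images, n_participants_per_group = npp,
    image_size = image_size, label_noise_rate = noise, seed = seed, ...))
}

# cache expensive fixtures across test files within one session
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  hit <- .fixture_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .fixture_cache[[key]] <- val
  val
}

# A small fitted classifier on a 50-record corpus with some label noise,
# used by the attribution tests (<= 5k parameters, 4 checkpoints).
tiny_fit <- function() {
  cached("tiny_fit", {
    corp <- tiny_corpus(n_images = 5L, npp = 5L, seed = 11L, noise = 0.1)
    cfg <- tiny_config()
    fit <- gaze_classifier(corp$records, cfg, seed = 3L, split_seed = 9L)
    list(corpus = corp, fit = fit)
  })
}

# random scanpath for IO round-trip tests (integer coordinates, 2-decimal ms)
random_scanpath <- function(n = NULL, image_id = "imgX", group = "TD",
                            participant = 1L, W = 100L, H = 80L) {
  n <- n %||% sample(2:12, 1)
  scanpath(data.frame(x = sample.int(W, n) - 1L, y = sample.int(H, n) - 1L,
                      duration = round(stats::rlnorm(n, log(250), 0.5), 2)),
           participant_index = participant, image_id = image_id,
           group_label = group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
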