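# The desk-scale stochastic experiment grid shared by the distillation and
# attribution acceptance checks: five independent seeds, each regenerating
# the ~300-record noisy corpus (10% flipped labels) and retraining, so that
# both generation and training variability are covered. Per seed: full-data
# training (8 epochs, 32x32 inputs), self-influence ranking from the FT
# checkpoints, influence-selected (SIST) and matched random (RST) retraining
# at the 77% usage tier on the shared test split, and category-aggregated
# pairwise influence with full-parameter gradients.

stochastic_grid <- function(base_seed = 100L) {
  cached(paste0("grid", base_seed), {
    cfg <- gaze_config("desk")
    out <- list()
    for (s in 1:5) {
      spec <- synthetic_gaze_spec(label_noise_rate = 0.1,
                                  seed = gazedistill:::derive_seed(base_seed, s))
      corp <- build_synthetic_corpus(spec)
      plan <- experiment_plan(tiers = 0.77, runs = 1,
                              seeds = gazedistill:::derive_seed(2L * base_seed, s),
                              base_seed = gazedistill:::derive_seed(3L * base_seed, s))
      ex <- run_experiment(corp$records, plan, cfg)
      rk <- ex$self_influence[[1]]
      tr <- ex$split$train
      pct <- 1 - (match(corp$truth$sample_id[tr], rk$sample_id) - 0.5) / nrow(rk)
      fl <- corp$truth$flipped[tr]
      runs <- ex$runs
      out[[s]] <- list(
        flip_pct = mean(pct[fl]), clean_pct = mean(pct[!fl]),
        ft = subset(runs, variant == "FT")$accuracy,
        sist = subset(runs, variant == "SIST")$accuracy,
        rst = subset(runs, variant == "RST")$accuracy,
        n_train = length(tr), n_records = length(corp$records),
        top_category = if (!is.null(ex$category)) ex$category$category[1] else "none")
      unlink(corp$dir, recursive = TRUE)
    }
    out
  })
}
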