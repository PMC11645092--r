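# The distillation experiment grid: full-data training (FT), retraining on
# the lowest-self-influence subset (SIST), and retraining on a matched-size
# random subset (RST) at each dataset-usage tier, all evaluated on one shared
# test split and averaged over independently seeded runs; plus category-level
# aggregation of pairwise influence.

#' Experiment plan for the distillation grid
#'
#' @param tiers retained training fractions (dataset-usage tiers); defaults
#'   to 77%, 67% and 50%.
#' @param runs number of independent runs `r` (different training seeds).
#' @param seeds training seeds, one per run (derived from `base_seed` when
#'   `NULL`).
#' @param base_seed seed from which run seeds and the shared split are
#'   derived.
#' @param attribution also compute per-run pairwise influence and its
#'   category aggregation (see [aggregate_influence_by_category()]).
#' @param attribution_mode gradient subset for the pairwise influence;
#'   `"full"` by default because the category structure lives in the branch
#'   encoder gradients, which the 4-dimensional fusion-layer gradient (whose
#'   bias coordinate dominates every inner product) cannot resolve.
#' @param target_class class whose test samples drive the category
#'   aggregation (1 = ASD).
#' @param top_m proponent images reported per category.
#' @return List of class `"experiment_plan"`.
#' @export
experiment_plan <- function(tiers = c(0.77, 0.67, 0.50), runs = 5L,
                            seeds = NULL, base_seed = 1L, attribution = TRUE,
                            attribution_mode = c("full", "last_layer"),
                            target_class = 1L, top_m = 3L) {
  stopifnot(all(tiers > 0), all(tiers <= 1), runs >= 1)
  seeds <- seeds %||% vapply(seq_len(runs), function(i)
    derive_seed(base_seed, 1000L + i), integer(1))
  stopifnot(length(seeds) == runs)
  structure(list(tiers = tiers, runs = as.integer(runs), seeds = seeds,
                 base_seed = as.integer(base_seed),
                 attribution = isTRUE(attribution),
                 attribution_mode = match.arg(attribution_mode),
                 target_class = as.integer(target_class),
                 top_m = as.integer(top_m)),
            class = "experiment_plan")
}

#' Retain the lowest-self-influence fraction of the training set
#'
#' Removal follows the descending self-influence ranking: the
#' `N - round(usage_fraction * N)` highest-scoring samples are removed, the
#' rest retained, so retained and removed partition the training set and
#' every retained score is at most every removed score (up to ties).
#'
#' @param ranking descending ranking from [rank_self_influence()].
#' @param usage_fraction fraction of samples to retain, in (0, 1].
#' @return List with data.frames `retained` and `removed` (same columns as
#'   the ranking).
#' @export
filter_by_self_influence <- function(ranking, usage_fraction) {
  if (usage_fraction <= 0 || usage_fraction > 1)
    stop("usage_fraction must be in (0, 1]")
  N <- nrow(ranking)
  n_keep <- round_half_up(usage_fraction * N)
  removed <- utils::head(ranking, N - n_keep)
  retained <- utils::tail(ranking, n_keep)
  list(retained = retained, removed = removed)
}

#' Uniform random training subset of matched size
#'
#' Samples without replacement; at a given tier its size equals the
#' influence-selected subset's size by construction (`round(fraction * N)`),
#' keeping the comparison budget-matched.
#'
#' @param train_idx training indices.
#' @param usage_fraction fraction retained, in (0, 1].
#' @param seed RNG seed (reproducible).
#' @return Sorted integer subset of `train_idx`.
#' @export
random_subset <- function(train_idx, usage_fraction, seed) {
  if (usage_fraction <= 0 || usage_fraction > 1)
    stop("usage_fraction must be in (0, 1]")
  n_keep <- round_half_up(usage_fraction * length(train_idx))
  sort(with_seed(seed, sample(train_idx, n_keep)))
}

#' Aggregate pairwise influence by stimulus category
#'
#' For each stimulus category, the mean of the positive influence scores its
#' training samples exert on the supplied test columns (pairs with
#' non-positive influence do not contribute), together with the most
#' frequent top-proponent images. Categories outside the known vocabulary
#' are flagged `"other"`.
#'
#' @param influence train-by-test influence matrix (rows named by training
#'   sample id), typically restricted to correctly classified test samples
#'   of the target class.
#' @param train_image_ids,train_categories stimulus id and category of each
#'   training row.
#' @param top_m how many top-proponent images to report per category.
#' @return data.frame (`category`, `mean_positive_influence`,
#'   `n_positive_pairs`, `n_train`, `top_images`), ordered by decreasing
#'   mean positive influence.
#' @export
aggregate_influence_by_category <- function(influence, train_image_ids,
                                            train_categories, top_m = 3L) {
  stopifnot(nrow(influence) == length(train_image_ids),
            length(train_image_ids) == length(train_categories))
  known <- c("people", "objects", "landscapes", "other")
  train_categories <- ifelse(train_categories %in% known, train_categories, "other")
  top_train <- apply(influence, 2, which.max)
  rows <- lapply(sort(unique(train_categories)), function(cat) {
    rws <- train_categories == cat
    vals <- influence[rws, , drop = FALSE]
    pos <- vals[vals > 0]
    prop_imgs <- table(train_image_ids[top_train][train_categories[top_train] == cat])
    top_imgs <- if (length(prop_imgs))
      paste(names(sort(prop_imgs, decreasing = TRUE))[seq_len(min(top_m, length(prop_imgs)))],
            collapse = ";") else ""
    data.frame(category = cat,
               mean_positive_influence = if (length(pos)) mean(pos) else 0,
               n_positive_pairs = length(pos), n_train = sum(rws),
               top_images = top_imgs)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_positive_influence, out$category), ]
  rownames(out) <- NULL
  out
}

#' Run the full distillation experiment grid
#'
#' Per run seed: trains the full-data model (FT), computes self-influence of
#' the training samples from the FT checkpoints, builds the
#' influence-selected (SIST) and matched random (RST) subsets at every tier,
#' retrains each variant, and evaluates everything on the one shared test
#' split; results are averaged over runs with their dispersion. When
#' `plan$attribution` is set, pairwise influence of the FT training samples
#' on correctly classified target-class test samples is aggregated by
#' stimulus category per run.
#'
#' @param records the corpus (list of [sample_record] objects).
#' @param plan an [experiment_plan()].
#' @param config a [gaze_config()].
#' @param categories optional named vector image_id -> category (taken from
#'   the records when `NULL`).
#' @param verbose print progress lines.
#' @return Object of class `"distill_experiment"`: `table` (mean +/- sd per
#'   variant x tier), `runs` (per-run metrics), `category` (per-run category
#'   aggregation), `self_influence` (per-run rankings), `split`, `plan`.
#' @export
run_experiment <- function(records, plan = experiment_plan(),
                           config = gaze_config("desk"), categories = NULL,
                           verbose = FALSE) {
  split <- stratified_split(records, config$split,
                            seed = derive_seed(plan$base_seed, 77L),
                            mode = config$split_mode)
  if (is.null(categories)) {
    categories <- vapply(records, function(r) r$image$category %||% "other",
                         character(1))
    names(categories) <- vapply(records, function(r) r$image_id, character(1))
    categories <- categories[!duplicated(names(categories))]
  }
  run_rows <- list(); cat_tables <- list(); rankings <- list()
  stage <- "setup"
  note <- function(...) if (verbose) message(sprintf(...))
  res <- tryCatch({
    for (s in seq_len(plan$runs)) {
      seed <- plan$seeds[s]
      stage <- sprintf("run %d: FT training", s)
      note("[%s]", stage)
      ft <- gaze_classifier(records, config, seed = seed, split = split)
      m_ft <- evaluate_split(ft)
      run_rows[[length(run_rows) + 1L]] <-
        cbind(data.frame(variant = "FT", tier = NA_real_, usage = 1,
                         run = s, seed = seed), as.data.frame(m_ft))
      stage <- sprintf("run %d: self-influence", s)
      ranking <- rank_self_influence(ft)
      rankings[[s]] <- ranking
      for (tier in plan$tiers) {
        stage <- sprintf("run %d: tier %.2f", s, tier)
        note("[%s]", stage)
        sist_idx <- sort(filter_by_self_influence(ranking, tier)$retained$idx)
        rst_idx <- random_subset(split$train, tier,
                                 seed = derive_seed(seed, round(tier * 1000)))
        stopifnot(length(sist_idx) == length(rst_idx))
        for (variant in c("SIST", "RST")) {
          idx <- if (variant == "SIST") sist_idx else rst_idx
          sub_split <- list(train = idx, val = split$val, test = split$test)
          fitv <- gaze_classifier(records, config, seed = seed, split = sub_split)
          mv <- evaluate_split(fitv)
          run_rows[[length(run_rows) + 1L]] <-
            cbind(data.frame(variant = variant, tier = tier, usage = tier,
                             run = s, seed = seed), as.data.frame(mv))
        }
      }
      if (plan$attribution) {
        stage <- sprintf("run %d: attribution", s)
        note("[%s]", stage)
        p_test <- nn_predict_probs(ft$params, ft$tensors, split$test, ft$config)
        correct <- (p_test >= config$threshold) == (ft$labels[split$test] == 1L)
        sel <- split$test[correct & ft$labels[split$test] == plan$target_class]
        if (length(sel)) {
          inf <- tracin_influence(ft, split$train, sel,
                                  mode = plan$attribution_mode)
          img_ids <- vapply(records[split$train], function(r) r$image_id,
                            character(1))
          cat_tables[[s]] <- cbind(run = s, aggregate_influence_by_category(
            inf, img_ids, unname(categories[img_ids]), plan$top_m))
        }
      }
    }
    NULL
  }, error = function(e) e)
  runs_df <- do.call(rbind, run_rows)
  if (!is.null(res))
    stop(sprintf("experiment failed at stage [%s]: %s (partial results: %d rows)",
                 stage, conditionMessage(res), nrow(runs_df %||% data.frame())))
  agg <- stats::aggregate(cbind(accuracy, precision, recall, f1) ~ variant + usage,
                          data = runs_df, FUN = mean)
  sdv <- stats::aggregate(cbind(accuracy, precision, recall, f1) ~ variant + usage,
                          data = runs_df, FUN = stats::sd)
  names(sdv)[3:6] <- paste0(names(sdv)[3:6], "_sd")
  table <- merge(agg, sdv, by = c("variant", "usage"))
  table <- table[order(factor(table$variant, c("FT", "SIST", "RST")),
                       -table$usage), ]
  rownames(table) <- NULL
  structure(list(table = table, runs = runs_df,
                 category = if (length(cat_tables)) do.call(rbind, cat_tables),
                 self_influence = rankings, split = split, plan = plan,
                 config = config),
            class = "distill_experiment")
}

#' @export
print.distill_experiment <- function(x, ...) {
  cat(sprintf("<distill_experiment> %d runs x tiers (%s); shared test n=%d\n",
              x$plan$runs, paste(x$plan$tiers, collapse = ", "),
              length(x$split$test)))
  print(x$table, digits = 4)
  if (!is.null(x$category)) {
    cat("\nTop category by mean positive influence, per run:\n")
    top <- do.call(rbind, lapply(split(x$category, x$category$run),
                                 function(d) d[1, c("run", "category",
                                                    "mean_positive_influence")]))
    print(top, digits = 4, row.names = FALSE)
  }
  invisible(x)
}
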