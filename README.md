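# gazedistill

Eye-tracking-based screening support for Autism Spectrum Disorder (ASD),
with explainable training: **gazedistill** classifies viewers as ASD or
typically developing (TD) from their scanpaths — the ordered fixation
sequences $(x_i, y_i, d_i)$ they produce while free-viewing natural images —
and then uses gradient-based training-data attribution to ask *which
training samples taught the model what*. It is aimed at researchers working
with free-viewing gaze corpora (e.g. the aggregated per-stimulus scanpath
text format popularised by ASD saliency benchmarks) who want an auditable,
fully scripted pipeline from raw fixation files to a trained classifier,
influence diagnostics and dataset-distillation experiments.

## What it implements

**Preprocessing and augmentation.** Aggregated scanpath files (columns
index / x / y / duration, the per-participant index restarting at 0) are
decomposed into individual scanpaths and paired with their stimuli. Sparse
scanpaths are densified by rescaling durations onto $[1,100]$
(per-scanpath min/max, half-up rounding), replicating each fixation
proportionally to its scaled duration with independent integer jitter
$\Delta x, \Delta y \in [-10, 10]$ px, and rendering binary fixation maps as
unions of radius-10 disks around the original fixations.

**The classifier.** A three-branch network — a CNN over the stimulus, a CNN
over the fixation map, an LSTM over the coordinate sequence — each branch
reduced to a scalar by a linear head:

$$\hat y = \sigma\!\left(\mathrm{Linear}\big[\,O_{img},\, O_{fix},\, O_{scn}\,\big]\right),
\qquad O_{scn} = \mathrm{Linear}\big(\mathrm{LSTM}(s_{i,j})_{h_T}\big),$$

trained with binary cross-entropy and Adam, snapshotting parameters after
every epoch. The network, backpropagation and optimiser are implemented in
base R over BLAS matrix algebra (there is no deep-learning framework
dependency); gradients are verified against central finite differences.

**Attribution (TracIn-style checkpoint replay).** With checkpoints
$w^{(i)}$ and learning rates $\eta_i$,

$$\mathrm{Influence}(x, x') = \sum_{i=1}^{k} \eta_i\,
\nabla \ell(w^{(i)}, x)\cdot\nabla \ell(w^{(i)}, x'), \qquad
\mathrm{SelfInfluence}(x) = \mathrm{Influence}(x, x).$$

Self-influence ranks outliers and mislabeled samples; pairwise influence
yields proponents/opponents per test sample and category-level aggregation
of which stimulus classes drive the ASD decision.

**Distillation experiments.** `run_experiment()` compares full-data training
(FT) against retraining on the lowest-self-influence subset (SIST) and a
matched-size random subset (RST) at usage tiers (77/67/50% by default), on
one shared test split, averaged over independently seeded runs.

**Synthetic gaze corpus.** `build_synthetic_corpus()` generates a desk-scale
corpus (default 300 records: 30 stimuli × 2 groups × 5 participants) with a
planted social-attention effect — on "people" images TD fixations land in
the face-like social region with probability 0.7 vs 0.3 for the ASD-like
group — written to disk in the same file formats the readers consume, with
controllable label noise and a full ground-truth manifest.

## Worked example

```r
library(gazedistill)

# a synthetic corpus with 10% flipped labels, written and re-read from disk
spec <- synthetic_gaze_spec(label_noise_rate = 0.1, seed = 7)
corpus <- build_synthetic_corpus(spec)
corpus
#> <gaze_corpus> 300 records (30 images x 2 groups x 5 participants), 30 flipped labels
#>   categories: landscapes=10 objects=8 people=12 | dir: /tmp/...

fit <- gaze_classifier(corpus$records, gaze_config("desk"), seed = 2, split_seed = 5)
summary(fit)
#> <gaze_classifier> 300 records (train 240 / val 30 / test 30), 8 epochs, seed 2
#>   fusion coefficients: o_img=0.454  o_fix=-0.124  o_scnpts=0.324  (Intercept)=-0.006
#> ...
#> test  <gaze_metrics> n=30  acc=0.5667  P=0.5833  R=0.4667  F1=0.5185
#>   counts: TP=7 FP=5 FN=8 TN=10

# which training samples did the optimiser fight with?
ranking <- rank_self_influence(fit)
head(ranking, 3)
#>        sample_id idx      score
#> 1  img001_td_p02   2 0.02731610
#> 2 img003_asd_p03  28 0.02122692
#> 3  img019_td_p02 182 0.01967573

# flipped labels concentrate toward the top of the ranking
mean_pct <- function(ids) mean(1 - (match(ids, ranking$sample_id) - 0.5) / nrow(ranking))
tr <- fit$split$train
mean_pct(corpus$truth$sample_id[tr][corpus$truth$flipped[tr]])    # flipped
#> [1] 0.571
mean_pct(corpus$truth$sample_id[tr][!corpus$truth$flipped[tr]])   # clean
#> [1] 0.493
```

The numbers mean: the desk-scale model reaches ~0.57 test accuracy here
(only the "people" third of the records is separable at all, and 10% of test
labels are themselves flipped, so ~0.65 is the practical ceiling), and the
mislabeled training records sit higher in the self-influence ranking (mean
percentile 0.57) than clean ones (0.49) — the screening signal the
distillation step exploits. Both quantities are noisy at this scale: a
single 300-record corpus draw can mask the ordering, which is why the
package's experiment protocol regenerates the corpus and retrains over five
seeds and reports the aggregate.

The full experiment grid, with influence-selected vs random retraining and
category attribution:

```r
plan <- experiment_plan(tiers = 0.77, runs = 1, base_seed = 1)
ex <- run_experiment(corpus$records, plan, gaze_config("desk"))
ex$table[, c("variant", "usage", "accuracy", "f1")]
```

A thin command-line front end over the same functions ships in
`inst/cli/gazedistill` (subcommands `synth`, `train`, `attribute`,
`distill`).

## Scientific caveats

The synthetic corpus is a structural stand-in for real gaze recordings
(planted effect sizes, i.i.d. scanpaths, no oculomotor noise); results on it
demonstrate that the pipeline recovers a planted social-attention effect,
not real-data performance. Record-level splits can leak participants in real
corpora — a participant-disjoint split mode is provided. See the methods
vignette (`vignettes/gaze-classification-and-attribution.Rmd`) for the full
model description, design decisions and limitations.
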