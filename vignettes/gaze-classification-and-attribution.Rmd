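---
title: "Gaze-based ASD classification, influence attribution and dataset distillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-based ASD classification, influence attribution and dataset distillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gazedistill)
```

## The problem

Children on the autism spectrum tend to allocate visual attention differently
from typically developing (TD) children — most prominently, fewer and shorter
fixations on socially relevant content such as faces. Eye trackers make this
measurable: a free-viewing experiment yields, per child and per stimulus
image, a *scanpath* — the time-ordered sequence of fixations $(x_i, y_i, d_i)$
with pixel coordinates and millisecond durations. gazedistill implements a
complete desk-scale pipeline that turns such scanpaths into an individual-level
ASD/TD classifier and then interrogates the trained model with
gradient-based training-data attribution.

The corpora this targets distribute *aggregated* scanpath files: one text file
per stimulus and group, with columns (index, x, y, duration), where the
within-participant fixation index restarts at 0 for each participant.
`read_scanpaths()` decomposes such a file at its index-0 rows — the
decomposition is unique because the index column encodes exactly where each
participant's sequence begins — and `pair_with_stimuli()` attaches each
decomposed scanpath to its stimulus image, producing one classification unit
(a `sample_record`) per participant-image pair.

## Augmentation

Individual scanpaths are sparse (sometimes only two fixations), so three
transformations densify them:

1. **Duration rescaling.** Durations are mapped linearly onto $[1, 100]$ using
   the scanpath's own minimum and maximum,
   $d'_i = \mathrm{round}(1 + 99\,(d_i - d_{\min})/(d_{\max} - d_{\min}))$,
   with half-up rounding. Because the anchors are per-scanpath, the map is
   invariant to the unit durations are expressed in. When all durations are
   equal the map is undefined; we assign the midpoint 50, avoiding both
   extremes (a recorded design choice — any constant in range would satisfy
   the counting invariants).
2. **Duration-proportional replication with jitter.** Fixation $i$ is
   replicated $d'_i$ times and every replica is shifted by an independent
   uniform *integer* offset $\Delta x, \Delta y \in [-10, 10]$ px, then clipped
   to the image bounds. Replication is proportional to duration, so temporal
   structure is preserved; independent shifts broaden the covered area.
   Clipping (rather than resampling) keeps the replica count exactly
   $\sum_i d'_i$. Whether the offsets should be integer or continuous, and
   whether rounding is half-up, is not pinned down by the protocol we follow;
   both choices are recorded here and exercised by the tests.
3. **Fixation maps.** A binary raster marks every pixel within Euclidean
   radius 10 px of any *original* (pre-jitter) fixation — the union of disks.
   Maps are rendered from the original fixations because map recreation is a
   parallel representation of the same scanpath, not a downstream product of
   the jitter. A count-map variant (`mode = "count"`) is available.

## The classifier

`gaze_classifier()` fits a three-branch network, each branch reduced to a
scalar by its own linear head:

$$O_{img} = \mathrm{Linear}(\mathrm{CNN}_{img}(I_j)), \quad
  O_{fix} = \mathrm{Linear}(\mathrm{CNN}_{fix}(M_{i,j})), \quad
  O_{scn} = \mathrm{Linear}(\mathrm{LSTM}(s_{i,j})_{h_T})$$

with $I_j$ the stimulus, $M_{i,j}$ the fixation map and $s_{i,j}$ the
coordinate sequence; the concatenated 3-vector passes through a final linear
layer and a sigmoid to give $\hat y = P(\mathrm{ASD})$, trained with binary
cross-entropy and Adam. The reference configuration (`gaze_config()`) uses
four 3x3 convolution layers per CNN branch (filters 32/64/128/256, ReLU,
2x2 max pooling after the first three layers, global average pooling after
the last) and a 2-layer LSTM with hidden size 1024 and inter-layer dropout
0.3, trained 16 epochs. A sigmoid over one logit is used rather than a
two-class softmax — they are mathematically equivalent for two classes, and
the single logit matches the binary cross-entropy loss.

The engine is written in base R over BLAS-backed matrix algebra:
convolutions via cached im2col index maps, the convolution input-gradient as
a correlation with the flipped kernel, batched LSTM steps with masked
final-state extraction (`h_T` is taken at each sequence's true last step, so
variable-length scanpaths batch without trimming). Backpropagation is exact:
the test suite compares it against central finite differences to a relative
error below $10^{-4}$ (observed ~$10^{-10}$).

Two initialisation choices matter at this depth-2-linear bottleneck (branch
head then fusion layer): heads are initialised at unit output scale and the
fusion layer with small random weights. Two consecutive small-variance linear
maps would otherwise make both the initial logit and the gradient flowing
back into the encoders vanishingly small; a zero fusion layer is even worse —
it never bootstraps, because encoder gradients are proportional to the fusion
weights. LSTM inputs are the fixation coordinates normalised to $[-1, 1]$ by
the original image dimensions, making the branch invariant to stimulus size.

After every epoch the full parameter vector and its learning rate are
snapshotted (`checkpoint_set()`), which is what attribution replays.
Evaluation (`classification_metrics()`) reports the confusion counts and
accuracy, precision, recall and F1 computed exactly from them, with
zero-denominator ratios reported as flagged zeros.

### Desk-scale profile

`gaze_config("desk")` is the configuration the package's own experiments and
tests run: 32x32 network inputs, filters 4/8/16/32, LSTM hidden 16, batch
size 8, learning rate 1.5e-3, 8 epochs, and the LSTM consumes the original
rather than the replicated sequence (a switch, `lstm_input`, controls this;
replicated sequences are hundreds of steps long and add nothing at this
scale). These values were chosen by a small grid search for reliable
convergence of desk-scale training — the analogue, at this scale, of the
architecture search behind the reference configuration. The split is
stratified 80/10/10 at the record level by default; `split_mode =
"participant"` gives the participant-disjoint alternative. Record-level
splitting risks participant leakage in real corpora; both modes exist so the
question can be examined rather than assumed away.

## Training-data attribution

With per-epoch checkpoints $w^{(i)}$ and learning rates $\eta_i$, the
influence of training sample $x$ on test sample $x'$ is the replayed
first-order estimate

$$\mathrm{Influence}(x, x') = \sum_{i=1}^{k} \eta_i \,
  \nabla \ell(w^{(i)}, x) \cdot \nabla \ell(w^{(i)}, x'),$$

and self-influence is its diagonal,
$\mathrm{SelfInfluence}(x) = \sum_i \eta_i \lVert \nabla \ell(w^{(i)}, x)\rVert^2 \ge 0$.
High self-influence flags samples the optimiser repeatedly fought with —
outliers and mislabeled points; strongly positive (negative) pairwise scores
identify proponents (opponents) of a test prediction.

Gradients are taken in evaluation mode. Two parameter subsets are supported:
`"last_layer"` (the 4 fusion-layer coordinates; with a sigmoid/BCE head the
per-sample gradient is the closed form $(\hat y - y)\,[O_{img}, O_{fix},
O_{scn}, 1]$, so scoring a whole dataset is a batched forward pass per
checkpoint) and `"full"` (per-sample backpropagation over all parameters).
The vectorised production path is tested against a naive per-sample,
per-checkpoint loop to $10^{-10}$ relative error.

The two subsets have distinct roles. Self-influence *ranking* uses the
last-layer subset — the standard scalable practice. Category-level *pairwise*
aggregation (`aggregate_influence_by_category()`) defaults to full gradients:
in a 4-dimensional fusion gradient the bias coordinate dominates every inner
product (it contributes $(\hat y_{tr} - y_{tr})(\hat y_{te} - y_{te})$
regardless of content), washing out exactly the between-category structure
the aggregation is after, whereas the encoder gradients carry it.

## Dataset distillation experiment

`run_experiment()` mirrors the two-stage protocol: train on the full training
split (**FT**), rank training samples by self-influence from the FT
checkpoints, remove the highest-scoring fraction and retrain (**SIST**, at
usage tiers 77/67/50% by default, implemented as retained-fraction quantiles
of the ranking), and retrain on a uniformly random subset of *identical size*
(**RST**). The test split is fixed once per experiment and shared by every
variant and run; results are averaged over `r` independently seeded runs with
their standard deviation, and every mean carries its per-run values.
Self-influence is computed once per seed from that seed's FT checkpoints, not
re-estimated during removal.

## The synthetic generator

`build_synthetic_corpus()` emulates the structure of a small free-viewing
corpus so the whole pipeline runs without any external data: 30 stimuli x 2
groups x 5 participants = 300 records by default, every participant viewing
every image; 2-20 fixations per scanpath (real per-participant scanpaths are
this sparse); log-normal durations around 250 ms (a typical free-viewing
fixation duration). Stimuli are 128x128 grayscale textures in three
categories. "People" images carry a bright disk — a face-like social region,
centred with +-10% jitter, emulating the central placement of faces in
photographs — and the planted group effect: each TD fixation lands inside the
region with probability 0.7, each ASD-like fixation with probability 0.3;
non-people images have no group difference at all. Labels can be corrupted by
flipping exactly `round(rate * N)` uniformly chosen records, with the flip
set recorded in the ground-truth manifest. The generator writes PNG stimuli,
aggregated four-column scanpath files and a manifest CSV, and loads
everything back through the package's own readers, so tests exercise the real
file formats end to end. Given a spec and seed the corpus is byte-identical
across rebuilds.

The effect sizes (0.7 vs 0.3) are deliberately large so that an 8-epoch
desk-scale fit can succeed in minutes; the signal is planted *only* on people
images so category-level attribution has a recoverable ground truth. What the
generator does not emulate: saccade dynamics, oculomotor noise,
participant-level idiosyncrasy (scanpaths are i.i.d. given group and image),
or fitted distributions from real ASD data. Passing tests therefore
demonstrate that the pipeline recovers a planted social-attention effect of
this form — not that it reproduces real-data accuracy levels.

## Desk-scale experiment protocol and what it shows

The stochastic checks run five independent seeds; each seed regenerates the
~300-record corpus with 10% flipped labels *and* retrains, so both
generation and training variability are covered (a single frozen corpus
would instead measure luck of one flip set). Per seed: FT training (8
epochs), self-influence ranking, SIST/RST retraining at the 77% tier on the
shared test split, and full-gradient category aggregation over correctly
classified ASD test samples. Expected behaviour at these conditions, verified
by the test suite and the acceptance script:

- flipped training samples sit higher in the self-influence ranking than
  clean ones (their mean percentile is larger) in at least 4 of 5 seeds —
  driven by the people-image flips, the only ones distinguishable in
  principle;
- mean SIST test accuracy is at least mean RST accuracy — SIST retains
  essentially all clean people-image records (they rank low) while RST
  discards ~23% of them;
- "people" ranks first in the category aggregation in at least 4 of 5 seeds.

Only a third of the records (the people images) are separable at all, and
test splits hold 30 records, so single-run accuracies are noisy; the
comparisons above are about ordering, not absolute levels. A trivial
reference classifier thresholding the in-region fixation fraction reaches
~0.85-0.9 accuracy on people-image records, bounding overall attainable
accuracy near 0.65 at these conditions.

## Numerical and degenerate-input conventions

- BCE is computed from the logit via the stable softplus form.
- Ranking ties break by sample id; subset sizes use half-up rounding of
  `fraction * N`; removal order follows the descending ranking.
- Undefined precision/recall/F1 (zero denominators) are flagged zeros, never
  NaN.
- Out-of-bounds fixations are kept and flagged in the parse report; fixation
  coordinates are 0-based, origin top-left, y downward.
- Single-class training sets warn and proceed (the loss is still defined);
  empty datasets and empty checkpoint sets are errors.
- Stimuli whose size differs from the network input are resampled bilinearly.

## Limitations

The engine is plain R: fine for the desk profile (a full 8-epoch training on
300 records takes ~15 s on one core), but the reference configuration at
1024 LSTM units and 128x128 inputs is far slower and is provided for
fidelity, not throughput. Attribution replays only first-order information —
it approximates leave-one-out effects and inherits all of that
approximation's known failure modes. And the synthetic corpus is a
structural, not statistical, stand-in for real gaze recordings.
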