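---
title: "A two-stage video pipeline for gait-based spinal-deformity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage video pipeline for gait-based spinal-deformity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitscreen)
```

## The problem

Adult spinal deformity (ASD) is diagnosed from standing radiographs and
clinical signs, but a standing X-ray is a static picture: it cannot show
how the spine is compensated, or decompensates, while the patient walks.
`gaitscreen` implements a screening pipeline that works directly on an
ordinary side-view walking video and outputs, for every one-second clip,
a score for ASD versus other spinal disorders (dropped head syndrome,
lumbar canal stenosis, hip osteoarthritis — pooled as "non-ASD").

The pipeline has two stages:

1. **Detection stage.** Clinic videos contain cluttered, static
   backgrounds and often a second person — the accompanying doctor — who
   enters the frame *after* the patient. The detection stage finds every
   person per frame, picks the patient by the first-entrant prior,
   follows them with a nearest-center rule, and cuts a square,
   patient-centered crop per frame so the classifier sees only the
   patient.
2. **Classification stage.** A 3D residual convolutional network with
   bottleneck blocks scores 8 frames sampled uniformly from each
   one-second (30-frame) clip. Convolving over time as well as space
   lets the network use motion (trunk pitch dynamics, head drop, limb
   swing), not just posture.

Because the clinical recordings are private, the package ships a
synthetic scene generator that reproduces the *structure* of the data —
a single walking figure crossing a fixed camera, an optional trailing
second figure, static clutter, class-dependent gait kinematics — with
exact per-frame ground truth. Every stage of the pipeline is tested
against that ground truth.

## Detection stage

Boxes are half-open `[x1, x2) x [y1, y2)` in 0-based pixel coordinates;
this makes areas and crop arithmetic exact in tests.

**Body center.** The patient's center is the midpoint of the two hip
keypoints (COCO indices 11/12) when both are detected with confidence at
least 0.3 — a common keypoint-visibility cutoff — otherwise the
bounding-box center. When both estimates exist but disagree by more than
`tolerance_px` (default 10 px) the hip midpoint is kept and the frame is
flagged for audit rather than silently overridden; which source should
win in that situation is genuinely underdetermined, so the package
records rather than guesses.

**Tracking.** The patient is initialized from frame 0 (if the
first-entrant prior is violated and frame 0 holds several people, the
largest box wins — a deliberate, documented fallback; an empty frame 0
is an error, not a guess). Each subsequent frame chooses the detection
whose center is nearest to the previous chosen center: the same person
moves the shortest distance between adjacent frames. This is provably
identity-safe whenever the inter-person distance always exceeds twice
the patient's per-frame displacement, and the test suite checks exactly
that property on seeded two-person scenes. Frames without detections
carry the previous detection over, up to `max_gap = 5` consecutive
frames (brief detector dropouts should not abort a clip); beyond that
the track is declared lost.

**Cropping.** The square crop side equals the box height `y2 - y1` —
the patient's retained height is the base length — centered on the
tracked body center, so tall-and-narrow walking figures are never
distorted. Parts of the square outside the frame are filled by
edge-pixel replication (zero fill is available); replication avoids
feeding artificial black borders to the network. The square is then
resized isotropically to 512 x 512.

The production detector is a pluggable backend behind a small contract
(box + optional 17 keypoints + score). All tests run against the
ground-truth oracle backend; evaluating a learned person detector is
out of scope here, and this keeps the package installable without any
model download.

## Clip pipeline

Videos are cut into consecutive non-overlapping 30-frame (1 s) shots;
a trailing remainder is dropped, not padded — training uses only full
shots. From each shot, `T = 8` frames are sampled at indices
`floor(k * 30 / 8)`, k = 0..7, i.e. frames 0, 3, 7, 11, 15, 18, 22, 26:
"uniformly" is realized as the standard stride-based rule, which is
deterministic and exactly testable. Model inputs are channel-first
`(3, T, side, side)` arrays in [0, 1]. The default input side is 224:
the network's printed stage geometry (112 / 56 / 28 / 14 / 7) is the
geometry of a 224 input. Feeding the 512 crops unresized is supported
as a configuration for the no-preprocessing ablation, whose input is
produced by a short-side scale (shorter side to 512, center crop)
instead of the detection stage.

## The classifier

The network is a ResNet-50-style 3D CNN with bottleneck blocks:

| layer | output (T x H x W) | content |
|---|---|---|
| conv1 | T x 112 x 112 | 3x7x7, 64, stride 1x2x2 |
| pool1 | T x 56 x 56 | max 1x3x3, stride 1x2x2 |
| conv2_x | T x 56 x 56 | [1x1x1, 64; 3x3x3, 64; 1x1x1, 256] x 3 |
| conv3_x | T x 28 x 28 | [... 128/512 ...] x 4 |
| conv4_x | T x 14 x 14 | [... 256/1024 ...] x 6 |
| conv5_x | T x 7 x 7 | [... 512/2048 ...] x 3 |
| pool5 | 1 x 1 x 1 | global spatiotemporal average pool, fc, sigmoid |

Every temporal stride is 1, so the clip length T survives to the global
pool; the pooled feature has length 2048, and the head maps it to two
classes through independent sigmoids. The predicted label is the
argmax; the ASD sigmoid output is the positive-class score for ROC
analysis. Two independent sigmoids (rather than one logit, which the
head description leaves open) keep the two-column head literal while
leaving the ROC well defined.

Design points the architecture description leaves open, resolved here
as the standard residual-network conventions: spatial downsampling by
stride 2 on the 3x3x3 convolution of the first block of stages 2-4 with
1x1x1 projection shortcuts; batch normalization after every
convolution; activation after the residual addition. A
`width_multiplier` scales all channel widths (0.25 gives a 512-length
pooled feature) so that shape and training invariants can be exercised
on one CPU; the full-width network is still built and run forward in
the acceptance checks.

The network, its forward pass and its hand-derived backward pass are
implemented in the package itself (im2col/col2im and pooling kernels in
C++, GEMM through BLAS); the gradient implementation is verified
against numerical differentiation in the development history and
indirectly by every training test.

### Transfer mode

`adapt_head()` swaps the final layer (e.g. a 400-way action-recognition
head) for a freshly initialized 2-way head, leaving every other weight
bitwise unchanged; checkpoints are validated for architecture and
feature-width compatibility on load. Producing pretrained weights is a
non-goal: a checkpoint is an optional input.

## Training protocol

Defaults follow the clinical protocol: Adam at learning rate 1e-5,
batch size 8, binary cross-entropy over the two sigmoid outputs against
one-hot labels (the loss is unstated in the source protocol;
cross-entropy is the canonical partner of a sigmoid head). Early
stopping ends training when the best validation loss has not improved
for 5 consecutive epochs — the protocol's phrasing ("loss did not
increase") is read as "did not improve", since a non-increasing loss is
the desired outcome and the literal reading would stop training
immediately. The learning rate halves when validation accuracy has not
improved for 3 consecutive epochs; the plateau counter resets on
improvement and after each halving, and the early-stop and halving
counters run independently (their interplay is otherwise unspecified).
The checkpoint with the lowest validation loss is retained.
`max_epochs` (default 100) is a hard stop on top of early stopping.

## Evaluation

**Patient-level stratified group 5-fold CV.** Clips of one patient are
strongly correlated, so splitting is done at patient level: every
patient appears in exactly one validation fold. The assignment is a
greedy deterministic deal — per class, patients are shuffled with the
seed and dealt one at a time to the fold currently holding the fewest
patients of that class (ties: fewest patients overall, then lowest fold
index) — which guarantees fold sizes within one patient of each other
and per-fold class mixes within one patient of the cohort's. For 81
patients and k = 5 the validation folds have sizes 17, 16, 16, 16, 16.

**Metrics.** Accuracy is the fraction of agreeing labels; F1 is the
harmonic mean of precision and recall for a configurable positive
class; AUROC is the Mann-Whitney rank statistic (ties count one half),
which equals the trapezoidal ROC area. For a hard rater — a human who
outputs only labels — the ROC has a single operating point and the area
is (sensitivity + specificity) / 2; `rater_auroc()` computes that
closed form, and the tests verify it coincides exactly with the rank
statistic applied to 0/1 scores. All metrics are averaged across folds.

**Confusion-matrix convention.** The matrix is printed with rows =
truth (ASD first) and columns = prediction, and the four cells carry
the source study's positional names (its "FP" cell is truth-ASD
predicted-non-ASD). All arithmetic uses positions, not names.

**Rater reproduction.** Published rater results are row-normalized
ratios plus class sizes (54 ASD / 27 non-ASD patients). Accuracy, F1
and AUROC are all scale invariant in the class sizes, so they can be
reconstructed from ratios alone via `report_from_ratios()`. Two
subtleties: (a) the published rater F1 values are reproducible only
with non-ASD as the positive class, so that is the default for this
path (the model path defaults to ASD-positive); (b) published ratios
are rounded to 4 decimals, so the reconstructed pseudo-counts are
snapped to the nearest half-integer (within 0.01) — cells are counts of
rated clips, and with these class weights they are integers or
half-integers — which recovers the exact published values.

## Grad-CAM++ visualization

For one clip and one target class, the gradient of the class logit with
respect to a chosen convolutional stage (default: the last) is obtained
from the package's own backward pass, run through an evaluation-mode
forward so batch-norm buffers are untouched. Channel weights use the
Grad-CAM++ alpha weighting (positive second-order terms), computed per
temporal slice so each of the T maps reflects its own frame; the
rectified weighted activation sum is upsampled bilinearly to frame size
and min-max normalized per clip. Since temporal extent is preserved
through the network, per-slice bilinear upsampling coincides with
trilinear upsampling of the map volume. The T maps are fused by
pixelwise maximum (mean selectable); the maximum preserves per-frame
attention peaks and is frame-order invariant. `overlay()` alpha-blends
a blue-to-red colormap onto a frame.

## The synthetic scene generator

`generate_scene()` renders an articulated stick figure — elliptical
torso and head, two-segment limbs — walking left to right across a
static cluttered background, at 30 FPS and (by default) 640 x 360;
default size is chosen for test speed, and the clinical 1920 x 1080
geometry is one argument away. Generation is a pure function of
configuration + seed (bitwise reproducible), and the caller's RNG state
is untouched. Ground truth per frame: identity, bounding box and 17
COCO-ordered keypoints. Only the hips are kinematically meaningful
(they define the body center the tracker uses); the remaining keypoints
are placed schematically. The walker would be nonsense if it wrapped
around, so a figure reaching the frame edge truncates the scene with a
flag.

A `MotionSignature` controls trunk pitch (forward lean, degrees), head
drop relative to the trunk, stride (px/frame), vertical sway and limb
phase. Cohorts draw per-patient signatures from two class families —
ASD: pronounced trunk pitch (~22 deg) and head drop, shorter stride,
more sway; non-ASD: upright (~4 deg) — jittered per patient; the
published description motivates class-dependent gait differences but
does not quantify them, so these values are the package's choice of a
plausibly separable regime and are *not* claimed to match clinical
effect sizes. A `separation` dial interpolates the two family means
toward their midpoint; at 0 both classes draw from one distribution,
giving an exact no-signal control. The optional second figure enters at
a configurable frame (always after frame 0) and trails the patient by
at least `distractor_gap_px`, making the "doctor follows patient" prior
true by construction and violable on purpose in negative tests.

Cohorts store scene *configurations* and render on demand
(`cohort_scenes()`); a dozen patients of materialized RGB frames would
be about 0.7 GB, and the experiment driver processes one scene at a
time, keeping only the small model tensors.

What passing tests on this generator do show: the tracker, crop
geometry, clip pipeline, training loop, CV machinery and metrics are
correct, and the classifier can extract a genuine kinematic class
signal from rendered motion while finding nothing when no signal
exists. What they do not show: performance on real patients — the
generator has no photorealism, no camera noise, no gait variability
beyond its parameter jitter, and its class separation is synthetic.

## Numerical and scale choices

- End-to-end experiments in the test suite run a 12-patient cohort
  (6/6), 3 one-second clips per patient, the tiny architecture
  (blocks 1,1,1,1 at width 0.25), model input side 32, Adam at 1e-3,
  at most 20 epochs per fold — sizes chosen so a full 5-fold experiment
  runs in minutes on one CPU while leaving the pipeline end-to-end
  real. The learning rate is raised from the clinical 1e-5 because the
  tiny network on 32 px inputs would otherwise need hundreds of epochs.
- The no-signal control is reported as the mean fold AUROC averaged
  over three cohort seeds: a 12-patient null has few effective units
  per fold (scores within a patient correlate), and a single draw of
  its null distribution is too coarse to test a band around 0.5.
- Batch norm uses eps 1e-5 and momentum 0.1 with unbiased running
  variance; BCE clamps probabilities at 1e-12; Adam uses the standard
  moment defaults (the protocol names only the learning rate).
- Ties: equidistant tracking candidates take the lowest detection
  index; equal-area frame-0 boxes take the lowest x1; AUROC ties count
  one half.
- One master seed fans out deterministically (fixed affine map into
  32-bit range) to cohort generation, fold split, per-fold weight
  initialization and batch order; no seed policy is published, so this
  is the package's own reproducibility contract.

## Known limitations

- The detection-stage contract is exercised only with the oracle
  backend; plugging in a learned detector changes failure modes
  (missed detections, identity noise) that only `max_gap` carry-over
  addresses here.
- The renderer is 2D and side-view only; out-of-plane motion,
  occlusion and camera motion are not modeled.
- Training the full-width network is out of reach on one CPU; only its
  construction, forward contract and tiny-width training behavior are
  verified.
- The published headline clip-level results (accuracy 0.7553, F1
  0.7063, AUROC 0.7864) require the private 81-patient clinical videos
  and accelerator-scale training; they are out of scope for this
  package's checks, which reproduce instead every desk-scale published
  number (rater metrics, architecture dimensions, CV aggregation).
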