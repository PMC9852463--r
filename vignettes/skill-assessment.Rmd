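---
title: "Assessing surgical skill from tool-motion sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing surgical skill from tool-motion sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-stakes laparoscopic certification tasks such as pattern cutting are
scored summatively (a continuous performance score with a pass/fail
cut-off) by protocols that are slow, proprietary and uninformative about
*why* a trainee failed. Task video, however, is recorded routinely. Once an
upstream detector has reduced each video to a per-frame trace of the two
instrument centroids — grasper and scissors `x`/`y` in pixel coordinates,
a `T x 4` matrix per trial — skill assessment becomes a variable-length
multivariate time-series problem. `skillseq` implements a complete
pipeline on such traces:

1. **Preprocessing** — detector drop-out imputation, downsampling,
   normalization;
2. **Embedding** — a denoising autoencoder that extracts salient
   per-timestep features;
3. **Assessment** — an attention-infused residual 1D CNN with global
   average pooling, with a softmax head for pass/fail classification and a
   linear head for score regression;
4. **Evaluation** — stratified k-fold, leave-one-supertrial-out (LOSO) and
   leave-one-user-out (LOUO) cross-validation with pooled-prediction
   metrics;
5. **Trustworthiness** — question–answer trust, trust densities, the trust
   spectrum and the NetTrustScore;
6. **Formative feedback** — class activation maps (CAMs) over time, plus a
   statistical validation that masks inputs with their CAMs and retrains.

The tool detector itself (an instance-segmentation network in the original
setting) is out of scope: the package's boundary is the coordinate table it
produces.

## Preprocessing

A frame the detector missed is reconstructed from its neighbours. For an
isolated gap the imputed frame is the average of the preceding and
succeeding frames; we extend this to runs of consecutive missing frames by
linear interpolation between the flanking observed frames — the unique
order-preserving extension whose two-point special case is the average —
and boundary gaps copy the nearest observed frame. Gap filling is
idempotent and never alters observed frames.

Sequences are then downsampled by *stride sampling* (every `fps/target`-th
frame, starting at frame 0; default target 1 FPS). Stride sampling rather
than block averaging preserves raw detections, including the
frame-to-frame jitter that carries skill information.

Coordinates are min–max normalized to `[0, 1]` per feature and scores are
z-normalized. Statistics are fitted on the training split of each
cross-validation fold only (`normalization.scope = "fold_train"`), so no
information from held-out trials leaks into preprocessing; a `"global"`
variant is exposed for comparison with protocols that normalize once.
A degenerate feature (`max == min`) maps to 0.

## The denoising autoencoder

The embedding network corrupts each normalized sequence with additive
zero-mean Gaussian noise of standard deviation `noise_alpha = 0.001`
(resampled every epoch) and reconstructs the clean sequence under a
mean-squared-error loss. Encoder and decoder are built from the same
attention-residual block as the classifier (below), without dilation; a
1x1 convolution maps the block's `filters` channels to the embedded width
`d_e` (default 8). The encoder output — one `T x d_e` matrix per trial —
is what the heads consume. Inference injects no noise and is
deterministic.

MSE as reconstruction loss, Adam with learning rate 1e-3, and
noise-per-epoch resampling are package choices (the original architecture's
full hyperparameter set is not public); all are exposed in `dae_config()`.
Validation loss is evaluated noise-free at each epoch end — a
deterministic, monotone proxy for the denoising objective — and training
stops when it has not improved for `patience` epochs (default 4), restoring
the best parameters.

## The attention-residual head

Each head is a single residual block: convolution → ReLU → scSE →
convolution, an identity shortcut (1x1 projection when channel counts
differ), ReLU after the addition, and a second scSE on the sum. scSE
(concurrent spatial and channel squeeze-and-excitation) recalibrates
feature maps through two sigmoid gates — a channel gate computed from the
time-averaged features through a bottleneck (reduction ratio 2), and a
spatial gate computed per timestep by a 1x1 projection — fused by
element-wise maximum, the common scSE convention. Classifier convolutions
are dilated (default 2); the autoencoder's are not.

Global average pooling collapses time, so one network accepts trials of
any duration; a fully connected layer with softmax gives class
probabilities (class-weighted cross-entropy loss, weights
`N / (n_classes * N_c)`), or a single unconstrained node gives the
z-normalized score (MSE loss). The batch size is one throughout because
trial lengths differ. Predicted class is the argmax, ties breaking to the
lower class index; confidence is the probability of the predicted class.

Because no deep-learning framework is assumed, the package carries its own
small sequence-network engine (`R/nn-engine.R`): same-padded dilated 1D
convolutions, scSE, residual blocks, GAP heads, Adam, and early stopping,
with hand-derived backpropagation. The test suite checks every layer's
gradient against central finite differences; all training is exactly
reproducible from a seed. The encoder is frozen while heads train by
default (`fine_tune = TRUE` propagates gradients into it).

## Cross-validation and metrics

`make_folds()` builds stratified k-fold plans (class ratio preserved
within one sample per fold), LOSO plans (fold *i* tests repetition *i* of
every subject), and LOUO plans (fold *s* tests every trial of subject
*s*); a stratified 10% validation split is carved from each fold's
training set for early stopping — a package decision, since the original
protocol does not state its split. `run_cv()` repeats training over
sessions with fresh derived seeds and pools test predictions across folds
(each trial is tested exactly once per session). Accuracy, sensitivity and
specificity come from the pooled confusion matrix, AUC from the pooled
positive-class probabilities ("pass" is positive by default), and score
performance is Spearman's rho with a two-sided p-value (exact permutation
below 10 pairs, t-approximation otherwise). Session aggregates are
reported as mean ± sd.

## Trust quantification

For a prediction with confidence `C`, the question–answer trust is
`C^alpha` when correct and `1 - C^beta` when incorrect (defaults
`alpha = beta = 1`): a model is trustworthy when it is confident
exactly where it is right. The trust spectrum `T_M(z)` is the mean trust
over records of true class `z` — the discrete estimator of the trust
integral, the only one available from finite prediction records — and the
NetTrustScore is the prevalence-weighted average of the spectrum.
Conditional summaries restrict the mean to correct/incorrect subsets.
Trust *densities* are Gaussian KDEs (Scott's bandwidth by default) drawn
on a grid covering at least `[-0.2, 1.2]` and extended three bandwidths
past the data so each curve integrates to one on its own grid; they are
diagnostics and never feed back into the scalar scores.

## Formative feedback: CAMs and their validation

With a GAP + linear head, the evidence the classifier sees for class `c`
decomposes over time: the class activation map is
`M_c(i) = sum_k w_k^c f_k(i)`, the pre-softmax class weights against the
activations of the convolution stack preceding pooling. Raw maps are
signed; for masking they are rectified and min–max normalized per trial
(masking with signed values would invert coordinates meaninglessly; a
degenerate rectified map normalizes to zeros). `project_cam()` linearly
interpolates a map onto another temporal length — an identity here, since
the stride-1 same-padded stack preserves length, but a guard for strided
variants and for overlay on the 30 FPS trajectory.

The validation procedure multiplies every trial's coordinates by its own
normalized CAM (the *true*-class map by default; the predicted-class
variant is exposed), retrains the whole pipeline from scratch on the
masked inputs with the identical fold plan and seeds, and compares
per-fold accuracy before vs after with a one-sided Wilcoxon signed-rank
test at level 0.05 (alternative: masking improves accuracy). Zero
differences are dropped; the null distribution is computed exactly by
convolution over tie-averaged ranks (ties are the norm for per-fold
accuracies), and an all-tied comparison reports p = 1 with a flag. The
phrase "sign test" is sometimes used for this procedure; the plain sign
test is available via `method = "sign"`.

## The synthetic cohort

Real certification datasets are proprietary and benchmark kinematics
require an external download, so the package ships a seeded generator
whose defaults define its study conditions: 12 subjects x 25 trials of
30 FPS bimanual traces in a 640 x 480 frame. The scissors travel a
smoothed circular arc (radius 100 px) whose speed is set by trial
duration; the grasper holds traction near a gauze corner with a
repositioning jump at each struggle event. Skill (per subject, Beta
distributed; per trial, jittered by sd 0.05) controls duration (60–120 s
in the expert regime vs 180–300 s in the novice regime), path jitter
(3 px vs 15 px), and the Poisson rate of struggle events (0.5 vs 4 per
trial). A logistic switch in skill (centre 0.447, width 0.06) moves
between the two parameter regimes: clearly skilled
and clearly struggling subjects land squarely inside the respective
ranges, the few borderline subjects produce genuinely borderline trials,
and the mapping stays strictly monotone in skill, which both the
monotonicity checks and the score regression rely on. Struggle windows
(5–15 s) add high-frequency jitter and local back-tracking and are
recorded as ground truth for saliency checks. Frames drop out i.i.d. with
probability 0.01. The surrogate score is transparent and linear —
`200 - 0.5 * duration_s - 10 * events + N(0, 5)`, pass at >= 70 — it is
*not* the proprietary certification formula, only a stand-in with the
same qualitative structure.

Two calibrations were fixed at design time. The transition centre (0.447)
is set so the skill at which a trial's expected score crosses the cut-off
coincides with the median of the default Beta(0.6, 0.8) cohort, making
the expected class ratio balanced; the transition itself is a task
property, so skewing the cohort's Beta shapes reproduces imbalanced
regimes. And subject skills are drawn by stratified
inversion of the Beta (one uniform draw per equal-probability stratum),
mimicking a cohort recruited to span the skill range and keeping the
realised ratio stable across seeds — with 12 subjects, fully independent
draws would make the ratio lurch seed to seed. Labels retain intrinsic
noise: a long, high-jitter trial with zero or one struggle events can
still score above the cut-off, so a motion-based classifier faces a small
irreducible error floor, as real summative scores also embed information
a motion trace cannot carry.

What the generator does *not* emulate: correlated detector failures (drop
-outs are i.i.d.), camera motion, tool occlusions and identity swaps,
multi-segment task structure, or any real scoring rubric. Passing the
shipped end-to-end checks therefore demonstrates that the pipeline
recovers skill structure *of this kind* from coordinate traces; it is not
evidence about any particular clinical dataset.

## Numerical choices and degenerate inputs

* Convolution kernels are odd-length so same padding is symmetric; weights
  use Glorot-uniform initialisation from the fit's seed.
* Early stopping compares losses strictly; the first epoch achieving the
  minimum is kept, and its parameters are restored at the end.
* Head training is multi-start: two independent deterministically seeded
  runs, keeping the one with the lower best validation loss — batch-size-one
  optimisation on ~250-trial folds is noisy enough that single runs
  occasionally land in poor basins. If the kept run still fails to beat the
  trivial constant predictor on validation loss (a collapse into the class
  prior), up to two further restarts are tried.
* Softmax is computed with max-subtraction; cross-entropy clamps
  probabilities at 1e-12.
* `which.max` tie-breaking makes equal-probability predictions go to the
  first class in `class_names`.
* Constant features normalize to 0; a constant trust sample falls back to
  a fixed 0.05 KDE bandwidth; a degenerate rectified CAM normalizes to
  zeros; an all-missing trial, an empty training set, a single-class AUC
  pool and a one-subject LOUO plan are errors, not silent results.
* Seeds: every stochastic component (generator, fold shuffling, parameter
  initialisation, epoch shuffling, noise) derives its own 32-bit seed from
  the caller's master seed, so any run is bit-reproducible.

## Problem sizes

The shipped end-to-end checks run the default cohort (N = 300), one
session of stratified tenfold cross-validation, epoch caps of 20 (DAE,
patience 4) and 50 (heads, patience 20), and the masked-retraining
analysis on the same folds — sizes chosen so the whole suite completes on
a single CPU in well under an hour while leaving the learning problem
non-trivial. Unit tests use a shrunken generator (durations 15–75 s, score
weights rescaled so the cut-off stays attainable).

## Known limitations

* The engine is plain R: adequate at these problem sizes, but not a
  substitute for a GPU framework at video-dataset scale.
* Exact layer widths of the original architecture are not public; the
  defaults here are declared, not reconstructed, and headline numbers from
  proprietary datasets are not reproduction targets.
* LOSO assumes equal repetition counts per subject (it tests the i-th
  repetition of each); ragged designs fall back to testing whatever
  repetitions exist at each index.
* The masking validation retrains on masked inputs with the same
  hyperparameters; it validates saliency placement, not calibration of
  the maps' magnitudes. Moreover, because the mean of a trial's normalized
  CAM is itself class-dependent (fail-class evidence is localized, so fail
  maps carry more mass than the diffuse pass maps), part of the
  after-masking improvement reflects label information leaking through
  mask amplitude — a property inherited from the procedure itself. The
  per-fold outcome is sensitive to any single fold model whose amplitude
  convention inverts: its masked test trials can anti-generalise, and the
  signed-rank test weights that one large-magnitude regression heavily
  (the plain sign test, `test = "sign"`, is robust to it).
* Pooled tenfold accuracy on the default synthetic cohort fluctuates by
  one to two trials (±0.5 percentage points) across legitimate
  training-configuration and seed micro-variations; single-session
  accuracy figures on this cohort should be read with that granularity
  in mind.
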