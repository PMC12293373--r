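---
title: "Few-shot classification of 3D volumes: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot classification of 3D volumes: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fewshot3d)
```

## The procedure

fewshot3d classifies 3D grayscale volumes in the 2-way k-shot regime. The
pipeline has three stages.

**1. Embedding.** A 3D convolutional encoder maps a preprocessed volume to
a D-dimensional vector. The default `tiny3d` architecture is three
stride-2 3×3×3 convolutions (8 → 16 → D channels) with leaky rectifier
activations, ending in global adaptive average pooling; there is no
classification layer, so the embedding length is D for any input extent.
The `resnet_style` variant adds an identity-skip residual block per stage
for scale-up experiments. Both are implemented with hand-derived
backpropagation (the convolution kernels in C++, everything else in R),
and every gradient path is checked against central finite differences in
the test suite.

**2. Metric learning with the GE2E loss.** A training batch stacks M
samples of each of N labels. With per-label centroids
$C_k = \frac{1}{M}\sum_j f_{kj}$ and cosine similarities
$S_{ji,k} = \cos(f_{ij}, C_k)$, each embedding is penalized by

$$L(e_{ij}) = -S_{ji,i} + \log \sum_{k=1}^{N} e^{S_{ji,k}},$$

summed over the batch. The loss is zero-floored only in the single-label
case (where it collapses analytically to 0); with N ≥ 2 it pulls
same-label embeddings toward their centroid and pushes labels apart. We
implement this formula literally by default. Two refinements from the
loss's speaker-verification origins are available but off by default,
because the printed form above is the definition we target: excluding
$f_{ij}$ from its own centroid (`self_exclusion`), and a learnable affine
$w\cos + b$ on the similarity (`scale`, `bias`). Whether the batch loss
should be summed or averaged is genuinely open; we default to the sum and
expose `reduction = "mean"` — the two differ only by a constant factor
N·M, absorbed by the learning rate.

**3. Prototype classification.** For an episode, each class prototype is
the unweighted mean of its k support embeddings (raw, not L2-normalized —
normalize-before-mean is a flag). A query gets the label of the nearest
prototype in Euclidean distance. The continuous ROC score is the margin
$d_{neg} - d_{pos}$; for two classes any monotone alternative (e.g.
softmax over negative distances) yields the identical AUC, so the margin
is the minimal assumption. Exact distance ties are resolved to label 0,
the conservative "intact" call.

## Episodes and leakage control

An episode draws exactly k support exams per class from the evaluation
pool; the query set is every remaining exam, excluding — by default — all
exams of any patient who contributed a support sample. Train/test
separation is likewise by patient, never by exam, so repeated scans of
one subject can never straddle a partition. The episode sampler is
deterministic given its seed, and sweeps use seed `base + e` for episode
e, making every reported mean reproducible bit for bit.

Defaults for the evaluation harness: k ∈ {2, 20, 40} and 20 episodes per
k. The query set defaults to "all remaining" eligible exams, matching
evaluation on a fixed held-out split; a fixed `n_query` is available when
matched statistical power across k matters more than using every sample.

## The synthetic phantom generator

Real volumetric datasets cannot ship with a package, so the generator
produces the study conditions under which everything here is validated:
240 patients, one 16×32×32 volume each, equal class balance. Every volume
is i.i.d. Gaussian background noise (SD 1); positive volumes add
`lesion_contrast` × SD inside a lesion region whose center is jittered by
up to 10% of each dimension. Two geometries emulate a pair of related but
distinct binary tasks, so pre-train-on-one / few-shot-on-the-other
transfer is testable: `ellipsoid_A`, a focal sphere (radius 4 voxels by
default), and `band_B`, a through-plane cylinder of the same in-plane
radius. The default contrast of 3 gives a task that a well-trained
encoder separates essentially perfectly while a random-initialization
encoder does not — the regime in which sampler bugs, loss bugs or leakage
are most visible.

What the phantom deliberately does **not** emulate: anatomy, partial
volume effects, scanner intensity non-uniformity, inter-reader label
noise, class imbalance, or lesions whose appearance overlaps between
classes. Passing the package's property tests therefore demonstrates
correctness of the machinery — sampling, loss, gradients, distances,
metrics — not clinical-grade performance on real MRI, where reported
AUCs for comparable tasks are far from 1.

## Parameters that matter

| Parameter | Default | Rationale |
|---|---|---|
| `volume_shape`, `target_shape` | 16×32×32 voxels | smallest extent at which a 3-stage stride-2 encoder retains spatial structure; one volume ≈ 16k voxels keeps a CPU training step at ~35 ms |
| normalization | per-volume z-score | removes the global-brightness shortcut (a lesion adds total intensity); constant volumes map to zeros rather than dividing by zero |
| depth policy | symmetric center crop/pad | deterministic and exactly invertible bookkeeping; linear resampling offered for strongly varying slice counts |
| `embedding_dim` | 32 | enough capacity to separate two classes with margin; doubling it roughly doubles runtime for no measurable gain at these sizes |
| GE2E batch | N = 2, M = 4 | batch size 8 for the 2-way task |
| optimizer | Adam, lr 3e-3, 300 steps | the loss reaches its analytic floor (~1.03 for a separable batch of 8) well within 300 steps at these problem sizes; training is ~11 s on one core |
| episodes | 20 per k, k ∈ {2, 20, 40} | standard-error of a mean AUC over 20 episodes is well under the effects being compared |

## Numerical choices

- **Log-sum-exp** in the loss is max-shifted; no similarity magnitude can
  overflow.
- **Leaky activations** (negative slope 0.1): with hard rectifiers and an
  adaptive optimizer, a stage can die wholesale, collapsing embeddings to
  the exact zero vector where cosine similarity is undefined; the leaky
  slope keeps every unit trainable. Zero-norm embeddings are still
  detected and raise a typed error rather than silent NaN.
- **Gradients through centroids** are included analytically (a centroid
  is a mean of embeddings, so each similarity has two dependence paths);
  the self-exclusion variant's per-query centroid gradients are likewise
  exact.
- **AUC** is computed from midranks — exactly the pairwise Mann–Whitney
  count with half-credit ties — so `roc_auc(-s) = 1 - roc_auc(s)` holds
  to machine precision and any strictly monotone rescoring is a no-op.
- **Determinism**: all randomness flows through seeded, state-restoring
  generators; the C++ convolution kernels are single-threaded, so
  evaluation is bit-reproducible and training curves reproduce exactly on
  one platform.
- **Checkpoints** are JSON with 17 significant digits, which round-trips
  IEEE doubles exactly; loading refuses unknown format versions or a
  mismatched architecture.
- Degenerate inputs are rejected with typed conditions (`fs3d_*_error`)
  at the earliest possible stage: label outside {0, 1} names the manifest
  row, an under-filled support class names the class and its count,
  single-class AUC raises an undefined-metric error instead of NaN.

## Design decisions that were genuinely open

- **Which plane feeds the model**: multi-series exams are consumed one
  series per run; plane fusion is out of scope, and the axis convention
  (depth = slice) is fixed package-wide.
- **Preprocessing**: no published preprocessing accompanies the protocol
  this package implements, so shape conformance + per-volume z-score are
  explicit package decisions, documented rather than inherited.
- **Embedding dimensionality** after adaptive pooling is exposed as
  configuration (default 32) since nothing pins it down externally.
- **Pre-training transfer protocol**: supervised cross-entropy training
  of encoder + temporary linear head on the sibling task, head discarded
  afterwards. The same schedule trains the supervised baseline on exactly
  the 2k support samples of an episode, evaluated on that episode's query
  pool, for a like-for-like comparison with the few-shot arm.

## Known limitations

- Desk-scale encoders only: the architectures train in seconds on a CPU
  but are far smaller than the deep residual backbones used for real
  clinical MRI; the package's claims are about the correctness of the
  method, not about matching published clinical AUCs.
- 2-way episodes only; N-way > 2 would need a different score definition
  for ROC analysis.
- The phantom's separability means ceiling effects: comparisons between
  arms (e.g. GE2E vs cross-entropy embeddings) can saturate at AUC 1 and
  differences then show only under harder conditions (lower contrast,
  fewer steps).
- No confidence intervals on per-episode metrics; per-episode values are
  exported so external tools can run whatever inference is appropriate.
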