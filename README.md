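# fewshot3d

Few-shot classification of 3D medical image volumes with prototype
networks and the generalized end-to-end (GE2E) embedding loss.

## The problem

Binary classifiers for volumetric scans (e.g. detecting an ACL or meniscus
tear in a knee MRI series) normally need hundreds of labeled exams per
condition. Few-shot learning sidesteps that: an embedding encoder, trained
once on a *related* task where labels are plentiful, maps each volume to a
feature vector; a new condition is then classified from only *k* labeled
support exams per class, with no further gradient training. This package
implements the full pipeline for the 2-way (binary) k-shot setting —
volume I/O and preprocessing, a trainable 3D convolutional encoder, GE2E
metric learning, patient-disjoint episodic evaluation, and a
SEN/SPE/ACC/ROC-AUC harness — plus a synthetic lesion-phantom generator so
the whole framework is testable offline with known ground truth.

It is aimed at methods researchers who want a compact, fully inspectable
reference implementation (every gradient is hand-derived and
finite-difference checked) rather than a GPU training stack.

## The model

**Embedding.** An encoder `f(·)` maps a `(depth, height, width)` volume to
a D-dimensional vector. The encoders here are small 3D CNNs ending in
global adaptive average pooling — no classification layer — so the output
length is D for any input extent.

**GE2E loss.** A training batch holds M samples of each of N labels, with
embeddings f_ij (sample j of label i) and label centroids
C_k = (1/M) Σ_j f_kj. With cosine similarity S_ji,k = cos(f_ij, C_k), each
embedding contributes

    L(e_ij) = −S_ji,i + log Σ_{k=1..N} exp(S_ji,k)

which pulls embeddings toward their own-label centroid and pushes them
from the others. The loss is implemented literally in this form by
default; the original refinements (self-exclusion of f_ij from its own
centroid, learnable scale/bias on the cosine) are options.

**Prototype classification.** For a k-shot episode, each class prototype
is the mean of its k support embeddings; a query is assigned the label
whose prototype is nearest in Euclidean distance (ties → label 0, the
"intact" call). The continuous score for ROC analysis is the distance
margin `d_neg − d_pos`.

**Metrics.** Sensitivity, specificity, accuracy and ROC-AUC; AUC is the
exact Mann–Whitney statistic (ties counted half), not a trapezoidal
approximation.

Axis convention throughout: `(depth, height, width)` with depth = slice
axis, matching per-exam `.npy` stacks; NIfTI volumes are read as stored.

## Worked example

```r
library(fewshot3d)

# 1. Simulate an MRNet-like two-class dataset: 240 patients, one 16x32x32
#    volume each; positives carry a focal lesion of contrast 3 x noise SD.
cfg <- synthetic_config(n_patients = 240, lesion_contrast = 3, seed = 1)
pool <- simulate_dataset(cfg)
pool
#> <sample_set 'synthetic_ellipsoid_A': 240 samples (120 neg / 120 pos), 240 patients>

# 2. Z-score every volume and split by patient (no leakage).
sp <- preprocess_spec(target_shape = c(16, 32, 32))
pool$samples <- lapply(pool$samples, function(x) {
  x$volume <- preprocess(x$volume, sp); x
})
splits <- split_by_patient(pool, c(0.5, 0.5), seed = 2)

# 3. Train the tiny3d encoder with the GE2E loss (N = 2 labels x M = 4
#    samples per step, batch size 8).
enc <- build_encoder(encoder_spec(), seed = 1)
enc <- train_ge2e(enc, splits$train, schedule = list(steps = 300, seed = 5))
tail(attr(enc, "history"), 3)
#>     step     loss
#> 298  298 1.031750
#> 299  299 1.028438
#> 300  300 1.031221

# 4. Episodic 2-way 20-shot evaluation on held-out patients.
res <- evaluate_many(enc, splits$test, episode_config(k_shot = 20),
                     n_episodes = 20, base_seed = 7)
res$summary
#>   metric      mean          sd
#> 1    acc 0.9993750 0.002795085
#> 2    sen 0.9988372 0.005200158
#> 3    spe 1.0000000 0.000000000
#> 4    auc 1.0000000 0.000000000

# 5. One episode in detail.
ep <- build_episode(splits$test, episode_config(k_shot = 20, seed = 7))
head(evaluate_episode(enc, ep), 3)
#>   exam_id true pred     score     d_neg    d_pos
#> 1  E00002    0    0 -3.914419 0.2537155 4.168135
#> 2  E00007    1    1  3.999313 5.5037584 1.504446
#> 3  E00016    1    1  3.531091 4.0321510 0.501060
```

The training loss settles near its analytic floor for a well-separated
2-label batch (≈ 1.03 for batch size 8), and the held-out episodes are
classified essentially perfectly: the synthetic task at contrast 3 is
clearly separable, which is exactly what makes it a useful correctness
probe — failures of the sampler, the loss, or the distance rule show up
immediately as AUC well below 1.

A thin CLI over the same workflows lives at `inst/cli/fewshot3d.R`
(commands `simulate`, `pretrain`, `train-ge2e`, `evaluate`, `baseline`);
YAML-configurable workflow functions are `run_simulate()`,
`run_pretrain()`, `run_train_ge2e()`, `run_evaluate()`, `run_baseline()`.

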