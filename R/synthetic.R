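#' Configuration for the synthetic lesion-phantom generator
#'
#' Generates MRNet-like two-class volume datasets with known ground truth:
#' every volume is Gaussian background noise, and positive ("injured")
#' volumes additionally carry a brighter lesion-like region. Two lesion
#' geometries stand in for two related-but-distinct binary tasks, so that
#' pre-train-on-one / few-shot-on-the-other transfer experiments can run
#' offline:
#' * `ellipsoid_A` — a spherical focal lesion of the given radius;
#' * `band_B` — a through-plane band (a cylinder along the slice axis) of
#'   the given in-plane radius.
#'
#' The lesion center is the volume center plus a per-exam jitter of at most
#' 10% of each dimension, drawn from the seeded generator. All exams of one
#' patient share a patient id and class label.
#'
#' @param n_patients Number of patients.
#' @param exams_per_patient Exams per patient (all share the patient label).
#' @param volume_shape Integer triple `(depth, height, width)`.
#' @param lesion_contrast Added intensity inside the lesion, in units of the
#'   noise SD. 0 makes the classes indistinguishable.
#' @param lesion_radius_voxels Lesion radius in voxels.
#' @param lesion_kind `"ellipsoid_A"` or `"band_B"`.
#' @param noise_sd Background noise standard deviation (> 0).
#' @param class_balance Fraction of positive patients, in (0, 1).
#' @param seed Integer seed; identical configs give bit-identical datasets.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients, exams_per_patient = 1L,
                             volume_shape = c(16L, 32L, 32L),
                             lesion_contrast = 3, lesion_radius_voxels = 4,
                             lesion_kind = c("ellipsoid_A", "band_B"),
                             noise_sd = 1, class_balance = 0.5, seed = 1L) {
  lesion_kind <- match.arg(lesion_kind)
  if (!is_count(n_patients) || !is_count(exams_per_patient)) {
    config_error("n_patients and exams_per_patient must be positive integers")
  }
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 1L)) {
    config_error("volume_shape must be three integers >= 1")
  }
  if (lesion_contrast < 0) config_error("lesion_contrast must be >= 0")
  if (lesion_radius_voxels <= 0) config_error("lesion_radius_voxels must be > 0")
  if (noise_sd <= 0) config_error("noise_sd must be > 0")
  if (class_balance <= 0 || class_balance >= 1) {
    config_error("class_balance must be in (0, 1)")
  }
  # lesion plus maximal jitter must stay inside the volume
  axes <- if (lesion_kind == "ellipsoid_A") 1:3 else 2:3
  if (any(lesion_radius_voxels + 0.1 * volume_shape[axes] >
          volume_shape[axes] / 2)) {
    config_error("lesion (radius + 10% jitter) does not fit inside volume_shape")
  }
  structure(list(n_patients = as.integer(n_patients),
                 exams_per_patient = as.integer(exams_per_patient),
                 volume_shape = volume_shape,
                 lesion_contrast = lesion_contrast,
                 lesion_radius_voxels = lesion_radius_voxels,
                 lesion_kind = lesion_kind, noise_sd = noise_sd,
                 class_balance = class_balance, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Ground-truth lesion mask
#'
#' @param shape Volume shape `(d, h, w)`.
#' @param center Lesion center (fractional voxel coordinates).
#' @param radius Radius in voxels.
#' @param kind `"ellipsoid_A"` (sphere) or `"band_B"` (through-plane
#'   cylinder).
#' @return Logical array of `shape`, `TRUE` inside the lesion.
#' @export
lesion_mask <- function(shape, center, radius,
                        kind = c("ellipsoid_A", "band_B")) {
  kind <- match.arg(kind)
  d <- slice.index(array(0, shape), 1L) - center[1]
  h <- slice.index(array(0, shape), 2L) - center[2]
  w <- slice.index(array(0, shape), 3L) - center[3]
  if (kind == "ellipsoid_A") {
    d^2 + h^2 + w^2 <= radius^2
  } else {
    h^2 + w^2 <= radius^2
  }
}

#' Simulate a labeled synthetic dataset
#'
#' @param cfg A [synthetic_config()].
#' @return A `sample_set` of `n_patients * exams_per_patient` samples; each
#'   sample's `meta` records the drawn `lesion_center` (for positives, the
#'   actual lesion position; negatives record the center that would have
#'   been used, keeping the random stream label-independent).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  shp <- cfg$volume_shape
  with_seed(cfg$seed, {
    n_pos <- round(cfg$class_balance * cfg$n_patients)
    if (cfg$n_patients >= 2L) n_pos <- min(max(n_pos, 1L), cfg$n_patients - 1L)
    pat_label <- sample(c(rep(1L, n_pos), rep(0L, cfg$n_patients - n_pos)))
    samples <- vector("list", cfg$n_patients * cfg$exams_per_patient)
    i <- 0L
    for (p in seq_len(cfg$n_patients)) {
      pid <- sprintf("P%04d", p)
      for (e in seq_len(cfg$exams_per_patient)) {
        i <- i + 1L
        center <- (shp + 1) / 2 + stats::runif(3, -0.1, 0.1) * shp
        vox <- array(stats::rnorm(prod(shp), 0, cfg$noise_sd), dim = shp)
        if (pat_label[p] == 1L && cfg$lesion_contrast > 0) {
          m <- lesion_mask(shp, center, cfg$lesion_radius_voxels,
                           cfg$lesion_kind)
          vox[m] <- vox[m] + cfg$lesion_contrast * cfg$noise_sd
        }
        v <- volume(vox, exam_id = sprintf("E%05d", i), patient_id = pid,
                    series_label = cfg$lesion_kind)
        samples[[i]] <- labeled_sample(v, label = pat_label[p],
                                       meta = list(lesion_center = center))
      }
    }
    sample_set(samples, name = sprintf("synthetic_%s", cfg$lesion_kind))
  })
}

#' Oracle lesion statistic for a synthetic sample
#'
#' Mean intensity inside the sample's ground-truth lesion mask minus the
#' mean outside — the statistic an ideal detector with access to the true
#' mask would use. Serves as an independent reference "embedding" in tests.
#'
#' @param x A sample from [simulate_dataset()].
#' @param cfg The generating [synthetic_config()].
#' @return Scalar contrast estimate.
#' @export
lesion_score <- function(x, cfg) {
  m <- lesion_mask(cfg$volume_shape, x$meta$lesion_center,
                   cfg$lesion_radius_voxels, cfg$lesion_kind)
  mean(x$volume$voxels[m]) - mean(x$volume$voxels[!m])
}

#' Split a sample set by patient
#'
#' Random partition of patients (not exams) into two sets, so that no
#' patient contributes samples to both sides — the leakage guard required
#' for honest train/test separation.
#'
#' @param s A `sample_set`.
#' @param fractions Two positive fractions summing to 1 (train, test).
#' @param seed Integer seed; the split is deterministic given it.
#' @return List of two `sample_set`s (`$train`, `$test`); their union is the
#'   input and their patient sets are disjoint.
#' @export
split_by_patient <- function(s, fractions = c(0.8, 0.2), seed = 1L) {
  if (length(fractions) != 2L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    config_error("fractions must be two positives summing to 1")
  }
  pats <- unique(patient_ids(s))
  if (length(pats) < 2L) {
    data_error("patient-level split needs at least 2 patients")
  }
  with_seed(seed, {
    shuffled <- sample(pats)
    n_train <- min(max(round(fractions[1] * length(pats)), 1L),
                   length(pats) - 1L)
    train_p <- shuffled[seq_len(n_train)]
    in_train <- patient_ids(s) %in% train_p
    list(train = subset_samples(s, which(in_train),
                                name = paste0(s$name, "_train")),
         test = subset_samples(s, which(!in_train),
                               name = paste0(s$name, "_test")))
  })
}

#' Write a simulated dataset to disk
#'
#' Materializes the generator's output in the on-disk dialect the loaders
#' consume: one `.npy` file per exam plus a manifest CSV.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
simulate_to_disk <- function(cfg, dir) {
  s <- simulate_dataset(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s$samples <- lapply(s$samples, function(x) {
    p <- file.path(dir, paste0(x$exam_id, ".npy"))
    write_npy(x$volume$voxels, p)
    x$path <- p
    x$format <- "npy"
    x
  })
  manifest <- file.path(dir, "manifest.csv")
  write_manifest(s, manifest)
  invisible(manifest)
}
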