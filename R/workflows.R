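# Orchestration of the experimental designs: simulate data, supervised
# (cross-entropy) pre-training, GE2E training, episodic k-shot evaluation
# and the supervised baseline trained on a support set of the same size.
# One config (nested list or YAML file) drives a run; the resolved config
# is written next to the outputs for provenance.

#' Default run configuration
#'
#' Nested list understood by every `run_*()` workflow. Any subset can be
#' overridden via a YAML file or an override list; keys absent from both
#' fall back to these defaults, and unknown keys abort.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    data = list(
      manifest = NULL,            # path to a manifest CSV, or NULL to simulate
      synthetic = list(n_patients = 240L, exams_per_patient = 1L,
                       volume_shape = c(16L, 32L, 32L), lesion_contrast = 3,
                       lesion_radius_voxels = 4, lesion_kind = "ellipsoid_A",
                       noise_sd = 1, class_balance = 0.5)),
    preprocess = list(target_shape = c(16L, 32L, 32L),
                      normalization = "zscore",
                      depth_policy = "center_crop_pad"),
    encoder = list(arch = "tiny3d", channels = c(8L, 16L),
                   embedding_dim = 32L),
    split = list(fractions = c(0.5, 0.5)),
    ge2e = list(self_exclusion = FALSE, scale = 1, bias = 0,
                n_labels = 2L, m_per_label = 4L, steps = 300L, lr = 3e-3),
    pretrain = list(batch_size = 8L, steps = 300L, lr = 3e-3),
    episodes = list(k = c(2L, 20L, 40L), n_episodes = 20L,
                    n_query = "all_remaining",
                    patient_disjoint_support_query = TRUE))
}

merge_config <- function(base, override, path = "config") {
  if (is.null(override)) return(base)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown)) {
    config_error(sprintf("unknown %s key(s): %s", path,
                         paste(unknown, collapse = ", ")))
  }
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
      merge_config(base[[k]], override[[k]], paste(path, k, sep = "$"))
    } else {
      override[[k]]
    }
  }
  base
}

#' Resolve a run configuration
#'
#' @param config `NULL` (defaults), a YAML file path, or an override list.
#' @param ... Further override lists applied in order (e.g. CLI flags).
#' @return The fully resolved config list.
#' @export
resolve_config <- function(config = NULL, ...) {
  cfg <- default_run_config()
  if (is.character(config)) {
    if (!file.exists(config)) config_error(sprintf("config file not found: %s",
                                                   config))
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(cfg, config)
  for (ov in list(...)) cfg <- merge_config(cfg, ov)
  cfg
}

prepare_out <- function(cfg, what) {
  if (is.null(cfg$out_dir)) config_error("out_dir is not set")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir,
                                  sprintf("%s_config_resolved.yaml", what)))
  cfg$out_dir
}

encoder_spec_of <- function(cfg) {
  encoder_spec(arch = cfg$encoder$arch, channels = cfg$encoder$channels,
               embedding_dim = cfg$encoder$embedding_dim,
               input_shape = cfg$preprocess$target_shape)
}

preprocess_spec_of <- function(cfg) {
  preprocess_spec(target_shape = cfg$preprocess$target_shape,
                  normalization = cfg$preprocess$normalization,
                  depth_policy = cfg$preprocess$depth_policy)
}

# load or simulate the dataset and preprocess every volume
load_pool <- function(cfg, lesion_kind = NULL, seed_offset = 0L) {
  sp <- preprocess_spec_of(cfg)
  if (!is.null(cfg$data$manifest)) {
    s <- read_manifest(cfg$data$manifest)
    return(materialize_volumes(s, sp))
  }
  sy <- cfg$data$synthetic
  scfg <- synthetic_config(
    n_patients = sy$n_patients, exams_per_patient = sy$exams_per_patient,
    volume_shape = sy$volume_shape, lesion_contrast = sy$lesion_contrast,
    lesion_radius_voxels = sy$lesion_radius_voxels,
    lesion_kind = lesion_kind %||% sy$lesion_kind, noise_sd = sy$noise_sd,
    class_balance = sy$class_balance, seed = cfg$seed + seed_offset)
  s <- simulate_dataset(scfg)
  s$samples <- lapply(s$samples, function(x) {
    x$volume <- preprocess(x$volume, sp)
    x
  })
  s
}

#' Simulate a synthetic dataset to disk
#'
#' @param config Config (see [resolve_config()]); uses the `data$synthetic`
#'   block, `seed` and `out_dir`.
#' @return Path of the written manifest.
#' @export
run_simulate <- function(config = NULL) {
  cfg <- resolve_config(config)
  out <- prepare_out(cfg, "simulate")
  sy <- cfg$data$synthetic
  scfg <- synthetic_config(
    n_patients = sy$n_patients, exams_per_patient = sy$exams_per_patient,
    volume_shape = sy$volume_shape, lesion_contrast = sy$lesion_contrast,
    lesion_radius_voxels = sy$lesion_radius_voxels,
    lesion_kind = sy$lesion_kind, noise_sd = sy$noise_sd,
    class_balance = sy$class_balance, seed = cfg$seed)
  simulate_to_disk(scfg, file.path(out, "dataset"))
}

#' Supervised pre-training workflow
#'
#' Trains an encoder plus temporary linear head with cross-entropy on the
#' patient-level training split, detaches the head, and writes the encoder
#' checkpoint and the training curve.
#'
#' @param config Config (see [resolve_config()]).
#' @return Invisibly, a list with the checkpoint path and the trained
#'   encoder.
#' @export
run_pretrain <- function(config = NULL) {
  cfg <- resolve_config(config)
  out <- prepare_out(cfg, "pretrain")
  pool <- load_pool(cfg)
  sp <- split_by_patient(pool, cfg$split$fractions, seed = cfg$seed + 1L)
  enc <- build_encoder(encoder_spec_of(cfg), seed = cfg$seed)
  clf <- attach_linear_head(enc, 2L, seed = cfg$seed + 2L)
  clf <- train_supervised(clf, sp$train,
                          schedule = c(cfg$pretrain, list(seed = cfg$seed + 3L)))
  enc <- detach_head(clf)
  ckpt <- file.path(out, "encoder_pretrained.json")
  save_encoder(enc, ckpt)
  utils::write.csv(attr(clf, "history"),
                   file.path(out, "pretrain_curve.csv"), row.names = FALSE)
  invisible(list(checkpoint = ckpt, encoder = enc))
}

#' GE2E training workflow
#'
#' Trains the encoder with the GE2E loss on the patient-level training
#' split, optionally starting from a pre-trained checkpoint, and writes
#' checkpoint plus loss curve.
#'
#' @param config Config (see [resolve_config()]).
#' @param init_checkpoint Optional encoder checkpoint to start from.
#' @return Invisibly, a list with the checkpoint path and the encoder.
#' @export
run_train_ge2e <- function(config = NULL, init_checkpoint = NULL) {
  cfg <- resolve_config(config)
  out <- prepare_out(cfg, "train_ge2e")
  pool <- load_pool(cfg)
  sp <- split_by_patient(pool, cfg$split$fractions, seed = cfg$seed + 1L)
  enc <- if (is.null(init_checkpoint)) {
    build_encoder(encoder_spec_of(cfg), seed = cfg$seed)
  } else {
    load_encoder(init_checkpoint, expect_spec = encoder_spec_of(cfg))
  }
  gcfg <- ge2e_config(self_exclusion = cfg$ge2e$self_exclusion,
                      scale = cfg$ge2e$scale, bias = cfg$ge2e$bias)
  enc <- train_ge2e(enc, sp$train, cfg = gcfg,
                    schedule = list(n_labels = cfg$ge2e$n_labels,
                                    m_per_label = cfg$ge2e$m_per_label,
                                    steps = cfg$ge2e$steps, lr = cfg$ge2e$lr,
                                    seed = cfg$seed + 4L))
  ckpt <- file.path(out, "encoder_ge2e.json")
  save_encoder(enc, ckpt)
  utils::write.csv(attr(enc, "history"),
                   file.path(out, "ge2e_curve.csv"), row.names = FALSE)
  invisible(list(checkpoint = ckpt, encoder = enc))
}

#' Episodic k-shot evaluation workflow
#'
#' Evaluates a (checkpointed or in-memory) encoder on the patient-level
#' test split, sweeping k, and writes a JSON summary plus per-episode
#' metrics CSV.
#'
#' @param config Config (see [resolve_config()]).
#' @param checkpoint Encoder checkpoint path, or an `encoder3d`.
#' @return Invisibly, a named list (one entry per k) of [evaluate_many()]
#'   results.
#' @export
run_evaluate <- function(config = NULL, checkpoint) {
  cfg <- resolve_config(config)
  out <- prepare_out(cfg, "evaluate")
  enc <- if (inherits(checkpoint, "encoder3d")) checkpoint else {
    load_encoder(checkpoint, expect_spec = encoder_spec_of(cfg))
  }
  pool <- load_pool(cfg)
  sp <- split_by_patient(pool, cfg$split$fractions, seed = cfg$seed + 1L)
  res <- list()
  rows <- list()
  for (k in cfg$episodes$k) {
    ecfg <- episode_config(
      k_shot = k, n_query = cfg$episodes$n_query,
      patient_disjoint_support_query =
        cfg$episodes$patient_disjoint_support_query)
    r <- evaluate_many(enc, sp$test, ecfg,
                       n_episodes = cfg$episodes$n_episodes,
                       base_seed = cfg$seed + 100L * k)
    res[[as.character(k)]] <- r
    rows[[as.character(k)]] <- cbind(k = k, r$metrics)
  }
  per_ep <- do.call(rbind, rows)
  utils::write.csv(per_ep, file.path(out, "episodes.csv"), row.names = FALSE)
  summary <- lapply(res, function(r) {
    s <- as.list(r$summary$mean)
    names(s) <- r$summary$metric
    s
  })
  jsonlite::write_json(summary, file.path(out, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Supervised baseline matched to a k-shot support budget
#'
#' Samples one k-shot episode from the test split, trains a cross-entropy
#' classifier on exactly its 2k support samples, and evaluates on the same
#' query pool the few-shot arm would see — the "supervised learning trained
#' with the same support sample" comparison.
#'
#' @param config Config (see [resolve_config()]); uses the first `k` of
#'   `episodes$k` (set `episodes$k` to 40 for the standard arm).
#' @return Invisibly, the `metrics_report`.
#' @export
run_baseline <- function(config = NULL) {
  cfg <- resolve_config(config)
  out <- prepare_out(cfg, "baseline")
  pool <- load_pool(cfg)
  sp <- split_by_patient(pool, cfg$split$fractions, seed = cfg$seed + 1L)
  k <- cfg$episodes$k[1]
  ep <- build_episode(sp$test, episode_config(
    k_shot = k, n_query = cfg$episodes$n_query,
    patient_disjoint_support_query =
      cfg$episodes$patient_disjoint_support_query,
    seed = cfg$seed + 100L * k + 1L))
  enc <- build_encoder(encoder_spec_of(cfg), seed = cfg$seed)
  clf <- attach_linear_head(enc, 2L, seed = cfg$seed + 2L)
  clf <- train_supervised(clf, ep$support,
                          schedule = c(cfg$pretrain, list(seed = cfg$seed + 3L)))
  rep <- summarize_results(predict_classifier(clf, ep$query))
  write_metrics_json(rep, file.path(out, "baseline_metrics.json"))
  invisible(rep)
}
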