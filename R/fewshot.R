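#' Episode configuration for 2-way k-shot evaluation
#'
#' @param k_shot Support samples per class (k).
#' @param n_way Number of classes; this package implements the binary case,
#'   so only 2 is accepted.
#' @param n_query `"all_remaining"` (default: every eligible non-support
#'   sample) or a fixed count, subsampled deterministically.
#' @param patient_disjoint_support_query Exclude from the query set every
#'   exam whose patient contributed a support sample (default `TRUE`).
#' @param seed Integer seed; an episode is bit-identical given it.
#' @return An object of class `episode_config`.
#' @export
episode_config <- function(k_shot, n_way = 2L, n_query = "all_remaining",
                           patient_disjoint_support_query = TRUE,
                           seed = 1L) {
  if (!is_count(k_shot)) config_error("k_shot must be a positive integer")
  if (!identical(as.integer(n_way), 2L)) {
    config_error("only 2-way episodes are supported")
  }
  if (!identical(n_query, "all_remaining") && !is_count(n_query)) {
    config_error("n_query must be 'all_remaining' or a positive integer")
  }
  structure(list(k_shot = as.integer(k_shot), n_way = 2L, n_query = n_query,
                 patient_disjoint_support_query =
                   isTRUE(patient_disjoint_support_query),
                 seed = as.integer(seed)),
            class = "episode_config")
}

#' Sample one support/query episode from a pool
#'
#' Draws exactly `k_shot` support exams per class; the query set is every
#' remaining exam (optionally capped at `n_query`), excluding — when
#' patient disjointness is on — all exams of patients present in the
#' support set, so the support never leaks patient identity into the
#' queries.
#'
#' @param pool A `sample_set` containing both classes.
#' @param cfg An [episode_config()].
#' @return An object of class `episode` with `$support`, `$query` and
#'   `$config`.
#' @export
build_episode <- function(pool, cfg) {
  stopifnot(inherits(pool, "sample_set"), inherits(cfg, "episode_config"))
  lab <- labels_of(pool)
  for (cl in c(0L, 1L)) {
    n_cl <- sum(lab == cl)
    if (n_cl < cfg$k_shot) {
      episode_error(sprintf(
        "class %d has %d samples but k_shot = %d are required",
        cl, n_cl, cfg$k_shot))
    }
  }
  with_seed(cfg$seed, {
    support_idx <- unlist(lapply(c(0L, 1L), function(cl) {
      ix <- which(lab == cl)
      ix[sample.int(length(ix), cfg$k_shot)]
    }))
    rest <- setdiff(seq_along(lab), support_idx)
    if (cfg$patient_disjoint_support_query) {
      sup_pat <- unique(patient_ids(pool)[support_idx])
      rest <- rest[!(patient_ids(pool)[rest] %in% sup_pat)]
    }
    if (length(rest) == 0L) {
      episode_error("no eligible query samples remain after support sampling")
    }
    if (!identical(cfg$n_query, "all_remaining")) {
      if (length(rest) > cfg$n_query) {
        rest <- sort(rest[sample.int(length(rest), cfg$n_query)])
      }
    }
    structure(list(
      support = subset_samples(pool, support_idx, name = "support"),
      query = subset_samples(pool, rest, name = "query"),
      config = cfg), class = "episode")
  })
}

#' @export
print.episode <- function(x, ...) {
  cat(sprintf("<episode: %d-shot support (%d samples), %d queries>\n",
              x$config$k_shot, length(x$support), length(x$query)))
  invisible(x)
}

#' Per-class prototypes from support embeddings
#'
#' The prototype of a class is the unweighted arithmetic mean of its
#' support embeddings, computed on the raw vectors by default; optionally
#' each embedding is L2-normalized first.
#'
#' @param embeddings n x D matrix of support embeddings.
#' @param labels Length-n binary labels.
#' @param normalize L2-normalize embeddings before averaging.
#' @return 2 x D matrix with rownames `"0"` and `"1"`.
#' @export
prototypes <- function(embeddings, labels, normalize = FALSE) {
  embeddings <- as.matrix(embeddings)
  if (normalize) {
    embeddings <- embeddings / sqrt(rowSums(embeddings^2))
  }
  if (!all(c(0L, 1L) %in% labels)) {
    input_error("support must contain both classes")
  }
  out <- rbind(colMeans(embeddings[labels == 0L, , drop = FALSE]),
               colMeans(embeddings[labels == 1L, , drop = FALSE]))
  rownames(out) <- c("0", "1")
  out
}

#' Classify one query embedding against prototypes
#'
#' Euclidean nearest-prototype rule: the predicted label minimizes
#' `||q - p_c||`; ties go to label 0 (the conservative "intact" call). The
#' continuous score is the distance margin `d_neg - d_pos`, positive when
#' the query is closer to the positive prototype.
#'
#' @param q Query embedding vector.
#' @param protos 2 x D prototype matrix from [prototypes()].
#' @return List with `exam_id`, `pred`, `score`, `d_neg`, `d_pos`.
#' @export
classify_query <- function(q, protos) {
  id <- attr(q, "exam_id") %||% NA_character_
  q <- as.numeric(q)
  if (length(q) != ncol(protos)) {
    input_error(sprintf("query has %d dimensions, prototypes have %d",
                        length(q), ncol(protos)))
  }
  d_neg <- sqrt(sum((q - protos["0", ])^2))
  d_pos <- sqrt(sum((q - protos["1", ])^2))
  list(exam_id = id,
       pred = if (d_pos < d_neg) 1L else 0L,
       score = d_neg - d_pos, d_neg = d_neg, d_pos = d_pos)
}

classify_matrix <- function(emb, protos) {
  d_neg <- sqrt(rowSums(sweep(emb, 2, protos["0", ])^2))
  d_pos <- sqrt(rowSums(sweep(emb, 2, protos["1", ])^2))
  data.frame(pred = as.integer(d_pos < d_neg), score = d_neg - d_pos,
             d_neg = d_neg, d_pos = d_pos)
}

#' Evaluate one episode with an encoder
#'
#' Embeds support and query volumes in inference mode, builds prototypes
#' from the support embeddings, and classifies every query.
#'
#' @param enc Encoder handle.
#' @param ep An [build_episode()] result with conforming volumes.
#' @param normalize_prototypes L2-normalize embeddings before averaging.
#' @return data.frame with one row per query: `exam_id`, `true`, `pred`,
#'   `score`, `d_neg`, `d_pos`.
#' @export
evaluate_episode <- function(enc, ep, normalize_prototypes = FALSE) {
  sup <- embed_batch(enc, ep$support)
  qry <- embed_batch(enc, ep$query)
  protos <- prototypes(sup$embeddings, sup$label,
                       normalize = normalize_prototypes)
  res <- classify_matrix(qry$embeddings, protos)
  cbind(data.frame(exam_id = qry$exam_id, true = qry$label,
                   stringsAsFactors = FALSE), res)
}

# episode evaluation on precomputed pool embeddings (one embed pass serves
# every episode of a sweep)
evaluate_episode_emb <- function(pool_emb, ep) {
  sup_ix <- match(exam_ids(ep$support), pool_emb$exam_id)
  qry_ix <- match(exam_ids(ep$query), pool_emb$exam_id)
  protos <- prototypes(pool_emb$embeddings[sup_ix, , drop = FALSE],
                       pool_emb$label[sup_ix])
  res <- classify_matrix(pool_emb$embeddings[qry_ix, , drop = FALSE], protos)
  cbind(data.frame(exam_id = pool_emb$exam_id[qry_ix],
                   true = pool_emb$label[qry_ix], stringsAsFactors = FALSE),
        res)
}

#' Episodic evaluation over many resampled episodes
#'
#' Embeds the pool once, then samples `n_episodes` episodes (episode `e`
#' uses seed `base_seed + e`), evaluates each, and aggregates the per-
#' episode metrics as mean and SD.
#'
#' @param enc Encoder handle.
#' @param pool A conforming `sample_set`.
#' @param cfg An [episode_config()] (its `seed` field is overridden per
#'   episode).
#' @param n_episodes Number of episodes.
#' @param base_seed Base seed for the episode sequence.
#' @return List with `per_episode` (list of [summarize_results()] reports),
#'   `metrics` (data.frame of per-episode acc/sen/spe/auc) and `summary`
#'   (mean and SD per metric).
#' @export
evaluate_many <- function(enc, pool, cfg, n_episodes = 20L, base_seed = 1L) {
  pool_emb <- embed_batch(enc, pool)
  reports <- vector("list", n_episodes)
  for (e in seq_len(n_episodes)) {
    cfg$seed <- as.integer(base_seed + e)
    ep <- build_episode(pool, cfg)
    reports[[e]] <- summarize_results(evaluate_episode_emb(pool_emb, ep))
  }
  met <- data.frame(
    episode = seq_len(n_episodes),
    acc = vapply(reports, function(r) r$acc, numeric(1)),
    sen = vapply(reports, function(r) r$sen %||% NA_real_, numeric(1)),
    spe = vapply(reports, function(r) r$spe %||% NA_real_, numeric(1)),
    auc = vapply(reports, function(r) r$auc, numeric(1)))
  summ <- data.frame(
    metric = c("acc", "sen", "spe", "auc"),
    mean = colMeans(met[, c("acc", "sen", "spe", "auc")], na.rm = TRUE),
    sd = vapply(met[, c("acc", "sen", "spe", "auc")], stats::sd,
                numeric(1), na.rm = TRUE))
  rownames(summ) <- NULL
  list(per_episode = reports, metrics = met, summary = summ)
}
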