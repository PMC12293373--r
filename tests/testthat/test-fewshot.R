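make_pool <- function(n = 100, seed = 1) {
  tiny_dataset(n_patients = n, seed = seed)
}

test_that("episode counting: 100-sample pool, k = 40 leaves 20 queries", {
  pool <- make_pool(100)
  ep <- build_episode(pool, episode_config(k_shot = 40, seed = 3))
  expect_length(ep$support, 80L)
  expect_length(ep$query, 20L)
  expect_identical(sum(labels_of(ep$support) == 0L), 40L)
  expect_identical(sum(labels_of(ep$support) == 1L), 40L)
})

test_that("episodes fail loudly when a class cannot fill the support", {
  pool <- make_pool(10)   # ~5 per class
  expect_error(build_episode(pool, episode_config(k_shot = 20)),
               "class [01] has \\d+ samples", class = "fs3d_episode_error")
})

test_that("support and query stay exam- and patient-disjoint over seeds", {
  pool <- tiny_dataset(n_patients = 20, exams_per_patient = 3, seed = 2)
  for (seed in 1:10) {
    ep <- build_episode(pool, episode_config(k_shot = 5, seed = seed))
    expect_length(intersect(exam_ids(ep$support), exam_ids(ep$query)), 0L)
    expect_length(intersect(patient_ids(ep$support),
                            patient_ids(ep$query)), 0L)
  }
  # with disjointness off, exams still never repeat
  ep2 <- build_episode(pool, episode_config(
    k_shot = 5, patient_disjoint_support_query = FALSE, seed = 1))
  expect_length(intersect(exam_ids(ep2$support), exam_ids(ep2$query)), 0L)
})

test_that("episodes are bit-identical per seed and honor fixed n_query", {
  pool <- make_pool(40)
  e1 <- build_episode(pool, episode_config(k_shot = 4, seed = 12))
  e2 <- build_episode(pool, episode_config(k_shot = 4, seed = 12))
  expect_identical(exam_ids(e1$support), exam_ids(e2$support))
  expect_identical(exam_ids(e1$query), exam_ids(e2$query))

  e3 <- build_episode(pool, episode_config(k_shot = 4, n_query = 6, seed = 12))
  expect_length(e3$query, 6L)
  expect_true(all(exam_ids(e3$query) %in% exam_ids(e1$query)))
})

test_that("prototypes equal loop means; k = 1 returns the lone embedding", {
  e1 <- matrix(c(5, 7, 0, 0), nrow = 2, byrow = TRUE)
  p <- prototypes(e1, c(1L, 0L))
  expect_equal(p["1", ], c(5, 7))

  emb2 <- rbind(c(0, 0), c(2, 2), c(9, 9))
  p2 <- prototypes(emb2, c(1L, 1L, 0L))
  expect_equal(unname(p2["1", ]), c(1, 1))

  set.seed(7)
  emb <- matrix(rnorm(80 * 16), 80, 16)
  lab <- rep(c(0L, 1L), each = 40)
  p3 <- prototypes(emb, lab)
  for (d in 1:16) {
    expect_equal(unname(p3["0", d]), sum(emb[1:40, d]) / 40,
                 tolerance = 1e-12)
    expect_equal(unname(p3["1", d]), sum(emb[41:80, d]) / 40,
                 tolerance = 1e-12)
  }
})

test_that("classification is nearest-prototype with ties toward label 0", {
  protos <- rbind("0" = c(0, 0), "1" = c(2, 0))
  hit <- classify_query(c(2, 0), protos)
  expect_identical(hit$pred, 1L)
  expect_gt(hit$score, 0)

  tie <- classify_query(c(1, 5), protos)
  expect_identical(tie$pred, 0L)
  expect_equal(tie$score, 0)

  set.seed(8)
  for (t in 1:100) {
    p0 <- rnorm(4); p1 <- rnorm(4); q <- rnorm(4)
    got <- classify_query(q, rbind("0" = p0, "1" = p1))
    expect_identical(got$pred, oracle_nearest(q, p0, p1))
    expect_equal(got$score, sqrt(sum((q - p0)^2)) - sqrt(sum((q - p1)^2)))
  }
})

test_that("query dimension mismatches are rejected", {
  protos <- rbind("0" = c(0, 0, 0), "1" = c(1, 1, 1))
  expect_error(classify_query(c(1, 2), protos), "dimensions",
               class = "fs3d_input_error")
})

test_that("episode evaluation is deterministic and ordered like the query set", {
  pool <- zscore_set(make_pool(30))
  enc <- build_encoder(tiny_spec(), seed = 1)
  ep <- build_episode(pool, episode_config(k_shot = 5, seed = 2))
  r1 <- evaluate_episode(enc, ep)
  r2 <- evaluate_episode(enc, ep)
  expect_identical(r1, r2)
  expect_identical(r1$exam_id, exam_ids(ep$query))
  expect_true(all(r1$pred == as.integer(r1$d_pos < r1$d_neg)))
})

test_that("relabeling the support flips predictions and mirrors the AUC", {
  set.seed(9)
  emb_s <- matrix(rnorm(20 * 6), 20, 6)
  lab_s <- rep(c(0L, 1L), 10)
  emb_q <- matrix(rnorm(30 * 6), 30, 6)
  lab_q <- rep(c(0L, 1L), 15)
  run <- function(sup_lab) {
    p <- prototypes(emb_s, sup_lab)
    fewshot3d:::classify_matrix(emb_q, p)
  }
  a <- run(lab_s)
  b <- run(1L - lab_s)
  expect_identical(b$pred, 1L - a$pred)
  expect_equal(b$score, -a$score)
  expect_equal(roc_auc(b$score, lab_q), 1 - roc_auc(a$score, lab_q),
               tolerance = 1e-15)
})

test_that("with the oracle statistic as embedding, AUC tracks lesion contrast", {
  auc_at <- function(contrast, seed) {
    cfg <- synthetic_config(n_patients = 60, volume_shape = c(8, 12, 12),
                            lesion_contrast = contrast,
                            lesion_radius_voxels = 2.5, seed = seed)
    s <- simulate_dataset(cfg)
    sc <- vapply(s$samples, lesion_score, numeric(1), cfg = cfg)
    # 1-d "embedding": nearest prototype along the oracle axis
    ep <- build_episode(s, episode_config(k_shot = 10, seed = seed))
    sup <- match(exam_ids(ep$support), exam_ids(s))
    qry <- match(exam_ids(ep$query), exam_ids(s))
    p <- prototypes(matrix(sc[sup], ncol = 1), labels_of(ep$support))
    res <- fewshot3d:::classify_matrix(matrix(sc[qry], ncol = 1), p)
    roc_auc(res$score, labels_of(ep$query))
  }
  hi <- mean(vapply(1:5, function(s) auc_at(6, s), numeric(1)))
  null <- mean(vapply(1:5, function(s) auc_at(0, s), numeric(1)))
  expect_gt(hi, 0.95)
  expect_lt(abs(null - 0.5), 0.15)
})

test_that("evaluate_many aggregates per-episode metrics with stable seeds", {
  pool <- zscore_set(make_pool(40))
  enc <- build_encoder(tiny_spec(), seed = 1)
  r <- evaluate_many(enc, pool, episode_config(k_shot = 5), n_episodes = 4,
                     base_seed = 3)
  expect_length(r$per_episode, 4L)
  expect_identical(nrow(r$metrics), 4L)
  expect_identical(r$summary$metric, c("acc", "sen", "spe", "auc"))
  r2 <- evaluate_many(enc, pool, episode_config(k_shot = 5), n_episodes = 4,
                      base_seed = 3)
  expect_identical(r$metrics, r2$metrics)
})
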