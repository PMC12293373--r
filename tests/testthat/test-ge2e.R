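test_that("centroids are per-label means, matching an explicit loop", {
  u <- c(1, 2, 3)
  emb <- array(0, c(2, 2, 3))
  emb[1, 1, ] <- u; emb[1, 2, ] <- u
  emb[2, 1, ] <- c(1, 0, 0); emb[2, 2, ] <- c(0, 1, 0)
  cents <- ge2e_centroids(embedding_batch(emb))
  expect_equal(cents[1, ], u)
  expect_equal(cents[2, ], c(0.5, 0.5, 0))

  set.seed(1)
  emb <- array(rnorm(3 * 4 * 8), c(3, 4, 8))
  cents <- ge2e_centroids(embedding_batch(emb))
  for (i in 1:3) for (d in 1:8) {
    expect_equal(cents[i, d], mean(emb[i, , d]), tolerance = 1e-12)
  }
})

test_that("similarity is the affine cosine, colinear 1 and orthogonal 0", {
  emb <- array(0, c(2, 1, 2))
  emb[1, 1, ] <- c(1, 0)
  emb[2, 1, ] <- c(0, 3)
  b <- embedding_batch(emb)
  S <- ge2e_similarity(b, ge2e_centroids(b))
  expect_equal(S[1, 1, 1], 1.0)   # f = (1,0) vs own centroid (1,0)
  expect_equal(S[1, 1, 2], 0.0)   # vs orthogonal centroid (0,3)

  set.seed(2)
  emb <- array(rnorm(3 * 3 * 5), c(3, 3, 5))
  b <- embedding_batch(emb)
  cents <- ge2e_centroids(b)
  S <- ge2e_similarity(b, cents)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    u <- emb[i, j, ]; ck <- cents[k, ]
    expect_equal(S[i, j, k],
                 sum(u * ck) / sqrt(sum(u^2) * sum(ck^2)), tolerance = 1e-10)
  }
})

test_that("single-label batches give exactly zero loss", {
  set.seed(3)
  for (M in c(1, 3, 5)) {
    emb <- array(rnorm(1 * M * 6), c(1, M, 6))
    expect_identical(ge2e_loss(embedding_batch(emb)), 0)
  }
})

test_that("the two-singleton case matches the hand-evaluated formula", {
  emb <- array(0, c(2, 1, 2))
  emb[1, 1, ] <- c(1, 0)
  emb[2, 1, ] <- c(0, 1)
  # per sample: own similarity 1, other 0 -> loss = -1 + log(e^1 + e^0)
  expected <- 2 * (-1 + log(exp(1) + 1))
  expect_equal(ge2e_loss(embedding_batch(emb)), expected, tolerance = 1e-12)
})

test_that("loss matches the loop oracle across configurations", {
  set.seed(4)
  for (rep in 1:20) {
    N <- sample(2:4, 1); M <- sample(2:5, 1); D <- sample(2:8, 1)
    emb <- array(rnorm(N * M * D), c(N, M, D))
    expect_equal(ge2e_loss(embedding_batch(emb)),
                 oracle_ge2e(emb), tolerance = 1e-6)
    cfg <- ge2e_config(self_exclusion = TRUE, scale = 2.5, bias = -0.7)
    expect_equal(ge2e_loss(embedding_batch(emb), cfg),
                 oracle_ge2e(emb, scale = 2.5, bias = -0.7,
                             self_exclusion = TRUE),
                 tolerance = 1e-6)
    expect_equal(ge2e_loss(embedding_batch(emb), reduction = "mean"),
                 oracle_ge2e(emb) / (N * M), tolerance = 1e-6)
  }
})

test_that("analytic embedding gradients match finite differences", {
  set.seed(5)
  for (cfg in list(ge2e_config(),
                   ge2e_config(self_exclusion = TRUE, scale = 1.4,
                               bias = 0.3))) {
    emb <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
    g <- ge2e_loss(embedding_batch(emb), cfg, grad = TRUE)
    h <- 1e-6
    for (t in 1:12) {
      i <- sample(3, 1); j <- sample(3, 1); d <- sample(4, 1)
      up <- dn <- emb
      up[i, j, d] <- up[i, j, d] + h
      dn[i, j, d] <- dn[i, j, d] - h
      num <- (ge2e_loss(embedding_batch(up), cfg) -
                ge2e_loss(embedding_batch(dn), cfg)) / (2 * h)
      expect_equal(g$grad[i, j, d], num, tolerance = 1e-5)
    }
  }
})

test_that("loss is permutation-equivariant and cosine-scale-invariant", {
  set.seed(6)
  emb <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  base <- ge2e_loss(embedding_batch(emb))
  perm_i <- sample(3); perm_j <- sample(4)
  expect_equal(ge2e_loss(embedding_batch(emb[perm_i, perm_j, , drop = FALSE])),
               base, tolerance = 1e-10)
  expect_equal(ge2e_loss(embedding_batch(emb * 3)), base, tolerance = 1e-8)
})

test_that("degenerate batches raise typed errors, not NaN", {
  emb <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  emb[1, 1, ] <- 0
  expect_error(embedding_batch(emb), class = "fs3d_numeric_error")
  ok <- embedding_batch(array(rnorm(2 * 1 * 3), c(2, 1, 3)))
  expect_error(ge2e_centroids(ok, ge2e_config(self_exclusion = TRUE)),
               class = "fs3d_config_error")
})

test_that("one optimizer step on a separable batch decreases the loss", {
  s <- zscore_set(tiny_dataset(n_patients = 10, lesion_contrast = 8, seed = 7))
  enc <- build_encoder(tiny_spec(), seed = 1)
  sched <- list(n_labels = 2L, m_per_label = 3L, steps = 1L, lr = 1e-3,
                seed = 9L)
  # loss of the step-1 batch before and after that step (same sampled batch)
  loss_of <- function(e) {
    lab <- labels_of(s)
    withr::with_seed(9L, {
      picks <- lapply(c(0L, 1L), function(cl) {
        ix <- which(lab == cl); ix[sample.int(length(ix), 3)]
      })
      emb <- array(0, c(2, 3, e$spec$embedding_dim))
      for (i in 1:2) for (j in 1:3) {
        emb[i, j, ] <- as.numeric(embed(e, s$samples[[picks[[i]][j]]]$volume))
      }
      ge2e_loss(embedding_batch(emb))
    })
  }
  before <- loss_of(enc)
  enc2 <- train_ge2e(enc, s, schedule = sched)
  expect_lt(loss_of(enc2), before)
})

test_that("training validates per-label availability before any step", {
  s <- zscore_set(tiny_dataset(n_patients = 4, seed = 8))
  enc <- build_encoder(tiny_spec(), seed = 1)
  expect_error(
    train_ge2e(enc, s, schedule = list(m_per_label = 10L, steps = 5L)),
    "only", class = "fs3d_data_error")
})

test_that("training is reproducible given the seed", {
  s <- zscore_set(tiny_dataset(n_patients = 8, seed = 9))
  enc <- build_encoder(tiny_spec(), seed = 2)
  sched <- list(steps = 5L, m_per_label = 2L, seed = 11L)
  h1 <- attr(train_ge2e(enc, s, schedule = sched), "history")
  h2 <- attr(train_ge2e(enc, s, schedule = sched), "history")
  expect_equal(h1$loss, h2$loss, tolerance = 1e-10)
})
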