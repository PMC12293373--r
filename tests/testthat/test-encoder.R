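test_that("encoder output length equals embedding_dim with no classifier head", {
  enc <- build_encoder(tiny_spec(embedding_dim = 16L), seed = 1)
  v <- volume(array(rnorm(8 * 12 * 12), c(8, 12, 12)), "e", "p")
  e <- embed(enc, v)
  expect_length(as.numeric(e), 16L)
  expect_true(all(is.finite(e)))
  expect_identical(attr(e, "exam_id"), "e")
})

test_that("initialization is deterministic per seed and differs across seeds", {
  s <- tiny_spec()
  e1 <- build_encoder(s, seed = 5)
  e2 <- build_encoder(s, seed = 5)
  e3 <- build_encoder(s, seed = 6)
  expect_identical(e1$params, e2$params)
  v <- volume(array(rnorm(8 * 12 * 12), c(8, 12, 12)), "e", "p")
  expect_false(isTRUE(all.equal(as.numeric(embed(e1, v)),
                                as.numeric(embed(e3, v)))))
})

test_that("adaptive pooling keeps the embedding length across input sizes", {
  enc <- build_encoder(tiny_spec(), seed = 2)
  x1 <- array(rnorm(8 * 12 * 12), c(8, 12, 12, 1))
  x2 <- array(rnorm(8 * 24 * 24), c(8, 24, 24, 1))
  e1 <- fewshot3d:::enc_forward(enc, x1)$e
  e2 <- fewshot3d:::enc_forward(enc, x2)$e
  expect_length(e1, length(e2))
})

test_that("embed validates the input shape naming both shapes", {
  enc <- build_encoder(tiny_spec(), seed = 1)
  v <- volume(array(0.5, c(4, 12, 12)), "e", "p")
  expect_error(embed(enc, v), "4x12x12.*8x12x12", class = "fs3d_input_error")
})

test_that("embed_batch equals per-sample embeddings in order", {
  enc <- build_encoder(tiny_spec(), seed = 3)
  s <- zscore_set(tiny_dataset(n_patients = 6, seed = 2))
  eb <- embed_batch(enc, s)
  expect_identical(dim(eb$embeddings), c(6L, 8L))
  for (i in seq_len(6)) {
    expect_equal(eb$embeddings[i, ], as.numeric(embed(enc, s$samples[[i]]$volume)),
                 tolerance = 1e-5)
  }
  expect_identical(eb$exam_id, exam_ids(s))
})

test_that("embedding depends only on the preprocessed voxels", {
  enc <- build_encoder(tiny_spec(), seed = 4)
  # shape-conforming input + no normalization: preprocessing is the exact
  # identity, so the two routes agree bit for bit
  spn <- preprocess_spec(c(8, 12, 12), normalization = "none")
  v <- volume(array(rnorm(8 * 12 * 12), c(8, 12, 12)), "e", "p")
  expect_identical(as.numeric(embed(enc, preprocess(v, spn))),
                   as.numeric(embed(enc, v)))
  # with z-scoring, re-preprocessing conforming input agrees to rounding
  spz <- preprocess_spec(c(8, 12, 12), normalization = "zscore")
  v_pre <- preprocess(volume(array(rnorm(10 * 16 * 16, 3, 2),
                                   c(10, 16, 16)), "e", "p"), spz)
  expect_equal(as.numeric(embed(enc, preprocess(v_pre, spz))),
               as.numeric(embed(enc, v_pre)), tolerance = 1e-12)
})

test_that("encoder backprop matches central finite differences", {
  set.seed(42)
  for (arch in c("tiny3d", "resnet_style")) {
    spec <- encoder_spec(arch, channels = 2L, embedding_dim = 2L,
                         input_shape = c(4L, 6L, 6L))
    enc <- build_encoder(spec, seed = 3)
    x <- array(rnorm(4 * 6 * 6), c(4, 6, 6, 1))
    ge <- rnorm(2)
    fw <- fewshot3d:::enc_forward(enc, x, cache = TRUE)
    g <- fewshot3d:::enc_backward(enc, fw$cache, ge)
    proj <- function(e) sum(fewshot3d:::enc_forward(e, x)$e * ge)
    h <- 1e-6
    for (t in 1:8) {
      l <- sample(names(enc$params), 1)
      ii <- sample(length(enc$params[[l]]$W), 1)
      up <- dn <- enc
      up$params[[l]]$W[ii] <- up$params[[l]]$W[ii] + h
      dn$params[[l]]$W[ii] <- dn$params[[l]]$W[ii] - h
      expect_equal(g[[l]]$W[ii], (proj(up) - proj(dn)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip exactly and refuse mismatched specs", {
  enc <- build_encoder(tiny_spec(), seed = 9)
  p <- tempfile(fileext = ".json")
  save_encoder(enc, p)
  enc2 <- load_encoder(p)
  v <- volume(array(rnorm(8 * 12 * 12), c(8, 12, 12)), "e", "p")
  expect_identical(as.numeric(embed(enc, v)), as.numeric(embed(enc2, v)))
  expect_error(load_encoder(p, expect_spec = tiny_spec(embedding_dim = 4L)),
               "match", class = "fs3d_config_error")
})

test_that("detaching the head returns an encoder carrying trained weights", {
  s <- zscore_set(tiny_dataset(n_patients = 12, seed = 5))
  enc0 <- build_encoder(tiny_spec(), seed = 1)
  clf <- attach_linear_head(enc0, 2, seed = 2)
  clf <- train_supervised(clf, s, schedule = list(steps = 10L, seed = 3L))
  enc1 <- detach_head(clf)
  expect_s3_class(enc1, "encoder3d")
  expect_null(enc1$params$head)
  v <- s$samples[[1]]$volume
  expect_false(isTRUE(all.equal(as.numeric(embed(enc0, v)),
                                as.numeric(embed(enc1, v)))))
})

test_that("invalid encoder configurations fail at build time", {
  expect_error(encoder_spec(embedding_dim = 1L), class = "fs3d_config_error")
  expect_error(encoder_spec(channels = integer(0)), class = "fs3d_config_error")
})
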