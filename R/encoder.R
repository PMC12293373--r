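#' Specification of a 3D convolutional embedding encoder
#'
#' The encoder maps a fixed-shape grayscale volume to a `embedding_dim`
#' vector. It ends in global adaptive average pooling over all remaining
#' spatial positions — not a classification layer — so the output length is
#' `embedding_dim` regardless of the spatial extent reaching the last stage.
#'
#' Two architectures are available:
#' * `tiny3d` (default): one stride-2 3x3x3 convolution + ReLU per entry of
#'   `channels`, a final stride-2 convolution to `embedding_dim` channels,
#'   then global average pooling. With the defaults this is ~20k parameters
#'   and trains in seconds per hundred steps on one CPU core.
#' * `resnet_style`: same downsampling trunk, but each stage is followed by
#'   a two-convolution residual block with an identity skip, for scale-up
#'   experiments.
#'
#' @param arch `"tiny3d"` or `"resnet_style"`.
#' @param channels Output channels of each downsampling stage before the
#'   embedding stage.
#' @param embedding_dim Length of the embedding vector (>= 2).
#' @param input_shape Expected volume shape `(depth, height, width)`.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(arch = c("tiny3d", "resnet_style"),
                         channels = c(8L, 16L), embedding_dim = 32L,
                         input_shape = c(16L, 32L, 32L)) {
  arch <- match.arg(arch)
  channels <- as.integer(channels)
  if (length(channels) < 1L || any(channels < 1L)) {
    config_error("channels must be one or more positive integers")
  }
  if (!is_count(embedding_dim) || embedding_dim < 2) {
    config_error("embedding_dim must be an integer >= 2")
  }
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 1L)) {
    config_error("input_shape must be three integers >= 1")
  }
  spec <- structure(list(arch = arch, channels = channels,
                         embedding_dim = as.integer(embedding_dim),
                         input_shape = input_shape),
                    class = "encoder_spec")
  # stride/shape arithmetic must be valid at build time, not at first use
  shp <- input_shape
  for (i in seq_len(length(channels) + 1L)) {
    shp <- (shp + 2L * 1L - 3L) %/% 2L + 1L
    if (any(shp < 1L)) {
      config_error(sprintf(
        "input_shape %s collapses below 1 voxel at stage %d",
        paste(input_shape, collapse = "x"), i))
    }
  }
  spec
}

conv_init <- function(k, cin, cout) {
  list(W = array(stats::rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
                 dim = c(k, k, k, cin, cout)),
       b = numeric(cout))
}

#' Build a trainable encoder
#'
#' Parameter initialization (He-scaled Gaussian) is deterministic given
#' `seed`. The returned handle is a plain parameter container: training
#' functions return updated copies, never mutate in place.
#'
#' @param spec An [encoder_spec()].
#' @param seed Integer seed for the initialization.
#' @return An object of class `encoder3d`.
#' @export
build_encoder <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "encoder_spec"))
  chans <- c(1L, spec$channels, spec$embedding_dim)
  params <- with_seed(seed, {
    p <- list()
    for (s in seq_len(length(chans) - 1L)) {
      p[[sprintf("down%d", s)]] <- conv_init(3L, chans[s], chans[s + 1L])
      if (spec$arch == "resnet_style") {
        p[[sprintf("res%da", s)]] <- conv_init(3L, chans[s + 1L], chans[s + 1L])
        p[[sprintf("res%db", s)]] <- conv_init(3L, chans[s + 1L], chans[s + 1L])
      }
    }
    p
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 version = 1L),
            class = "encoder3d")
}

#' @export
print.encoder3d <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$W) + length(p$b),
                      numeric(1)))
  cat(sprintf("<encoder3d %s: %s -> %d-d embedding, %d parameters>\n",
              x$spec$arch, paste(x$spec$input_shape, collapse = "x"),
              x$spec$embedding_dim, n_par))
  invisible(x)
}

# leaky rectifier: keeps a small negative-side slope so units cannot die
# under aggressive adaptive-optimizer steps (a dead stage would collapse
# embeddings to the zero vector, where cosine similarity is undefined)
LEAK <- 0.1

relu <- function(x) {
  neg <- x < 0
  x[neg] <- LEAK * x[neg]
  x
}

relu_grad <- function(z) {
  g <- array(1, dim(z))
  g[z < 0] <- LEAK
  g
}

# Forward pass. `x` is a (d, h, w, 1) array; returns the embedding and,
# when cache = TRUE, the pre-activations needed for the backward pass.
enc_forward <- function(enc, x, cache = FALSE) {
  p <- enc$params
  n_stage <- length(enc$spec$channels) + 1L
  cc <- if (cache) list(x0 = x) else NULL
  h <- x
  for (s in seq_len(n_stage)) {
    z <- conv3d_fwd(h, p[[sprintf("down%d", s)]]$W, p[[sprintf("down%d", s)]]$b,
                    2L, 1L)
    a <- relu(z)
    if (cache) {
      cc[[sprintf("zdown%d", s)]] <- z
      cc[[sprintf("in_down%d", s)]] <- h
    }
    h <- a
    if (enc$spec$arch == "resnet_style") {
      za <- conv3d_fwd(h, p[[sprintf("res%da", s)]]$W,
                       p[[sprintf("res%da", s)]]$b, 1L, 1L)
      ra <- relu(za)
      zb <- conv3d_fwd(ra, p[[sprintf("res%db", s)]]$W,
                       p[[sprintf("res%db", s)]]$b, 1L, 1L)
      zsum <- h + zb
      if (cache) {
        cc[[sprintf("in_res%d", s)]] <- h
        cc[[sprintf("za%d", s)]] <- za
        cc[[sprintf("ra%d", s)]] <- ra
        cc[[sprintf("zsum%d", s)]] <- zsum
      }
      h <- relu(zsum)
    }
  }
  dm <- dim(h)
  e <- colMeans(matrix(h, nrow = prod(dm[1:3]), ncol = dm[4]))
  if (cache) {
    cc$top_dim <- dm
  }
  list(e = e, cache = cc)
}

# Backward pass: gradient of a scalar loss w.r.t. every parameter, given
# the gradient `ge` w.r.t. the embedding. Returns a list shaped like
# enc$params.
enc_backward <- function(enc, cc, ge) {
  p <- enc$params
  n_stage <- length(enc$spec$channels) + 1L
  g <- lapply(p, function(q) list(W = array(0, dim(q$W)),
                                  b = numeric(length(q$b))))
  dm <- cc$top_dim
  nvox <- prod(dm[1:3])
  gh <- array(rep(ge / nvox, each = nvox), dim = dm)
  for (s in rev(seq_len(n_stage))) {
    if (enc$spec$arch == "resnet_style") {
      gzsum <- gh * relu_grad(cc[[sprintf("zsum%d", s)]])
      bb <- conv3d_bwd(cc[[sprintf("ra%d", s)]], p[[sprintf("res%db", s)]]$W,
                       gzsum, 1L, 1L)
      g[[sprintf("res%db", s)]]$W <- bb$gw
      g[[sprintf("res%db", s)]]$b <- bb$gb
      gza <- bb$gx * relu_grad(cc[[sprintf("za%d", s)]])
      ba <- conv3d_bwd(cc[[sprintf("in_res%d", s)]],
                       p[[sprintf("res%da", s)]]$W, gza, 1L, 1L)
      g[[sprintf("res%da", s)]]$W <- ba$gw
      g[[sprintf("res%da", s)]]$b <- ba$gb
      gh <- gzsum + ba$gx   # skip path + residual path
    }
    gz <- gh * relu_grad(cc[[sprintf("zdown%d", s)]])
    bd <- conv3d_bwd(cc[[sprintf("in_down%d", s)]],
                     p[[sprintf("down%d", s)]]$W, gz, 2L, 1L)
    g[[sprintf("down%d", s)]]$W <- bd$gw
    g[[sprintf("down%d", s)]]$b <- bd$gb
    gh <- bd$gx
  }
  g
}

#' Embed a volume
#'
#' Runs the encoder in inference mode (the architectures contain no
#' stochastic layers, so inference is deterministic by construction) and
#' returns the `embedding_dim`-length vector.
#'
#' @param enc An [build_encoder()] handle.
#' @param v A [volume()] whose shape matches `enc$spec$input_shape`
#'   (apply [preprocess()] first).
#' @return Numeric vector with attribute `exam_id`.
#' @export
embed <- function(enc, v) {
  stopifnot(inherits(enc, "encoder3d"), inherits(v, "volume"))
  shp <- dim(v$voxels)
  want <- enc$spec$input_shape
  if (!identical(as.integer(shp), want)) {
    input_error(sprintf(
      "volume %s has shape %s but the encoder expects %s",
      v$exam_id, paste(shp, collapse = "x"), paste(want, collapse = "x")))
  }
  x <- v$voxels
  dim(x) <- c(shp, 1L)
  e <- enc_forward(enc, x)$e
  attr(e, "exam_id") <- v$exam_id
  e
}

#' Embed every volume of a sample set
#'
#' @param enc Encoder handle.
#' @param s A `sample_set` with materialized volumes.
#' @return List with `embeddings` (n x embedding_dim matrix, rows in the
#'   set's order), `label`, `patient_id` and `exam_id` vectors.
#' @export
embed_batch <- function(enc, s) {
  stopifnot(inherits(s, "sample_set"))
  emb <- t(vapply(s$samples, function(x) as.numeric(embed(enc, x$volume)),
                  numeric(enc$spec$embedding_dim)))
  list(embeddings = emb, label = labels_of(s), patient_id = patient_ids(s),
       exam_id = exam_ids(s))
}

#' Attach a temporary linear classification head
#'
#' Supervised pre-training needs a classifier on top of the embedding; the
#' head is attached for training and discarded afterwards with
#' [detach_head()], leaving an encoder whose embeddings reflect the trained
#' weights.
#'
#' @param enc Encoder handle.
#' @param n_classes Number of classes (2 for the binary tasks here).
#' @param seed Seed for the head initialization.
#' @return An object of class `classifier3d`.
#' @export
attach_linear_head <- function(enc, n_classes = 2L, seed = 1L) {
  stopifnot(inherits(enc, "encoder3d"))
  D <- enc$spec$embedding_dim
  head <- with_seed(seed, list(
    W = matrix(stats::rnorm(D * n_classes, 0, sqrt(1 / D)), D, n_classes),
    b = numeric(n_classes)))
  structure(list(encoder = enc, head = head, n_classes = as.integer(n_classes)),
            class = "classifier3d")
}

#' @rdname attach_linear_head
#' @param clf A `classifier3d`.
#' @return For `detach_head()`: the trained `encoder3d`; head parameters are
#'   discarded.
#' @export
detach_head <- function(clf) {
  stopifnot(inherits(clf, "classifier3d"))
  clf$encoder
}

# --- checkpoints ------------------------------------------------------------

#' Save / load encoder checkpoints
#'
#' Checkpoints are JSON (text, full double precision) holding the format
#' version, the spec, the build seed and the parameter arrays.
#' `load_encoder()` refuses checkpoints with an unknown format version, and,
#' when `expect_spec` is given, refuses a mismatched architecture.
#'
#' @param enc Encoder handle.
#' @param path Checkpoint path (`.json`).
#' @param expect_spec Optional [encoder_spec()] the checkpoint must match.
#' @return `save_encoder()`: `path` invisibly; `load_encoder()`: an
#'   `encoder3d`.
#' @export
save_encoder <- function(enc, path) {
  stopifnot(inherits(enc, "encoder3d"))
  payload <- list(
    format = "fewshot3d-encoder", version = enc$version,
    spec = unclass(enc$spec), seed = enc$seed,
    params = lapply(enc$params, function(p) {
      list(dim = dim(p$W), W = as.numeric(p$W), b = as.numeric(p$b))
    }))
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path, expect_spec = NULL) {
  if (!file.exists(path)) config_error(sprintf("no checkpoint at %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "fewshot3d-encoder") || !identical(x$version, 1L)) {
    config_error(sprintf("unrecognized checkpoint format in %s", path))
  }
  spec <- encoder_spec(arch = x$spec$arch, channels = x$spec$channels,
                       embedding_dim = x$spec$embedding_dim,
                       input_shape = x$spec$input_shape)
  if (!is.null(expect_spec) && !identical(unclass(spec),
                                          unclass(expect_spec))) {
    config_error(sprintf("checkpoint %s does not match the expected spec",
                         path))
  }
  params <- lapply(x$params, function(p) {
    list(W = array(p$W, dim = p$dim), b = as.numeric(p$b))
  })
  structure(list(spec = spec, params = params, seed = as.integer(x$seed),
                 version = 1L),
            class = "encoder3d")
}

# --- Adam optimizer over nested parameter lists -----------------------------

adam_init <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (l in names(params)) {
    for (q in names(params[[l]])) {
      g <- grads[[l]][[q]]
      state$m[[l]][[q]] <- beta1 * state$m[[l]][[q]] + (1 - beta1) * g
      state$v[[l]][[q]] <- beta2 * state$v[[l]][[q]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[q]] / (1 - beta1^t)
      vhat <- state$v[[l]][[q]] / (1 - beta2^t)
      params[[l]][[q]] <- params[[l]][[q]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}
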