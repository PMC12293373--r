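#' GE2E loss configuration
#'
#' The generalized end-to-end loss scores each embedding against per-label
#' centroids by cosine similarity and penalizes
#' `-S(own label) + log sum_k exp(S(label k))`. The default configuration
#' implements that formula literally: unit scale, zero bias, centroids as
#' plain within-batch means. The refinements of the original
#' speaker-verification formulation — excluding the embedding itself from
#' its own-label centroid, and a learnable affine `w * cos + b` on the
#' similarity — are available as options, off by default.
#'
#' @param self_exclusion Exclude `f_ij` from the centroid used for its own
#'   similarity `S_ji,i` (requires at least 2 samples per label).
#' @param scale,bias Affine transform of the cosine: `w * cos + b`, `w > 0`.
#' @param scale_bias_learnable Update `scale`/`bias` during training.
#' @return An object of class `ge2e_config`.
#' @export
ge2e_config <- function(self_exclusion = FALSE, scale = 1, bias = 0,
                        scale_bias_learnable = FALSE) {
  if (scale <= 0) config_error("scale must be > 0")
  structure(list(self_exclusion = isTRUE(self_exclusion), scale = scale,
                 bias = bias,
                 scale_bias_learnable = isTRUE(scale_bias_learnable)),
            class = "ge2e_config")
}

#' Assemble an N x M x D embedding batch
#'
#' `f[i, j, ]` is the embedding of the j-th sample of the i-th label.
#'
#' @param embeddings Numeric array `(n_labels, m_per_label, embedding_dim)`.
#' @param label_ids Optional length-N label identifiers.
#' @return An object of class `embedding_batch`.
#' @export
embedding_batch <- function(embeddings, label_ids = NULL) {
  if (!is.array(embeddings) || length(dim(embeddings)) != 3L) {
    input_error("embeddings must be an N x M x D array")
  }
  if (!all(is.finite(embeddings))) input_error("embeddings must be finite")
  d <- dim(embeddings)
  norms <- sqrt(apply(embeddings^2, c(1, 2), sum))
  if (any(norms == 0)) {
    numeric_error("zero-vector embedding: cosine similarity undefined")
  }
  structure(list(embeddings = embeddings,
                 label_ids = label_ids %||% seq_len(d[1]) - 1L),
            class = "embedding_batch")
}

#' Per-label centroids of an embedding batch
#'
#' Centroid `C_k` is the arithmetic mean of label k's M embeddings. With
#' `self_exclusion`, the loss internally substitutes, for the own-label
#' similarity of `f_ij` only, the per-query variant that averages the other
#' M - 1 embeddings; the matrix returned here is always the plain mean.
#'
#' @param b An [embedding_batch()].
#' @param cfg A [ge2e_config()].
#' @return N x D numeric matrix.
#' @export
ge2e_centroids <- function(b, cfg = ge2e_config()) {
  stopifnot(inherits(b, "embedding_batch"))
  d <- dim(b$embeddings)
  if (cfg$self_exclusion && d[2] < 2L) {
    config_error("self_exclusion needs at least 2 samples per label")
  }
  apply(b$embeddings, c(1, 3), mean)
}

cos_sim <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    numeric_error("zero-norm vector in cosine similarity")
  }
  sum(u * v) / (nu * nv)
}

#' Similarity tensor S[i, j, k] = w * cos(f_ij, C_k) + b
#'
#' @param b An [embedding_batch()].
#' @param cents Centroid matrix from [ge2e_centroids()].
#' @param cfg A [ge2e_config()]; with `self_exclusion` the entry
#'   `S[i, j, i]` uses the centroid excluding `f_ij`.
#' @return N x M x N numeric array.
#' @export
ge2e_similarity <- function(b, cents, cfg = ge2e_config()) {
  stopifnot(inherits(b, "embedding_batch"))
  f <- b$embeddings
  d <- dim(f)
  N <- d[1]; M <- d[2]
  S <- array(NA_real_, c(N, M, N))
  for (i in seq_len(N)) {
    for (j in seq_len(M)) {
      u <- f[i, j, ]
      for (k in seq_len(N)) {
        ck <- if (cfg$self_exclusion && k == i) {
          (M * cents[i, ] - u) / (M - 1)
        } else {
          cents[k, ]
        }
        S[i, j, k] <- cfg$scale * cos_sim(u, ck) + cfg$bias
      }
    }
  }
  S
}

#' GE2E loss of an embedding batch
#'
#' Total loss `sum_ij [ -S_ji,i + log sum_k exp(S_ji,k) ]`, with the
#' log-sum-exp computed max-shifted for numerical stability. With a single
#' label (N = 1) every per-sample term collapses to exactly zero. When
#' `grad = TRUE` the analytic gradient with respect to the embeddings —
#' including the dependence of the centroids on the embeddings — is
#' returned alongside, plus gradients for the scale/bias parameters.
#'
#' @param b An [embedding_batch()].
#' @param cfg A [ge2e_config()].
#' @param reduction `"sum"` (default) or `"mean"` over the N*M samples.
#' @param grad Also compute gradients.
#' @return The scalar loss, or (with `grad`) a list
#'   `(loss, grad [N x M x D], gscale, gbias)`.
#' @export
ge2e_loss <- function(b, cfg = ge2e_config(), reduction = c("sum", "mean"),
                      grad = FALSE) {
  reduction <- match.arg(reduction)
  stopifnot(inherits(b, "embedding_batch"))
  f <- b$embeddings
  d <- dim(f)
  N <- d[1]; M <- d[2]; D <- d[3]
  cents <- ge2e_centroids(b, cfg)
  S <- ge2e_similarity(b, cents, cfg)

  loss <- 0
  P <- array(0, dim(S))          # softmax over k, per (i, j)
  for (i in seq_len(N)) {
    for (j in seq_len(M)) {
      s <- S[i, j, ]
      mx <- max(s)
      lse <- mx + log(sum(exp(s - mx)))
      loss <- loss + (-s[i] + lse)
      P[i, j, ] <- exp(s - lse)
    }
  }
  scl <- if (reduction == "mean") 1 / (N * M) else 1
  loss <- loss * scl
  if (!grad) return(loss)

  gf <- array(0, c(N, M, D))
  gc <- matrix(0, N, D)
  gscale <- 0
  gbias <- 0
  w <- cfg$scale
  cn <- sqrt(rowSums(cents^2))
  for (i in seq_len(N)) {
    for (j in seq_len(M)) {
      u <- f[i, j, ]
      nu <- sqrt(sum(u^2))
      for (k in seq_len(N)) {
        g <- (P[i, j, k] - as.numeric(k == i)) * scl
        if (g == 0) next
        excl <- cfg$self_exclusion && k == i
        ck <- if (excl) (M * cents[i, ] - u) / (M - 1) else cents[k, ]
        nc <- if (excl) sqrt(sum(ck^2)) else cn[k]
        cosv <- (S[i, j, k] - cfg$bias) / w
        gscale <- gscale + g * cosv
        gbias <- gbias + g
        # direct dependence through f_ij
        gf[i, j, ] <- gf[i, j, ] + g * w * (ck / (nu * nc) - cosv * u / nu^2)
        gck <- g * w * (u / (nu * nc) - cosv * ck / nc^2)
        if (excl) {
          # excluded centroid depends on the other M-1 embeddings of label i
          for (jj in seq_len(M)) {
            if (jj != j) gf[i, jj, ] <- gf[i, jj, ] + gck / (M - 1)
          }
        } else {
          gc[k, ] <- gc[k, ] + gck
        }
      }
    }
  }
  # plain centroids are means: spread their gradient over the M embeddings
  for (k in seq_len(N)) {
    for (j in seq_len(M)) gf[k, j, ] <- gf[k, j, ] + gc[k, ] / M
  }
  list(loss = loss, grad = gf, gscale = gscale, gbias = gbias)
}
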