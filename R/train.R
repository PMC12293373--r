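# Training loops: GE2E metric learning and supervised cross-entropy
# pre-training. Both are plain Adam loops over the hand-derived gradients;
# determinism follows from the seeded batch sampler and the single-threaded
# conv kernels.

grads_add <- function(a, b) {
  for (l in names(a)) for (q in names(a[[l]])) {
    a[[l]][[q]] <- a[[l]][[q]] + b[[l]][[q]]
  }
  a
}

check_conforming <- function(s, enc) {
  for (x in s$samples) {
    if (is.null(x$volume)) {
      data_error("training set has unmaterialized volumes; run materialize_volumes()")
    }
  }
  shp <- dim(s$samples[[1]]$volume$voxels)
  if (!identical(as.integer(shp), enc$spec$input_shape)) {
    input_error(sprintf("volumes are %s but the encoder expects %s",
                        paste(shp, collapse = "x"),
                        paste(enc$spec$input_shape, collapse = "x")))
  }
}

as_input <- function(v) {
  x <- v$voxels
  dim(x) <- c(dim(x), 1L)
  x
}

#' Train an encoder with the GE2E loss
#'
#' Each step draws M samples from each of N labels, embeds them, evaluates
#' the GE2E loss and its analytic gradient, backpropagates through the
#' encoder and takes one Adam step. The default batch composition for the
#' 2-way task is N = 2 labels x M = 4 samples (batch size 8).
#'
#' @param enc Encoder handle from [build_encoder()].
#' @param train A `sample_set` with volumes preprocessed to the encoder's
#'   input shape; every label must have at least `m_per_label` samples.
#' @param cfg A [ge2e_config()].
#' @param schedule List with `n_labels` (2), `m_per_label` (4), `steps`
#'   (300), `lr` (Adam step size, 3e-3), `seed`.
#' @param reduction Loss reduction, `"sum"` (default) or `"mean"`.
#' @param verbose Print the loss every 50 steps.
#' @return The trained `encoder3d`, with the per-step loss curve attached as
#'   attribute `"history"` (a data.frame of step and loss).
#' @export
train_ge2e <- function(enc, train, cfg = ge2e_config(),
                       schedule = list(), reduction = "sum",
                       verbose = FALSE) {
  sch <- utils::modifyList(
    list(n_labels = 2L, m_per_label = 4L, steps = 300L, lr = 3e-3, seed = 1L),
    schedule)
  check_conforming(train, enc)
  lab <- labels_of(train)
  classes <- sort(unique(lab))
  if (length(classes) < sch$n_labels) {
    data_error(sprintf("need %d labels but the training set has %d",
                       sch$n_labels, length(classes)))
  }
  idx_by_class <- lapply(classes, function(cl) which(lab == cl))
  short <- vapply(idx_by_class, length, integer(1)) < sch$m_per_label
  if (any(short)) {
    data_error(sprintf(
      "label %s has only %d samples; %d per label required",
      classes[which(short)[1]], length(idx_by_class[[which(short)[1]]]),
      sch$m_per_label))
  }
  D <- enc$spec$embedding_dim
  N <- sch$n_labels; M <- sch$m_per_label
  params <- enc$params
  state <- adam_init(params)
  curve <- numeric(sch$steps)
  with_seed(sch$seed, {
    for (step in seq_len(sch$steps)) {
      picks <- lapply(idx_by_class[seq_len(N)], function(ix) {
        ix[sample.int(length(ix), M)]
      })
      enc$params <- params
      emb <- array(0, c(N, M, D))
      caches <- vector("list", N * M)
      for (i in seq_len(N)) for (j in seq_len(M)) {
        fw <- enc_forward(enc, as_input(train$samples[[picks[[i]][j]]]$volume),
                          cache = TRUE)
        emb[i, j, ] <- fw$e
        caches[[(i - 1L) * M + j]] <- fw$cache
      }
      lg <- ge2e_loss(embedding_batch(emb), cfg, reduction = reduction,
                      grad = TRUE)
      curve[step] <- lg$loss
      total <- NULL
      for (i in seq_len(N)) for (j in seq_len(M)) {
        g <- enc_backward(enc, caches[[(i - 1L) * M + j]], lg$grad[i, j, ])
        total <- if (is.null(total)) g else grads_add(total, g)
      }
      upd <- adam_step(params, total, state, sch$lr)
      params <- upd$params
      state <- upd$state
      if (cfg$scale_bias_learnable) {
        cfg$scale <- max(cfg$scale - sch$lr * lg$gscale, 1e-3)
        cfg$bias <- cfg$bias - sch$lr * lg$gbias
      }
      if (verbose && step %% 50L == 0L) {
        message(sprintf("ge2e step %d: loss %.4f", step, lg$loss))
      }
    }
  })
  enc$params <- params
  attr(enc, "history") <- data.frame(step = seq_len(sch$steps), loss = curve)
  enc
}

#' Supervised cross-entropy training of an encoder plus linear head
#'
#' The baseline mechanism for producing pre-trained weights: a temporary
#' linear classification head on the embedding, trained with softmax
#' cross-entropy. Detach the head afterwards with [detach_head()] to obtain
#' the transferable encoder.
#'
#' @param clf A `classifier3d` from [attach_linear_head()].
#' @param train A conforming `sample_set` with both labels present.
#' @param schedule List with `batch_size` (8), `steps` (300), `lr` (3e-3),
#'   `seed`.
#' @param verbose Print the loss every 50 steps.
#' @return The trained `classifier3d` with attribute `"history"`.
#' @export
train_supervised <- function(clf, train, schedule = list(), verbose = FALSE) {
  stopifnot(inherits(clf, "classifier3d"))
  sch <- utils::modifyList(
    list(batch_size = 8L, steps = 300L, lr = 3e-3, seed = 1L), schedule)
  enc <- clf$encoder
  check_conforming(train, enc)
  lab <- labels_of(train)
  if (length(unique(lab)) < 2L) data_error("supervised training needs both labels")
  params <- enc$params
  params$head <- clf$head
  state <- adam_init(params)
  curve <- numeric(sch$steps)
  n <- length(train)
  with_seed(sch$seed, {
    for (step in seq_len(sch$steps)) {
      picks <- sample.int(n, min(sch$batch_size, n))
      B <- length(picks)
      enc$params <- params[setdiff(names(params), "head")]
      loss <- 0
      total <- NULL
      ghead <- list(W = params$head$W * 0, b = params$head$b * 0)
      for (ix in picks) {
        y <- lab[ix] + 1L
        fw <- enc_forward(enc, as_input(train$samples[[ix]]$volume),
                          cache = TRUE)
        z <- drop(crossprod(params$head$W, fw$e)) + params$head$b
        z <- z - max(z)
        p <- exp(z) / sum(exp(z))
        loss <- loss - log(p[y]) / B
        dz <- p / B
        dz[y] <- dz[y] - 1 / B
        ghead$W <- ghead$W + outer(fw$e, dz)
        ghead$b <- ghead$b + dz
        ge <- drop(params$head$W %*% dz)
        g <- enc_backward(enc, fw$cache, ge)
        total <- if (is.null(total)) g else grads_add(total, g)
      }
      total$head <- ghead
      curve[step] <- loss
      upd <- adam_step(params, total, state, sch$lr)
      params <- upd$params
      state <- upd$state
      if (verbose && step %% 50L == 0L) {
        message(sprintf("ce step %d: loss %.4f", step, loss))
      }
    }
  })
  enc$params <- params[setdiff(names(params), "head")]
  clf$encoder <- enc
  clf$head <- params$head
  attr(clf, "history") <- data.frame(step = seq_len(sch$steps), loss = curve)
  clf
}

#' Predict class scores with a trained classifier
#'
#' @param clf A trained `classifier3d`.
#' @param s A conforming `sample_set`.
#' @return data.frame with exam_id, true label, predicted label and the
#'   positive-class logit margin as score.
#' @export
predict_classifier <- function(clf, s) {
  check_conforming(s, clf$encoder)
  eb <- embed_batch(clf$encoder, s)
  logits <- eb$embeddings %*% clf$head$W +
    matrix(clf$head$b, nrow(eb$embeddings), clf$n_classes, byrow = TRUE)
  data.frame(exam_id = eb$exam_id, true = eb$label,
             pred = max.col(logits, ties.method = "first") - 1L,
             score = logits[, 2L] - logits[, 1L],
             stringsAsFactors = FALSE)
}
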