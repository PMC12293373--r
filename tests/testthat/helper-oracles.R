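# Independent reference implementations used to check the package's fast
# paths. These are written as literal, loop-by-loop transcriptions and must
# stay independent of the code they verify.

# GE2E loss via explicit triple loops: centroids as plain means, cosine by
# dot product over norms, per-sample term -S_own + log sum_k exp(S_k).
oracle_ge2e <- function(emb, scale = 1, bias = 0, self_exclusion = FALSE) {
  d <- dim(emb)
  N <- d[1]; M <- d[2]
  cents <- array(0, c(N, d[3]))
  for (i in seq_len(N)) {
    for (j in seq_len(M)) cents[i, ] <- cents[i, ] + emb[i, j, ] / M
  }
  total <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(M)) {
      s <- numeric(N)
      for (k in seq_len(N)) {
        ck <- cents[k, ]
        if (self_exclusion && k == i) {
          ck <- (cents[i, ] * M - emb[i, j, ]) / (M - 1)
        }
        u <- emb[i, j, ]
        s[k] <- scale * sum(u * ck) / (sqrt(sum(u^2)) * sqrt(sum(ck^2))) +
          bias
      }
      total <- total + (-s[i] + log(sum(exp(s))))
    }
  }
  total
}

# ROC-AUC by brute-force pair counting with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# nearest-prototype by direct comparison, tie toward label 0
oracle_nearest <- function(q, p0, p1) {
  d0 <- sqrt(sum((q - p0)^2))
  d1 <- sqrt(sum((q - p1)^2))
  if (d1 < d0) 1L else 0L
}
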