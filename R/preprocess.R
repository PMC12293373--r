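#' Deterministic volume preprocessing specification
#'
#' Maps arbitrary input volumes onto the fixed shape and intensity scale the
#' encoder expects. Shape is adjusted per axis either by symmetric zero
#' padding / central cropping (`center_crop_pad`) or by separable linear
#' resampling (`linear_resample`). Intensities are then normalized per
#' volume: `zscore` (mean 0, population SD 1; a constant volume maps to all
#' zeros), `minmax` (to `[0, 1]`; constant maps to zeros) or `none`.
#'
#' @param target_shape Integer triple `(depth, height, width)`.
#' @param normalization One of `"zscore"`, `"minmax"`, `"none"`.
#' @param depth_policy One of `"center_crop_pad"`, `"linear_resample"`
#'   (applied to all three axes).
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(target_shape = c(16L, 32L, 32L),
                            normalization = c("zscore", "minmax", "none"),
                            depth_policy = c("center_crop_pad",
                                             "linear_resample")) {
  normalization <- match.arg(normalization)
  depth_policy <- match.arg(depth_policy)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L)) {
    config_error("target_shape must be three integers >= 1")
  }
  structure(list(target_shape = target_shape, normalization = normalization,
                 depth_policy = depth_policy), class = "preprocess_spec")
}

# symmetric crop-or-pad of one axis to length `target`; pad with zeros,
# extra voxel (odd difference) goes to the trailing side
crop_pad_axis <- function(a, axis, target) {
  n <- dim(a)[axis]
  if (n == target) return(a)
  idx_all <- lapply(dim(a), seq_len)
  if (n > target) {
    start <- (n - target) %/% 2L
    idx_all[[axis]] <- seq.int(start + 1L, start + target)
    do.call(`[`, c(list(a), idx_all, list(drop = FALSE)))
  } else {
    newdim <- dim(a)
    newdim[axis] <- target
    out <- array(0, dim = newdim)
    start <- (target - n) %/% 2L
    idx_all[[axis]] <- seq.int(start + 1L, start + n)
    out <- do.call(`[<-`, c(list(out), idx_all, list(value = a)))
    out
  }
}

# separable linear resampling of one axis, endpoints aligned
resample_axis <- function(a, axis, target) {
  n <- dim(a)[axis]
  if (n == target) return(a)
  xout <- if (target == 1L) (n + 1) / 2 else seq(1, n, length.out = target)
  newdim <- dim(a)
  newdim[axis] <- target
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = n)
  mi <- apply(m, 2L, function(col) {
    if (n == 1L) rep(col, length(xout))
    else stats::approx(seq_len(n), col, xout = xout)$y
  })
  mi <- matrix(mi, nrow = target)
  aperm(array(mi, dim = newdim[perm]), order(perm))
}

#' Preprocess a volume to a fixed shape and intensity scale
#'
#' Deterministic; idempotent on input that already conforms to the spec
#' (up to floating-point tolerance for `zscore`).
#'
#' @param v A [volume()].
#' @param spec A [preprocess_spec()].
#' @return A `volume` with `dim(voxels) == spec$target_shape`.
#' @export
preprocess <- function(v, spec) {
  stopifnot(inherits(v, "volume"), inherits(spec, "preprocess_spec"))
  a <- v$voxels
  fit <- switch(spec$depth_policy,
                center_crop_pad = crop_pad_axis,
                linear_resample = resample_axis)
  for (axis in 1:3) a <- fit(a, axis, spec$target_shape[axis])
  a <- switch(spec$normalization,
    zscore = {
      mu <- mean(a)
      s <- sqrt(mean((a - mu)^2))   # population SD
      if (s < .Machine$double.eps) array(0, dim(a)) else (a - mu) / s
    },
    minmax = {
      r <- range(a)
      if (diff(r) < .Machine$double.eps) array(0, dim(a))
      else (a - r[1]) / diff(r)
    },
    none = a)
  volume(a, exam_id = v$exam_id, patient_id = v$patient_id,
         series_label = v$series_label)
}
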