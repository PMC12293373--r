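#' Construct a 3D volume with exam/patient identity
#'
#' A `volume` holds one 3D grayscale series of one exam. The axis convention
#' throughout the package is `(depth, height, width)` with depth the slice
#' axis, matching per-exam array stacks whose first axis indexes slices.
#'
#' @param voxels 3D numeric array `(depth, height, width)`; a 2D matrix is
#'   promoted to a single-slice volume.
#' @param exam_id,patient_id Identifier strings.
#' @param series_label Free-text series tag (e.g. `"sagittal"`).
#' @return An object of class `volume`.
#' @export
volume <- function(voxels, exam_id, patient_id, series_label = "unknown") {
  if (is.matrix(voxels)) dim(voxels) <- c(1L, dim(voxels))
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    format_error("voxels must be a 3D array (depth, height, width)")
  }
  if (!is.numeric(voxels) || !all(is.finite(voxels))) {
    format_error("voxels must be numeric and finite")
  }
  structure(
    list(voxels = voxels, exam_id = as.character(exam_id),
         patient_id = as.character(patient_id),
         series_label = as.character(series_label)),
    class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume %s (patient %s, %s): %d x %d x %d>\n",
              x$exam_id, x$patient_id, x$series_label, d[1], d[2], d[3]))
  invisible(x)
}

labeled_sample <- function(volume = NULL, label, exam_id = NULL,
                           patient_id = NULL, path = NULL, format = NULL,
                           meta = list()) {
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) data_error("label must be 0 or 1")
  if (!is.null(volume)) {
    exam_id <- volume$exam_id
    patient_id <- volume$patient_id
  }
  structure(
    list(volume = volume, label = label, exam_id = as.character(exam_id),
         patient_id = as.character(patient_id), path = path, format = format,
         meta = meta),
    class = "labeled_sample")
}

#' Construct a labeled sample set
#'
#' Ordered collection of binary-labeled volumes grouped by patient; the unit
#' that training batches and few-shot episodes are drawn from. Exam ids must
#' be unique; patients may contribute several exams, all carrying one label.
#'
#' @param samples List of internal `labeled_sample` objects.
#' @param name Set name (used in messages and filenames).
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(samples, name = "dataset") {
  ids <- vapply(samples, `[[`, character(1), "exam_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    data_error(sprintf("duplicate exam_id: %s", paste(unique(dup),
                                                      collapse = ", ")))
  }
  structure(list(samples = samples, name = name), class = "sample_set")
}

#' @export
length.sample_set <- function(x) length(x$samples)

#' @export
print.sample_set <- function(x, ...) {
  lab <- labels_of(x)
  cat(sprintf("<sample_set '%s': %d samples (%d neg / %d pos), %d patients>\n",
              x$name, length(x), sum(lab == 0L), sum(lab == 1L),
              length(unique(patient_ids(x)))))
  invisible(x)
}

#' Accessors for sample sets
#'
#' @param s A `sample_set`.
#' @return Integer labels, or character exam/patient ids, one per sample in
#'   the set's order.
#' @export
labels_of <- function(s) vapply(s$samples, `[[`, integer(1), "label")

#' @rdname labels_of
#' @export
exam_ids <- function(s) vapply(s$samples, `[[`, character(1), "exam_id")

#' @rdname labels_of
#' @export
patient_ids <- function(s) vapply(s$samples, `[[`, character(1), "patient_id")

#' Read a label manifest into a sample set
#'
#' The manifest is a header-ed UTF-8 CSV with one row per exam, carrying the
#' exam id, the patient id, the binary label (0 = intact/negative,
#' 1 = injured/positive) and the path of the volume file. Volumes are not
#' loaded here; [materialize_volumes()] (or any consumer) loads them on
#' demand via [load_volume()].
#'
#' @param path Manifest CSV path.
#' @param schema Named character vector mapping the canonical column roles
#'   `exam_id`, `patient_id`, `label`, `path` to the CSV's column names.
#' @param name Name for the resulting set.
#' @return A `sample_set` with lazily loadable volumes (`volume = NULL`,
#'   `path`/`format` recorded per sample). Row order is preserved.
#' @export
read_manifest <- function(path,
                          schema = c(exam_id = "exam_id",
                                     patient_id = "patient_id",
                                     label = "label", path = "path"),
                          name = basename(path)) {
  if (!file.exists(path)) config_error(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  needed <- c("exam_id", "patient_id", "label", "path")
  schema <- schema[needed]
  missing <- needed[!(schema %in% names(df)) | is.na(schema)]
  if (length(missing)) {
    config_error(sprintf("manifest %s lacks column(s) for: %s", path,
                         paste(missing, collapse = ", ")))
  }
  lab_raw <- df[[schema[["label"]]]]
  bad <- which(!lab_raw %in% c("0", "1"))
  if (length(bad)) {
    data_error(sprintf("label '%s' on row %d of %s is not in {0,1}",
                       lab_raw[bad[1]], bad[1], path))
  }
  samples <- lapply(seq_len(nrow(df)), function(i) {
    labeled_sample(label = as.integer(lab_raw[i]),
                   exam_id = df[[schema[["exam_id"]]]][i],
                   patient_id = df[[schema[["patient_id"]]]][i],
                   path = df[[schema[["path"]]]][i])
  })
  sample_set(samples, name = name)
}

#' Write a sample set's manifest
#'
#' @param s A `sample_set` whose samples carry a `path`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(s, path) {
  df <- data.frame(
    exam_id = exam_ids(s), patient_id = patient_ids(s),
    label = labels_of(s),
    path = vapply(s$samples, function(x) x$path %||% "", character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Load one 3D volume from disk
#'
#' Supported formats: NIfTI-1 (`.nii` / `.nii.gz`, via RNifti) and single
#' NumPy arrays (`.npy`, the per-exam-series stack dialect). The array is
#' returned unmodified with axis order `(slice, row, column)`; a 2D array is
#' promoted to depth 1. Arrays with more than 3 dimensions are rejected.
#'
#' @param path Volume file.
#' @param format `"auto"` (by extension), `"nifti"` or `"npy"`.
#' @param exam_id,patient_id,series_label Identity attached to the volume.
#' @return A [volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "npy"),
                        exam_id = basename(path), patient_id = "unknown",
                        series_label = "unknown") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.npy$", path)) "npy" else "nifti"
  }
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  arr <- switch(format,
    npy = read_npy(path),
    nifti = {
      img <- RNifti::readNifti(path)
      arr <- as.array(img)
      attributes(arr) <- list(dim = dim(arr))
      arr
    })
  if (is.null(dim(arr))) dim(arr) <- c(1L, 1L, length(arr))
  nd <- length(dim(arr))
  if (nd > 3L) {
    format_error(sprintf("%s holds a %d-dimensional array; at most 3 allowed",
                         path, nd))
  }
  if (nd == 2L) dim(arr) <- c(1L, dim(arr))
  if (!is.numeric(arr)) format_error(sprintf("non-numeric payload in %s", path))
  volume(arr, exam_id = exam_id, patient_id = patient_id,
         series_label = series_label)
}

#' Load (and optionally preprocess) all volumes of a lazy sample set
#'
#' @param s A `sample_set` from [read_manifest()].
#' @param spec Optional [preprocess_spec()] applied to each volume.
#' @return The same set with `volume` fields filled in.
#' @export
materialize_volumes <- function(s, spec = NULL) {
  s$samples <- lapply(s$samples, function(x) {
    if (is.null(x$volume)) {
      x$volume <- load_volume(x$path, format = x$format %||% "auto",
                              exam_id = x$exam_id, patient_id = x$patient_id)
    }
    if (!is.null(spec)) x$volume <- preprocess(x$volume, spec)
    x
  })
  s
}

# subset helper used by episodes/splits (keeps order of `idx`)
subset_samples <- function(s, idx, name = s$name) {
  sample_set(s$samples[idx], name = name)
}
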