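# Small fixtures built in code: tiny encoder specs and pocket-sized
# synthetic datasets that keep unit tests fast.

tiny_spec <- function(input_shape = c(8L, 12L, 12L), embedding_dim = 8L,
                      arch = "tiny3d") {
  encoder_spec(arch = arch, channels = 4L, embedding_dim = embedding_dim,
               input_shape = input_shape)
}

tiny_dataset <- function(n_patients = 12L, lesion_contrast = 5,
                         lesion_kind = "ellipsoid_A", seed = 1L,
                         exams_per_patient = 1L,
                         volume_shape = c(8L, 12L, 12L)) {
  simulate_dataset(synthetic_config(
    n_patients = n_patients, exams_per_patient = exams_per_patient,
    volume_shape = volume_shape, lesion_contrast = lesion_contrast,
    lesion_radius_voxels = 2.5, lesion_kind = lesion_kind, seed = seed))
}

# z-score every volume in place (shape already conforms for tiny_dataset)
zscore_set <- function(s, shape = dim(s$samples[[1]]$volume$voxels)) {
  sp <- preprocess_spec(target_shape = shape, normalization = "zscore")
  s$samples <- lapply(s$samples, function(x) {
    x$volume <- preprocess(x$volume, sp)
    x
  })
  s
}

write_csv_manifest <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
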