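#' Read a NumPy `.npy` array file
#'
#' Minimal reader for the NumPy binary format (versions 1.0/2.0), covering
#' the dialect used for per-exam MRI volume stacks: little-endian float or
#' integer scalars, C or Fortran order, any number of dimensions. Values are
#' returned as a plain R array (double storage) with the original shape, so
#' an array saved from `numpy` with shape `(d, h, w)` comes back with
#' `dim == c(d, h, w)` and `a[i, j, k]` equal to `a[i-1, j-1, k-1]` in
#' Python.
#'
#' @param path Path to a `.npy` file.
#' @return A numeric array (or vector for 1-d input).
#' @export
read_npy <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (length(magic) < 6L || !identical(rawToChar(magic[2:6]), "NUMPY") ||
      magic[1] != as.raw(0x93)) {
    format_error(sprintf("not a .npy file (bad magic): %s", path))
  }
  ver <- readBin(con, "integer", n = 2L, size = 1L, signed = FALSE)
  hlen <- if (ver[1] == 1L) {
    readBin(con, "integer", n = 1L, size = 2L, endian = "little",
            signed = FALSE)
  } else {
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", n = hlen))

  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_str <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s|,$", "", shape_str), ",")[[1]])
  if (length(shape) == 0L || anyNA(shape)) shape <- integer(0)
  n <- if (length(shape)) prod(shape) else 1L

  typ <- substr(descr, nchar(descr) - 1L, nchar(descr))
  endian <- if (substr(descr, 1L, 1L) == ">") "big" else "little"
  vals <- switch(typ,
    "f8" = readBin(con, "double", n = n, size = 8L, endian = endian),
    "f4" = readBin(con, "double", n = n, size = 4L, endian = endian),
    "i8" = readBin(con, "double", n = n, size = 8L, endian = endian),
    "i4" = as.double(readBin(con, "integer", n = n, size = 4L,
                             endian = endian)),
    "i2" = as.double(readBin(con, "integer", n = n, size = 2L,
                             endian = endian)),
    "i1" = as.double(readBin(con, "integer", n = n, size = 1L)),
    "u1" = as.double(readBin(con, "integer", n = n, size = 1L,
                             signed = FALSE)),
    format_error(sprintf("unsupported .npy dtype '%s' in %s", descr, path))
  )
  if (length(vals) != n) {
    format_error(sprintf("truncated .npy payload in %s", path))
  }
  if (length(shape) <= 1L) return(vals)
  if (fortran) {
    array(vals, dim = shape)
  } else {
    # C-order payload: fill the reversed shape column-major, then transpose.
    aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
  }
}

#' Write a numeric array as a NumPy `.npy` file
#'
#' Writes version 1.0 files with dtype `<f8` in C order, readable by
#' `numpy.load` with shape equal to `dim(x)`.
#'
#' @param x Numeric vector or array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  if (!is.numeric(x)) format_error("write_npy() needs a numeric array")
  shape <- dim(x) %||% length(x)
  shape_py <- if (length(shape) == 1L) {
    sprintf("(%d,)", shape)
  } else {
    sprintf("(%s)", paste(shape, collapse = ", "))
  }
  header <- sprintf(
    "{'descr': '<f8', 'fortran_order': False, 'shape': %s, }", shape_py)
  # total header (magic 6 + version 2 + len 2 + dict) padded to 64 bytes
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  vals <- if (length(shape) > 1L) {
    as.vector(aperm(x, rev(seq_along(shape))))
  } else {
    as.vector(x)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(nchar(header), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.double(vals), con, size = 8L, endian = "little")
  invisible(path)
}
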