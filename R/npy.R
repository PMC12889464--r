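# Minimal NPY v1.0 reader/writer for the phy-style columnar outputs.
# Supports little-endian int32/int64/float64, 1-D and 2-D C-order arrays,
# which is all the sorted-output layout needs.  int64 values are held in R
# doubles (exact below 2^53, far beyond any sample index used here).

npy_descr <- function(dtype) {
  switch(dtype,
         int32 = "<i4", int64 = "<i8", float64 = "<f8",
         stop("unsupported npy dtype: ", dtype))
}

#' Write a numeric vector or matrix as an NPY file
#'
#' @param x numeric vector or matrix (matrices are written C-order).
#' @param path output path.
#' @param dtype one of "int32", "int64", "float64".
#' @return `path`, invisibly.
#' @keywords internal
npy_write <- function(x, path, dtype = "float64") {
  shape <- if (is.array(x)) {
    d <- dim(x)
    if (length(d) == 1L) sprintf("(%d,)", d) else
      paste0("(", paste(d, collapse = ", "), ")")
  } else {
    sprintf("(%d,)", length(x))
  }
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    npy_descr(dtype), shape)
  # pad so magic(6) + version(2) + hlen(2) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  # C-order serialization: reverse dims, permute back
  v <- if (is.array(x) && length(dim(x)) > 1L) {
    as.vector(aperm(x, rev(seq_along(dim(x)))))
  } else {
    as.vector(x)
  }
  if (dtype == "int32") {
    writeBin(as.integer(v), con, size = 4L, endian = "little")
  } else if (dtype == "int64") {
    # emit each value as low/high 32-bit words (values are nonneg indices
    # or exact integers well below 2^53)
    v <- as.numeric(v)
    if (any(v < -2^52 | v >= 2^52)) stop("int64 value out of exact range")
    neg <- v < 0
    v64 <- ifelse(neg, v + 2^64, v)
    hi <- floor(v64 / 2^32)
    lo <- v64 - hi * 2^32
    words <- as.vector(rbind(bit32_to_int(lo), bit32_to_int(hi)))
    writeBin(words, con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 8L, endian = "little")
  }
  invisible(path)
}

# reinterpret a [0, 2^32) double as a signed 32-bit integer
bit32_to_int <- function(u) {
  as.integer(ifelse(u >= 2^31, u - 2^32, u))
}

#' Read an NPY file written in the supported subset
#'
#' @param path NPY file path.
#' @return numeric vector (1-D) or matrix (2-D).
#' @keywords internal
npy_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  if (as.integer(magic[7]) != 1L)
    stop("unsupported NPY version in ", path)
  hlen <- readBin(con, "integer", size = 2L, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  if (fortran) stop("fortran-order NPY not supported: ", path)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  n <- prod(pmax(shape, 0L))
  if (length(shape) == 0L || all(is.na(shape))) shape <- integer(0)
  v <- switch(descr,
    "<i4" = as.numeric(readBin(con, "integer", n = n, size = 4L, endian = "little")),
    "<i8" = {
      words <- readBin(con, "integer", n = 2L * n, size = 4L, endian = "little")
      lo <- words[seq(1L, length.out = n, by = 2L)]
      hi <- words[seq(2L, length.out = n, by = 2L)]
      lo_u <- ifelse(lo < 0, lo + 2^32, lo)
      val <- hi * 2^32 + lo_u
      ifelse(val >= 2^63, val - 2^64, val)
    },
    "<f8" = readBin(con, "numeric", n = n, size = 8L, endian = "little"),
    stop("unsupported NPY dtype '", descr, "' in ", path))
  if (length(shape) <= 1L) {
    v
  } else {
    # data are C-order: fill with reversed dims, permute back
    aperm(array(v, dim = rev(shape)), rev(seq_along(shape)))
  }
}
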