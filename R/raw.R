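#' Raw extracellular recording
#'
#' Container for a samples x channels block of signed 16-bit samples at a
#' stated sampling rate, tied to a probe geometry.  `gain` converts integer
#' counts to microvolts (uV = counts * gain).
#'
#' @param data integer matrix, n_samples x n_channels, int16 range.
#' @param fs sampling rate in Hz.
#' @param gain uV per count.
#' @param geometry a [probe_geometry()] with matching channel count.
#' @return An object of class `raw_recording` (list with fields `data`,
#'   `fs`, `gain`, `geometry`).
#' @export
raw_recording <- function(data, fs = 30000, gain = 1, geometry) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (ncol(data) != n_channels(geometry))
    stop(sprintf("data has %d channels but geometry has %d",
                 ncol(data), n_channels(geometry)))
  if (any(abs(data) > 32767)) stop("samples exceed int16 range")
  storage.mode(data) <- "integer"
  structure(list(data = data, fs = fs, gain = gain, geometry = geometry),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "Raw recording: %.2f s (%d samples) x %d channels @ %g Hz, gain %.4g uV/count\n",
    nrow(x$data) / x$fs, nrow(x$data), ncol(x$data), x$fs, x$gain))
  invisible(x)
}

#' Recording as a microvolt matrix
#' @param rec a [raw_recording()].
#' @return double matrix in uV.
#' @export
as_uv <- function(rec) {
  rec$data * rec$gain
}

parse_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, function(p) trimws(p[1]), "")
  vals <- vapply(kv, function(p) trimws(p[2]), "")
  stats::setNames(as.list(vals), keys)
}

meta_num <- function(meta, key, path) {
  if (is.null(meta[[key]]))
    stop(sprintf("meta file '%s' is missing required key '%s'", path, key))
  v <- suppressWarnings(as.numeric(meta[[key]]))
  if (is.na(v)) stop(sprintf("meta key '%s' is not numeric: '%s'", key, meta[[key]]))
  v
}

#' Read a raw binary recording
#'
#' Reads a frame-interleaved (sample-major) little-endian int16 binary with
#' a flat `key=value` metadata sidecar and a probe geometry table.  The
#' meta file must declare `imSampRate` (Hz), `nSavedChans` and
#' `gain_uV_per_count`.
#'
#' @param binary_path path to the `.bin` file.
#' @param meta_path path to the `.meta` sidecar.
#' @param geometry_path path to the `probe.tsv` geometry table.
#' @return A [raw_recording()].
#' @export
read_raw <- function(binary_path, meta_path, geometry_path) {
  meta <- parse_meta(meta_path)
  fs <- meta_num(meta, "imSampRate", meta_path)
  nch <- as.integer(meta_num(meta, "nSavedChans", meta_path))
  gain <- meta_num(meta, "gain_uV_per_count", meta_path)
  geometry <- read_probe(geometry_path)
  if (n_channels(geometry) != nch)
    stop(sprintf("meta declares %d channels but geometry has %d",
                 nch, n_channels(geometry)))
  nbytes <- file.size(binary_path)
  frame_bytes <- 2L * nch
  if (nbytes %% frame_bytes != 0)
    stop(sprintf(
      "binary size %d bytes is not a multiple of %d (2 bytes x %d channels); nearest frame counts need %d or %d bytes",
      nbytes, frame_bytes, nch,
      (nbytes %/% frame_bytes) * frame_bytes,
      (nbytes %/% frame_bytes + 1) * frame_bytes))
  n_samples <- nbytes %/% frame_bytes
  con <- file(binary_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n_samples * nch, size = 2L,
               signed = TRUE, endian = "little")
  data <- matrix(v, nrow = n_samples, ncol = nch, byrow = TRUE)
  raw_recording(data, fs = fs, gain = gain, geometry = geometry)
}

#' Write a raw binary recording
#'
#' Inverse of [read_raw()]: frame-interleaved little-endian int16 plus the
#' `key=value` meta sidecar and probe table.  Round-trips bit-identically.
#'
#' @param rec a [raw_recording()].
#' @param binary_path,meta_path,geometry_path output paths.
#' @return `binary_path`, invisibly.
#' @export
write_raw <- function(rec, binary_path, meta_path, geometry_path) {
  stopifnot(inherits(rec, "raw_recording"))
  con <- file(binary_path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(rec$data)), con, size = 2L, endian = "little")
  writeLines(c(
    sprintf("imSampRate=%.10g", rec$fs),
    sprintf("nSavedChans=%d", ncol(rec$data)),
    sprintf("gain_uV_per_count=%.10g", rec$gain),
    sprintf("fileSizeBytes=%.0f", 2 * length(rec$data))
  ), meta_path)
  write_probe(rec$geometry, geometry_path)
  invisible(binary_path)
}
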