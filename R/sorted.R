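#' Sorted spike output
#'
#' Columnar container for the events emitted by the sorter: spike times
#' (1-based sample indices inside R; written to disk 0-based), the matched
#' template and assigned cluster per spike, the matching-pursuit amplitude,
#' and the localized probe position in um.
#'
#' @param times numeric vector of spike times in samples (nondecreasing).
#' @param clusters,templates integer ids per spike (1-based in R).
#' @param amplitudes numeric amplitude per spike.
#' @param positions n x 2 matrix of (x, y) um per spike.
#' @param fs sampling rate in Hz.
#' @param n_clusters total number of clusters in the bank (defaults to the
#'   max observed id).
#' @param skips optional data.frame of skipped sample spans from the
#'   streaming engine (columns `start`, `end`).
#' @return An object of class `sorted_output`.
#' @export
sorted_output <- function(times, clusters, templates, amplitudes, positions,
                          fs = 30000, n_clusters = NULL, skips = NULL) {
  n <- length(times)
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (n == 0L) positions <- matrix(numeric(0), ncol = 2)
  if (length(clusters) != n || length(templates) != n ||
      length(amplitudes) != n || nrow(positions) != n)
    stop("all sorted-output fields must have one row per spike")
  if (n > 1L && any(diff(times) < 0)) stop("spike times must be nondecreasing")
  structure(list(
    times = as.numeric(times),
    clusters = as.integer(clusters),
    templates = as.integer(templates),
    amplitudes = as.numeric(amplitudes),
    positions = positions,
    fs = fs,
    n_clusters = if (is.null(n_clusters)) {
      if (n) max(as.integer(clusters)) else 0L
    } else as.integer(n_clusters),
    skips = skips
  ), class = "sorted_output")
}

#' @export
print.sorted_output <- function(x, ...) {
  cat(sprintf("Sorted output: %d spikes, %d clusters @ %g Hz\n",
              length(x$times), x$n_clusters, x$fs))
  if (!is.null(x$skips) && nrow(x$skips))
    cat(sprintf("  %d skipped spans (%.0f samples total)\n", nrow(x$skips),
                sum(x$skips$end - x$skips$start)))
  invisible(x)
}

#' Per-cluster spike trains
#' @param sorted a [sorted_output()].
#' @return list of numeric spike-time vectors, one per cluster id 1..n_clusters.
#' @export
cluster_trains <- function(sorted) {
  lapply(seq_len(sorted$n_clusters), function(k)
    sorted$times[sorted$clusters == k])
}

#' Write sorted output in the phy-style layout
#'
#' One NPY file per field (`spike_times.npy` int64 0-based,
#' `spike_clusters.npy`/`spike_templates.npy` int32 0-based,
#' `amplitudes.npy` float64, `spike_positions.npy` n x 2 float64) plus a
#' `manifest.json` with `n_spikes`, `n_clusters`, `fs` and any skip spans.
#'
#' @param output a [sorted_output()].
#' @param dir_path output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_sorted <- function(output, dir_path) {
  stopifnot(inherits(output, "sorted_output"))
  if (!dir.exists(dir_path))
    if (!dir.create(dir_path, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", dir_path)
  npy_write(output$times - 1, file.path(dir_path, "spike_times.npy"), "int64")
  npy_write(output$clusters - 1L, file.path(dir_path, "spike_clusters.npy"), "int32")
  npy_write(output$templates - 1L, file.path(dir_path, "spike_templates.npy"), "int32")
  npy_write(output$amplitudes, file.path(dir_path, "amplitudes.npy"), "float64")
  npy_write(output$positions, file.path(dir_path, "spike_positions.npy"), "float64")
  manifest <- list(
    n_spikes = length(output$times),
    n_clusters = output$n_clusters,
    fs = output$fs,
    skips = if (is.null(output$skips)) list() else output$skips
  )
  jsonlite::write_json(manifest, file.path(dir_path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read sorted output written by [write_sorted()]
#' @param dir_path directory containing the phy-style arrays.
#' @return A [sorted_output()].
#' @export
read_sorted <- function(dir_path) {
  need <- c("spike_times.npy", "spike_clusters.npy", "spike_templates.npy",
            "amplitudes.npy", "spike_positions.npy", "manifest.json")
  missing <- need[!file.exists(file.path(dir_path, need))]
  if (length(missing))
    stop("sorted directory is missing: ", paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(dir_path, "manifest.json"),
                                  simplifyVector = TRUE)
  skips <- manifest$skips
  if (is.null(skips) || (is.list(skips) && !length(skips))) skips <- NULL
  sorted_output(
    times = npy_read(file.path(dir_path, "spike_times.npy")) + 1,
    clusters = npy_read(file.path(dir_path, "spike_clusters.npy")) + 1L,
    templates = npy_read(file.path(dir_path, "spike_templates.npy")) + 1L,
    amplitudes = npy_read(file.path(dir_path, "amplitudes.npy")),
    positions = {
      p <- npy_read(file.path(dir_path, "spike_positions.npy"))
      if (!is.matrix(p)) p <- matrix(p, ncol = 2)
      p
    },
    fs = manifest$fs,
    n_clusters = manifest$n_clusters,
    skips = skips
  )
}
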