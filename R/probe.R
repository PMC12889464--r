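#' Probe geometry
#'
#' A probe geometry ties each recording channel to a physical position on
#' the probe shank.  Channel indices are 0-based (acquisition convention)
#' and must be contiguous; positions are in micrometres.
#'
#' @param channel integer vector of channel indices, `0:(n-1)` in any order.
#' @param x,y numeric channel positions in um.
#' @return An object of class `probe_geometry`: a data.frame with columns
#'   `channel`, `x`, `y` (sorted by channel) and attribute `n_channels`.
#' @examples
#' geom <- probe_geometry(0:3, x = rep(0, 4), y = seq(0, 60, by = 20))
#' @export
probe_geometry <- function(channel, x, y) {
  channel <- as.integer(channel)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(channel)
  if (n < 1L) stop("probe geometry needs at least one channel")
  if (length(x) != n || length(y) != n)
    stop("channel, x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("channel positions must be finite")
  if (anyDuplicated(channel) || !setequal(channel, 0:(n - 1L)))
    stop("channel indices must be unique and contiguous from 0")
  ord <- order(channel)
  g <- data.frame(channel = channel[ord], x = x[ord], y = y[ord])
  attr(g, "n_channels") <- n
  class(g) <- c("probe_geometry", "data.frame")
  g
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("Probe geometry: %d channels, x span %.0f um, y span %.0f um\n",
              n_channels(x), diff(range(x$x)), diff(range(x$y))))
  invisible(x)
}

#' Number of channels of a geometry or recording
#' @param x a `probe_geometry` or `raw_recording`.
#' @return integer channel count.
#' @export
n_channels <- function(x) UseMethod("n_channels")

#' @export
n_channels.probe_geometry <- function(x) attr(x, "n_channels")

#' @export
n_channels.raw_recording <- function(x) ncol(x$data)

#' Pairwise channel distances (um)
#' @param geometry a [probe_geometry()].
#' @return n x n matrix of Euclidean distances.
#' @keywords internal
channel_distances <- function(geometry) {
  as.matrix(stats::dist(cbind(geometry$x, geometry$y)))
}

#' Read / write a probe geometry table
#'
#' The on-disk format is a 3-column tab-separated table with a header line
#' `channel<TAB>x<TAB>y`.
#'
#' @param path file path (`probe.tsv`).
#' @return `read_probe` returns a [probe_geometry()].
#' @export
read_probe <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("channel", "x", "y")
  if (!all(need %in% names(tab)))
    stop("probe table must have header columns channel, x, y; got: ",
         paste(names(tab), collapse = ", "))
  probe_geometry(tab$channel, tab$x, tab$y)
}

#' @rdname read_probe
#' @param geometry a [probe_geometry()] to write.
#' @export
write_probe <- function(geometry, path) {
  utils::write.table(as.data.frame(geometry)[, c("channel", "x", "y")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
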