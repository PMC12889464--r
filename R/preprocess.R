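#' Online preprocessing specification
#'
#' Parameters of the five-step batch preprocessing chain: (1) per-channel
#' mean subtraction, (2) common median referencing across channels, (3)
#' zero-phase FFT high-pass at `highpass_hz`, (4) spatial whitening, (5)
#' drift correction.  The high-pass transition band is a raised cosine over
#' `highpass_hz` +/- `transition_hz`.
#'
#' @param fs sampling rate in Hz.
#' @param n_channels channel count.
#' @param highpass_hz high-pass cutoff (default 300).
#' @param transition_hz half-width of the raised-cosine transition (75).
#' @param whitening_matrix n x n spatial whitening matrix (default identity).
#' @param drift_matrix n x n drift-correction matrix (default identity).
#' @param pad_samples reflection padding applied before the FFT filter.
#' @return An object of class `preproc_spec`.
#' @export
preproc_spec <- function(fs, n_channels, highpass_hz = 300, transition_hz = 75,
                         whitening_matrix = NULL, drift_matrix = NULL,
                         pad_samples = 512L) {
  if (is.null(whitening_matrix)) whitening_matrix <- diag(n_channels)
  if (is.null(drift_matrix)) drift_matrix <- diag(n_channels)
  for (m in list(whitening_matrix, drift_matrix)) {
    if (!is.matrix(m) || nrow(m) != n_channels || ncol(m) != n_channels)
      stop("whitening and drift matrices must be n_channels x n_channels")
    if (!all(is.finite(m))) stop("whitening/drift matrices must be finite")
  }
  structure(list(fs = fs, n_channels = as.integer(n_channels),
                 highpass_hz = highpass_hz, transition_hz = transition_hz,
                 whitening_matrix = whitening_matrix,
                 drift_matrix = drift_matrix,
                 pad_samples = as.integer(pad_samples)),
            class = "preproc_spec")
}

#' High-pass frequency response
#'
#' The designed zero-phase response: 0 below `highpass_hz - transition_hz`,
#' 1 above `highpass_hz + transition_hz`, raised-cosine in between.
#'
#' @param freq_hz frequencies at which to evaluate.
#' @param spec a [preproc_spec()].
#' @return gain in `[0, 1]` per frequency.
#' @export
highpass_response <- function(freq_hz, spec) {
  lo <- spec$highpass_hz - spec$transition_hz
  hi <- spec$highpass_hz + spec$transition_hz
  f <- abs(freq_hz)
  g <- numeric(length(f))
  g[f >= hi] <- 1
  mid <- f > lo & f < hi
  g[mid] <- 0.5 * (1 - cos(pi * (f[mid] - lo) / (hi - lo)))
  g
}

# per-sample median across channels via an elementwise sorting network
# (odd-even transposition on the column vectors); fast for small C
row_median_channels <- function(x) {
  C <- ncol(x)
  if (C == 1L) return(x[, 1])
  cols <- lapply(seq_len(C), function(j) x[, j])
  for (pass in seq_len(C)) {
    start <- if (pass %% 2L == 1L) 1L else 2L
    if (start > C - 1L) next
    js <- seq(start, C - 1L, by = 2L)
    for (j in js) {
      a <- pmin(cols[[j]], cols[[j + 1L]])
      b <- pmax(cols[[j]], cols[[j + 1L]])
      cols[[j]] <- a; cols[[j + 1L]] <- b
    }
  }
  if (C %% 2L == 1L) {
    cols[[(C + 1L) %/% 2L]]
  } else {
    0.5 * (cols[[C %/% 2L]] + cols[[C %/% 2L + 1L]])
  }
}

# zero-phase FFT high-pass with reflection padding
fft_highpass <- function(x, spec) {
  T <- nrow(x)
  pad <- min(spec$pad_samples, T - 1L)
  if (pad > 0L) {
    top <- x[pad:1, , drop = FALSE]
    bot <- x[T:(T - pad + 1L), , drop = FALSE]
    xp <- rbind(top, x, bot)
  } else {
    xp <- x
  }
  L <- stats::nextn(nrow(xp), c(2, 3, 5))
  npad2 <- L - nrow(xp)
  freqs <- c(0:(L %/% 2), -((L - L %/% 2 - 1L):1)) * spec$fs / L
  gain <- highpass_response(freqs, spec)
  out <- matrix(0, T, ncol(x))
  # channel by channel keeps the peak allocation at one padded column
  for (j in seq_len(ncol(x))) {
    xf <- stats::fft(c(xp[, j], numeric(npad2)))
    v <- Re(stats::fft(xf * gain, inverse = TRUE)) / L
    out[, j] <- v[(pad + 1L):(pad + T)]
  }
  out
}

#' Preprocess one batch
#'
#' Applies, in order: per-channel mean subtraction, common median
#' referencing (per-sample median across channels subtracted from every
#' channel), zero-phase FFT high-pass, left-multiplication by the
#' whitening matrix, then by the drift matrix.
#'
#' @param batch numeric samples x channels matrix (uV or counts).
#' @param spec a [preproc_spec()].
#' @return Preprocessed matrix of the same shape.
#' @export
preprocess_batch <- function(batch, spec) {
  batch <- as.matrix(batch)
  if (!all(is.finite(batch))) stop("non-finite values in batch")
  if (ncol(batch) != spec$n_channels)
    stop(sprintf("batch has %d channels, spec expects %d",
                 ncol(batch), spec$n_channels))
  if (nrow(batch) < 8L) stop("batch too short for filtering")
  x <- sweep(batch, 2L, colMeans(batch))           # (1) mean subtraction
  x <- x - row_median_channels(x)                  # (2) CMR
  x <- fft_highpass(x, spec)                       # (3) high-pass
  x <- x %*% t(spec$whitening_matrix)              # (4) whitening
  x %*% t(spec$drift_matrix)                       # (5) drift correction
}

#' Channel-block ZCA whitening matrix
#'
#' Symmetric (ZCA-style) whitening estimated blockwise: for each channel,
#' the local covariance over channels within `neighborhood_radius_um` is
#' regularized by `eps` on the diagonal and inverted through its
#' eigendecomposition; the output row is the channel's row of the local
#' inverse square root.  For white unit-variance input the result is close
#' to the identity; as `eps` grows the matrix tends to `eps^-0.5 * I`.
#'
#' @param noise_segment samples x channels matrix of (filtered) noise.
#' @param geometry a [probe_geometry()].
#' @param neighborhood_radius_um channels within this radius form a block
#'   (default 100).
#' @param eps diagonal regularization; default `1e-6 * mean(diag(cov))`.
#' @return n_channels x n_channels whitening matrix.
#' @export
compute_whitening <- function(noise_segment, geometry,
                              neighborhood_radius_um = 100, eps = NULL) {
  x <- as.matrix(noise_segment)
  C <- ncol(x)
  if (C != n_channels(geometry))
    stop("noise segment channel count does not match geometry")
  cv <- crossprod(sweep(x, 2L, colMeans(x))) / (nrow(x) - 1L)
  if (is.null(eps)) eps <- 1e-6 * mean(diag(cv))
  if (eps < 0) stop("eps must be >= 0")
  dists <- channel_distances(geometry)
  W <- matrix(0, C, C)
  for (i in seq_len(C)) {
    nb <- which(dists[i, ] <= neighborhood_radius_um)
    S <- cv[nb, nb, drop = FALSE] + diag(eps, length(nb))
    eg <- eigen(S, symmetric = TRUE)
    if (min(eg$values) <= 0)
      stop("singular channel covariance; increase eps regularization")
    inv_sqrt <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
    W[i, nb] <- inv_sqrt[which(nb == i), ]
  }
  W
}
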