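#' Template-learning parameters
#'
#' @param min_train_s minimum training duration in seconds (default 60).
#' @param detect_mad_mult detection threshold in robust (MAD) SDs per
#'   channel (default 5).
#' @param n_pcs minimum temporal PCA components (default 6; reduced to
#'   the numerical rank of the snippet matrix when lower).
#' @param n_pcs_max,pca_capture the final basis grows beyond `n_pcs` (up
#'   to `n_pcs_max`, default 24) until every learned template retains at
#'   least `pca_capture` (default 0.995) of its energy in the basis span.
#' @param neighborhood_radius_um local channel neighborhood (default 100).
#' @param threshold_quantile quantile of the spike-free detection
#'   statistic (squared rectified amplitude, max-pooled as online) used
#'   as the learned threshold (default 0.999).
#' @param threshold_rel_floor absolute floor on the squared-amplitude
#'   threshold (default 0.05, i.e. spikes below ~22% of their template's
#'   amplitude are never accepted).
#' @param min_isi_samples duplicate-suppression window (default 15,
#'   0.5 ms at 30 kHz).
#' @param max_cluster_sample events subsampled for clustering (4000).
#' @param cut_mult cut height multiplier on the 75th-percentile
#'   nearest-neighbor feature distance (default 2).
#' @param min_cluster_size smallest surviving cluster in the subsample.
#' @param min_energy_frac templates with whitened energy below this
#'   fraction of the strongest template are rejected as noise fragments
#'   (default 0.005, i.e. 7% of the strongest amplitude).
#' @param whitening_eps whitening regularization (NULL = 1e-6 x mean
#'   diagonal).
#' @return list of parameters.
#' @export
learn_params <- function(min_train_s = 60, detect_mad_mult = 5, n_pcs = 6,
                         n_pcs_max = 24L, pca_capture = 0.995,
                         neighborhood_radius_um = 100,
                         threshold_quantile = 0.999,
                         threshold_rel_floor = 0.05,
                         min_isi_samples = 15L,
                         max_cluster_sample = 4000L,
                         cut_mult = 2, min_cluster_size = 20L,
                         min_energy_frac = 0.005, whitening_eps = NULL) {
  as.list(environment())
}

# threshold crossing detection with spatiotemporal non-maximum suppression;
# returns data.frame(time, channel, amp)
detect_events <- function(xw, geometry, mad_mult, radius_um, M) {
  T <- nrow(xw); C <- ncol(xw)
  center <- (M - 1L) %/% 2L
  thr <- apply(xw, 2L, function(v) stats::mad(v, center = 0))
  thr <- pmax(mad_mult * thr, 0.05 * max(abs(xw)))
  cand <- NULL
  for (c in seq_len(C)) {
    v <- xw[, c]
    idx <- which(v < -thr[c])
    idx <- idx[idx > center & idx <= T - center]
    if (!length(idx)) next
    ok <- v[idx] <= v[pmax(idx - 1L, 1L)] & v[idx] <= v[pmin(idx + 1L, T)]
    idx <- idx[ok]
    if (length(idx))
      cand <- rbind(cand, cbind(time = idx, channel = c, amp = -v[idx]))
  }
  if (is.null(cand)) return(data.frame(time = numeric(0),
                                       channel = integer(0), amp = numeric(0)))
  cand <- as.data.frame(cand)
  cand <- cand[order(cand$time), ]
  dists <- channel_distances(geometry)
  # group candidates whose times fall within one template length, then
  # keep the strongest candidate per spatial cluster inside each group
  gaps <- c(TRUE, diff(cand$time) > M - 1L)
  grp <- cumsum(gaps)
  out <- vector("list", max(grp))
  for (g in seq_len(max(grp))) {
    sub <- cand[grp == g, , drop = FALSE]
    kept <- NULL
    while (nrow(sub)) {
      i <- which.max(sub$amp)
      kept <- rbind(kept, sub[i, ])
      # the whitened footprint extends past the feature neighborhood, so
      # suppression uses a wider spatial radius to catch far-channel
      # ringing of the same spike
      near <- dists[sub$channel[i], sub$channel] <= 3 * radius_um &
        abs(sub$time - sub$time[i]) <= M - 1L
      sub <- sub[!near, , drop = FALSE]
    }
    out[[g]] <- kept
  }
  out <- do.call(rbind, out)
  out[order(out$time), ]
}

# fraction of a target waveform's energy explained by a greedy lagged
# least-squares combination of other templates (up to max_iter components);
# used to reject composite clusters formed by coincident spike pairs
explained_fraction <- function(target, others, M, max_iter = 3L) {
  res <- target
  en0 <- sum(target^2)
  if (en0 <= 0) return(1)
  for (iter in seq_len(max_iter)) {
    best <- NULL
    for (j in seq_along(others)) {
      tj <- others[[j]]
      ej <- sum(tj^2)
      if (ej <= 0) next
      for (lag in -(M - 1L):(M - 1L)) {
        i1 <- max(1L, 1L - lag):min(M, M - lag)
        i2 <- i1 + lag
        cc <- sum(res[i1, , drop = FALSE] * tj[i2, , drop = FALSE])
        gain <- cc^2 / ej
        if (is.null(best) || gain > best$gain)
          best <- list(j = j, lag = lag, a = cc / ej, gain = gain)
      }
    }
    if (is.null(best) || best$gain < 1e-3 * en0) break
    tj <- others[[best$j]]
    i1 <- max(1L, 1L - best$lag):min(M, M - best$lag)
    res[i1, ] <- res[i1, , drop = FALSE] -
      best$a * tj[i1 + best$lag, , drop = FALSE]
  }
  1 - sum(res^2) / en0
}

# average-linkage clustering of flattened PCA features with a
# noise-adaptive cut height; returns integer labels (NA = unassigned)
cluster_features <- function(feat, params, seed) {
  n <- nrow(feat)
  set.seed(seed)
  sub <- if (n > params$max_cluster_sample)
    sort(sample.int(n, params$max_cluster_sample)) else seq_len(n)
  fs <- feat[sub, , drop = FALSE]
  if (nrow(fs) < max(2L, params$min_cluster_size)) return(NULL)
  d <- stats::dist(fs)
  dm <- as.matrix(d)
  diag(dm) <- Inf
  nnd <- apply(dm, 1L, min)
  scale0 <- stats::median(dm[is.finite(dm)])
  cut_h <- max(params$cut_mult * stats::quantile(nnd, 0.75),
               1e-6 * max(scale0, 1e-12), 1e-9)
  hc <- stats::hclust(d, method = "average")
  lab <- stats::cutree(hc, h = cut_h)
  sizes <- table(lab)
  good <- as.integer(names(sizes)[sizes >= params$min_cluster_size])
  if (!length(good)) return(NULL)
  # relabel surviving clusters 1..K and compute centroids + capture radius
  centroids <- t(vapply(good, function(g)
    colMeans(fs[lab == g, , drop = FALSE]), numeric(ncol(fs))))
  radii <- vapply(seq_along(good), function(j) {
    mem <- fs[lab == good[j], , drop = FALSE]
    dd <- sqrt(rowSums(sweep(mem, 2L, centroids[j, ])^2))
    stats::quantile(dd, 0.95)
  }, 0)
  # assign every event to the nearest centroid, gated by capture radius
  d_all <- vapply(seq_along(good), function(j)
    rowSums(sweep(feat, 2L, centroids[j, ])^2), numeric(n))
  d_all <- matrix(d_all, nrow = n)
  best <- max.col(-d_all, ties.method = "first")
  bestd <- sqrt(d_all[cbind(seq_len(n), best)])
  gate <- pmax(2 * radii[best], 1e-6 * max(scale0, 1e-12))
  lab_all <- ifelse(bestd <= gate, best, NA_integer_)
  lab_all
}

#' Learn a template bank from a training recording
#'
#' Simplified offline learner: preprocess the training segment, detect
#' threshold-crossing events per channel, extract aligned M-sample
#' snippets, build a temporal PCA basis, cluster the PCA features
#' (average-linkage with a noise-adaptive cut), and take cluster means as
#' templates.  Fills every bank field, including the pairwise template
#' cross-correlations and the PCA-space cluster centroids, and calibrates
#' the detection threshold as a high quantile of the spike-free detection
#' statistic.
#'
#' @param training a [raw_recording()] of at least `params$min_train_s`.
#' @param params a [learn_params()] list.
#' @param seed RNG seed (clustering subsample).
#' @param M template length in samples (odd, default 61).
#' @return A [template_bank()].
#' @export
learn_templates <- function(training, params = learn_params(), seed = 1,
                            M = 61L) {
  stopifnot(inherits(training, "raw_recording"))
  fs <- training$fs
  geometry <- training$geometry
  if (nrow(training$data) / fs < params$min_train_s)
    stop(sprintf("training duration %.1f s is below min_train_s = %g",
                 nrow(training$data) / fs, params$min_train_s))
  C <- n_channels(geometry)
  center <- (M - 1L) %/% 2L

  # steps 1-3 of the chain, then whitening estimated from the spike-free
  # samples of the filtered data: spikes are sparse but energetic, and a
  # covariance that includes them makes ZCA suppress the spike subspace
  # itself, distorting the whitened waveforms
  spec0 <- preproc_spec(fs, C)
  x1 <- preprocess_batch(as_uv(training), spec0)
  mad1 <- apply(x1, 2L, function(v) stats::mad(v, center = 0))
  defl <- rowSums(sweep(abs(x1), 2L, pmax(5 * mad1, 1e-12), "/") > 1) > 0
  spike_rows <- which(defl)
  mask <- rep(FALSE, nrow(x1))
  for (off in -M:M) {
    idx <- spike_rows + off
    mask[idx[idx >= 1L & idx <= nrow(x1)]] <- TRUE
  }
  noise_rows <- if (mean(mask) > 0.9) seq_len(nrow(x1)) else which(!mask)
  Wm <- compute_whitening(x1[noise_rows, , drop = FALSE], geometry,
                          params$neighborhood_radius_um,
                          params$whitening_eps)
  # null the channel-common spatial direction: the median reference is
  # not additive across superimposed spikes, and its residue is exactly
  # channel-constant per sample, i.e. along W * 1 after whitening;
  # projecting that direction out of the whitening matrix makes spike
  # superpositions add linearly in the preprocessed domain
  cm <- Wm %*% rep(1, C)
  if (sum(cm^2) > 0)
    Wm <- (diag(C) - tcrossprod(cm) / sum(cm^2)) %*% Wm
  xw <- x1 %*% t(Wm)
  spec <- preproc_spec(fs, C, whitening_matrix = Wm)

  rm(x1); gc(verbose = FALSE)
  ev <- detect_events(xw, geometry, params$detect_mad_mult,
                      params$neighborhood_radius_um, M)
  if (!nrow(ev)) stop("no units learned: no events detected above threshold")

  # contamination: an event whose snippet window holds another detected
  # event (within 2x the neighborhood radius) carries a superimposed
  # waveform or is a secondary echo; such snippets are excluded from
  # basis estimation, clustering and template averaging
  dists <- channel_distances(geometry)
  clean <- rep(TRUE, nrow(ev))
  if (nrow(ev) > 1L) {
    for (i in seq_len(nrow(ev))) {
      j <- i + 1L
      while (j <= nrow(ev) && ev$time[j] - ev$time[i] < M) {
        if (dists[ev$channel[i], ev$channel[j]] <=
            2 * params$neighborhood_radius_um) {
          clean[i] <- FALSE; clean[j] <- FALSE
        }
        j <- j + 1L
      }
    }
  }
  if (sum(clean) < max(20L, nrow(ev) %/% 2L)) clean[] <- TRUE
  ev <- ev[clean, , drop = FALSE]

  # aligned snippets
  snips <- array(0, dim = c(nrow(ev), M, C))
  for (i in seq_len(nrow(ev)))
    snips[i, , ] <- xw[(ev$time[i] - center):(ev$time[i] + center), ]

  # temporal PCA on per-channel waveforms within each event's neighborhood
  rows <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    nb <- which(dists[ev$channel[i], ] <= params$neighborhood_radius_um)
    rows[[i]] <- t(matrix(snips[i, , nb], M))
  }
  Z <- do.call(rbind, rows)
  if (nrow(Z) > 20000L) {
    set.seed(seed + 1L)
    Z <- Z[sort(sample.int(nrow(Z), 20000L)), , drop = FALSE]
  }
  sv <- svd(Z, nu = 0)
  rank <- sum(sv$d > 1e-8 * sv$d[1])
  if (rank < 1L) stop("no units learned: snippet matrix has no variance")
  # initial clustering basis: enough components that shape differences
  # between units sharing a channel survive the truncation, but none
  # from the noise bulk (singular values must rise clear of the median)
  P <- max(params$n_pcs,
           min(params$n_pcs_max, sum(sv$d > 2 * stats::median(sv$d))))
  P <- min(P, rank)
  basis <- t(sv$v[, seq_len(P), drop = FALSE])   # P x M, orthonormal rows

  # per-event features, masked to the event's channel neighborhood
  feat <- matrix(0, nrow(ev), P * C)
  for (i in seq_len(nrow(ev))) {
    Fm <- basis %*% snips[i, , ]
    nb <- dists[ev$channel[i], ] <= params$neighborhood_radius_um
    Fm[, !nb] <- 0
    feat[i, ] <- as.vector(Fm)
  }

  lab <- cluster_features(feat, params, seed)
  if (is.null(lab) || !any(!is.na(lab)))
    stop("no units learned: no cluster met the minimum size")
  K0 <- max(lab, na.rm = TRUE)

  # cluster medians: robust to the minority of snippets contaminated by
  # an overlapping spike from another unit
  det_thr <- pmax(params$detect_mad_mult *
                    apply(xw, 2L, function(v) stats::mad(v, center = 0)),
                  0.01 * max(abs(xw)))
  means <- vector("list", K0); detectable <- logical(K0); sizes <- integer(K0)
  for (k in seq_len(K0)) {
    mem <- which(!is.na(lab) & lab == k)
    sizes[k] <- length(mem)
    tm <- apply(snips[mem, , , drop = FALSE], c(2, 3), stats::median)
    means[[k]] <- tm
    pk <- which.max(apply(abs(tm), 2L, max))
    # a cluster mean must itself be detectable, else it is noise/fragment
    detectable[k] <- max(-tm[, pk]) >= det_thr[pk]
  }

  # composite rejection: clusters formed by coincident spike pairs have a
  # template explainable as a lagged combination of other (larger)
  # clusters' templates; accept clusters largest-first and reject any
  # whose template is mostly explained by the already-accepted ones
  ord_k <- order(sizes, decreasing = TRUE)
  accepted <- integer(0)
  for (k in ord_k) {
    if (!detectable[k]) next
    if (length(accepted) &&
        explained_fraction(means[[k]], means[accepted], M) > 0.9) next
    accepted <- c(accepted, k)
  }
  if (!length(accepted))
    stop("no units learned: no cluster mean cleared the detection threshold")
  # noise-fragment rejection: a template whose whitened energy is a tiny
  # fraction of the strongest has matched-filter responses at the noise
  # scale and would fire indiscriminately
  ens <- vapply(accepted, function(k) sum(means[[k]]^2), 0)
  accepted <- accepted[ens >= params$min_energy_frac * max(ens)]
  accepted <- sort(accepted)
  K <- length(accepted)

  # clean members: snippets close to their cluster median (contaminated
  # snippets are excluded from the final basis and statistics)
  clean_mem <- vector("list", K)
  for (j in seq_len(K)) {
    k <- accepted[j]
    mem <- which(!is.na(lab) & lab == k)
    resid <- vapply(mem, function(i)
      sum((snips[i, , ] - means[[k]])^2), 0)
    en <- sum(means[[k]]^2)
    keep <- resid <= pmax(0.3 * en, 2 * stats::median(resid))
    clean_mem[[j]] <- mem[keep]
  }

  # re-align members to their cluster median (+/- 2 samples) before the
  # final average: the detected trough can flip between adjacent samples
  # when the true trough falls near a half-sample, and a median over
  # mixed alignments blurs the template
  med_clean <- vector("list", K)
  for (j in seq_len(K)) {
    mem <- clean_mem[[j]]
    med0 <- apply(snips[mem, , , drop = FALSE], c(2, 3), stats::median)
    aligned <- array(0, dim = c(length(mem), M, C))
    for (ii in seq_along(mem)) {
      i <- mem[ii]
      best_lag <- 0L; best_cc <- -Inf
      for (lag in -2:2) {
        t0 <- ev$time[i] + lag
        if (t0 - center < 1L || t0 + center > nrow(xw)) next
        cc <- sum(xw[(t0 - center):(t0 + center), ] * med0)
        if (cc > best_cc) { best_cc <- cc; best_lag <- lag }
      }
      t0 <- ev$time[i] + best_lag
      aligned[ii, , ] <- xw[(t0 - center):(t0 + center), ]
    }
    med_clean[[j]] <- apply(aligned, c(2, 3), stats::median)
  }
  # final temporal basis from the accepted cluster medians (denoised), so
  # the templates themselves are represented nearly exactly; the
  # component count grows from n_pcs until every template retains at
  # least `pca_capture` of its energy (or n_pcs_max is reached)
  Z2 <- do.call(rbind, lapply(med_clean, function(m) t(m)))
  sv2 <- svd(Z2, nu = 0)
  rank2 <- sum(sv2$d > 1e-8 * sv2$d[1])
  P <- min(params$n_pcs, rank2)
  for (Ptry in P:min(params$n_pcs_max, rank2)) {
    Ut <- t(sv2$v[, seq_len(Ptry), drop = FALSE])
    cap <- vapply(med_clean, function(m)
      sum((Ut %*% m)^2) / sum(m^2), 0)
    P <- Ptry
    if (min(cap) >= params$pca_capture) break
  }
  basis <- t(sv2$v[, seq_len(P), drop = FALSE])
  proj <- crossprod(basis)   # M x M projector onto the basis span

  templates <- array(0, dim = c(K, M, C))
  peak_channels <- integer(K)
  centroids <- matrix(0, K, P * C)
  template_features <- array(0, dim = c(K, P, C))
  for (j in seq_len(K)) {
    mem <- clean_mem[[j]]
    tm <- proj %*% med_clean[[j]]
    templates[j, , ] <- tm
    pk <- which.max(apply(abs(tm), 2L, max))
    peak_channels[j] <- pk
    nb <- dists[pk, ] <= params$neighborhood_radius_um
    Fm <- basis %*% matrix(tm, M, C)
    Fm[, !nb] <- 0
    template_features[j, , ] <- Fm
    # member features in the final basis, masked to the template's
    # neighborhood (matches how events are featurized online)
    mf <- t(vapply(mem, function(i) {
      Fi <- basis %*% snips[i, , ]
      Fi[, !nb] <- 0
      as.vector(Fi)
    }, numeric(P * C)))
    centroids[j, ] <- apply(mf, 2L, stats::median)
  }

  pair_cc <- compute_pair_cc(templates)
  energies <- vapply(seq_len(K), function(k) pair_cc[k, k, M], 0)

  thr <- calibrate_threshold(xw, basis, templates, pair_cc, ev$time, M,
                             params)
  bank <- template_bank(templates, basis, template_features, pair_cc,
                        detect_threshold = thr, centroids = centroids,
                        template_to_cluster = seq_len(K),
                        min_isi_samples = params$min_isi_samples,
                        preproc = spec, geometry = geometry,
                        peak_channels = peak_channels,
                        neighborhood_radius_um = params$neighborhood_radius_um)
  bank
}

# learned threshold: q-quantile of the normalized detection statistic's
# temporal local maxima on spike-free stretches, floored at a fraction of
# the smallest template energy
calibrate_threshold <- function(xw, basis, templates, pair_cc, event_times,
                                M, params) {
  K <- dim(templates)[1]
  energies <- vapply(seq_len(K), function(k) pair_cc[k, k, M], 0)
  T <- nrow(xw); center <- (M - 1L) %/% 2L
  W <- matrix(0, nrow(basis) * ncol(xw), K)
  for (k in seq_len(K))
    W[, k] <- as.vector(basis %*% matrix(templates[k, , ], M, ncol(xw)))
  # mask +/- 2M around detected events
  spike_mask <- rep(FALSE, T)
  for (t0 in event_times) {
    lo <- max(1L, t0 - 2L * M); hi <- min(T, t0 + 2L * M)
    spike_mask[lo:hi] <- TRUE
  }
  # block maxima over the same 2M+1 window the online max-pooling uses, so
  # the quantile controls the per-window false-detection rate
  pool_w <- 2L * M + 1L
  maxima <- vector("list", K)
  blk <- 65536L
  starts <- seq(1L, T, by = blk - M)
  for (s in starts) {
    e <- min(s + blk - 1L, T)
    if (e - s + 1L < M + 2L) next
    Fm <- project_batch(xw[s:e, , drop = FALSE], basis, M)
    conv <- Fm %*% W
    stat <- sweep(pmax(conv, 0), 2L, energies, "/")^2
    stat[spike_mask[s:e], ] <- NA
    valid <- (center + 1L):(nrow(stat) - center)
    sv <- stat[valid, , drop = FALSE]
    n_blocks <- nrow(sv) %/% pool_w
    if (n_blocks < 1L) next
    sv <- sv[seq_len(n_blocks * pool_w), , drop = FALSE]
    for (k in seq_len(K)) {
      bm <- suppressWarnings(
        apply(matrix(sv[, k], nrow = pool_w), 2L, max, na.rm = TRUE))
      bm <- bm[is.finite(bm)]
      if (length(bm)) maxima[[k]] <- c(maxima[[k]], bm)
    }
  }
  # one noise-calibrated threshold per template: weak templates have
  # larger noise-driven amplitude maxima and need a higher floor
  q <- vapply(maxima, function(m)
    if (length(m)) stats::quantile(m, params$threshold_quantile,
                                   names = FALSE) else 0, 0)
  pmax(q, params$threshold_rel_floor)
}

#' Import a template bank from a phy-layout directory
#'
#' Reads `templates.npy` (K x M x C), `channel_map.npy` and
#' `channel_positions.npy`; uses `whitening_mat.npy` when present.  The
#' PCA basis is rebuilt from the imported templates, the templates are
#' projected onto it, and the pairwise cross-correlations are recomputed.
#'
#' @param kilosort_dir directory in the phy layout.
#' @param detect_threshold squared-amplitude detection threshold to
#'   store (no raw data is available at import time; default 0.05).
#' @param fs sampling rate (default 30000).
#' @param n_pcs temporal PCA size (default 6, rank-limited).
#' @param min_isi_samples,neighborhood_radius_um see [template_bank()].
#' @return A [template_bank()].
#' @export
import_bank <- function(kilosort_dir, detect_threshold = 0.05, fs = 30000,
                        n_pcs = 6, min_isi_samples = 15L,
                        neighborhood_radius_um = 100) {
  need <- c("templates.npy", "channel_map.npy", "channel_positions.npy")
  missing <- need[!file.exists(file.path(kilosort_dir, need))]
  if (length(missing))
    stop("phy directory is missing: ", paste(missing, collapse = ", "))
  tm <- npy_read(file.path(kilosort_dir, "templates.npy"))
  if (length(dim(tm)) != 3L) stop("templates.npy must be K x M x C")
  K <- dim(tm)[1]; M <- dim(tm)[2]; C <- dim(tm)[3]
  if (M %% 2L == 0L) {   # trim to odd length, keeping the center
    tm <- tm[, seq_len(M - 1L), , drop = FALSE]
    M <- M - 1L
  }
  chmap <- npy_read(file.path(kilosort_dir, "channel_map.npy"))
  pos <- npy_read(file.path(kilosort_dir, "channel_positions.npy"))
  if (!is.matrix(pos)) pos <- matrix(pos, ncol = 2)
  if (length(chmap) != C || nrow(pos) != C)
    stop(sprintf("channel count mismatch: templates have %d channels, map %d, positions %d",
                 C, length(chmap), nrow(pos)))
  geometry <- probe_geometry(seq_len(C) - 1L, pos[, 1], pos[, 2])
  wfile <- file.path(kilosort_dir, "whitening_mat.npy")
  Wm <- if (file.exists(wfile)) npy_read(wfile) else diag(C)
  spec <- preproc_spec(fs, C, whitening_matrix = Wm)

  Z <- do.call(rbind, lapply(seq_len(K), function(k) t(matrix(tm[k, , ], M, C))))
  sv <- svd(Z, nu = 0)
  rank <- sum(sv$d > 1e-8 * sv$d[1])
  P <- min(n_pcs, max(rank, 1L))
  basis <- t(sv$v[, seq_len(P), drop = FALSE])
  proj <- crossprod(basis)
  templates <- array(0, dim = c(K, M, C))
  peak_channels <- integer(K)
  for (k in seq_len(K)) {
    templates[k, , ] <- proj %*% matrix(tm[k, , ], M, C)
    peak_channels[k] <- which.max(apply(abs(templates[k, , ]), 2L, max))
  }
  dists <- channel_distances(geometry)
  template_features <- array(0, dim = c(K, P, C))
  centroids <- matrix(0, K, P * C)
  for (k in seq_len(K)) {
    Fm <- basis %*% matrix(templates[k, , ], M, C)
    nb <- dists[peak_channels[k], ] <= neighborhood_radius_um
    Fm[, !nb] <- 0
    template_features[k, , ] <- Fm
    centroids[k, ] <- as.vector(Fm)
  }
  template_bank(templates, basis, template_features,
                compute_pair_cc(templates),
                detect_threshold = detect_threshold, centroids = centroids,
                template_to_cluster = seq_len(K),
                min_isi_samples = min_isi_samples, preproc = spec,
                geometry = geometry, peak_channels = peak_channels,
                neighborhood_radius_um = neighborhood_radius_um)
}
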