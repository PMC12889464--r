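# shared fixture builders; everything is generated in code at test time

tiny_geom <- function(C = 8L, pitch = 40) {
  probe_geometry(seq_len(C) - 1L, x = rep(c(0, 32), length.out = C),
                 y = rep(seq(0, by = pitch, length.out = ceiling(C / 2)),
                         each = 2)[seq_len(C)])
}

# a hand-built bank over synthetic biphasic templates (no training run);
# identity whitening, M small for speed
toy_bank <- function(K = 3L, C = 8L, M = 21L, fs = 30000,
                     detect_threshold = 0.05, min_isi = 15L) {
  geometry <- tiny_geom(C)
  tmpl <- make_templates(geometry, K, seed = 42,
                         shape_params = list(M = M,
                                             width_range_us = c(120, 400)),
                         fs = fs)
  templates <- array(0, dim = c(K, M, C))
  for (k in seq_len(K)) templates[k, , ] <- tmpl[[k]]
  # orthonormal temporal basis spanning the templates exactly
  Z <- do.call(rbind, lapply(tmpl, t))
  sv <- svd(Z, nu = 0)
  P <- sum(sv$d > 1e-10 * sv$d[1])
  basis <- t(sv$v[, seq_len(P), drop = FALSE])
  proj <- crossprod(basis)
  for (k in seq_len(K)) templates[k, , ] <- proj %*% templates[k, , ]
  peaks <- vapply(seq_len(K), function(k)
    which.max(apply(abs(templates[k, , ]), 2, max)), 0L)
  dists <- as.matrix(stats::dist(cbind(geometry$x, geometry$y)))
  template_features <- array(0, dim = c(K, P, C))
  centroids <- matrix(0, K, P * C)
  for (k in seq_len(K)) {
    Fm <- basis %*% templates[k, , ]
    Fm[, dists[peaks[k], ] > 100] <- 0
    template_features[k, , ] <- Fm
    centroids[k, ] <- as.vector(Fm)
  }
  template_bank(templates, basis, template_features,
                compute_pair_cc(templates),
                detect_threshold = detect_threshold,
                centroids = centroids, template_to_cluster = seq_len(K),
                min_isi_samples = min_isi,
                preproc = preproc_spec(fs, C), geometry = geometry,
                peak_channels = peaks)
}

# ground truth with fully specified spike times (no Poisson draw)
manual_ground_truth <- function(units, spikes, duration_s, fs = 30000) {
  structure(list(units = units, spikes = spikes, trials = NULL, fs = fs,
                 duration_s = duration_s, state = NULL),
            class = "ground_truth")
}

# small learned session shared across train/engine tests (built once)
.session_cache <- new.env(parent = emptyenv())

small_session <- function() {
  if (!is.null(.session_cache$s)) return(.session_cache$s)
  geometry <- tiny_geom(8L)
  units <- make_units(geometry, K = 4, seed = 2, fs = 30000)
  gt <- simulate_trains(units, duration_s = 20, fs = 30000, seed = 3)
  rec <- render_recording(gt, geometry, noise_sd = 15, amp_jitter = 0.1,
                          seed = 4)
  bank <- learn_templates(rec, learn_params(min_train_s = 10), seed = 5)
  .session_cache$s <- list(geometry = geometry, units = units, gt = gt,
                           rec = rec, bank = bank)
  .session_cache$s
}
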