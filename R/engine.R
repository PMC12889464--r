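#' Plan overlapping processing batches
#'
#' Window k starts at `k * (batch_len - 2M)` (0-based samples), so
#' consecutive windows overlap by exactly 2M samples.  Each window owns
#' the emit range `[start + M, end - M)`, except that the first window's
#' emit range starts at 0 and the last ends at `n_samples`; the emit
#' ranges are disjoint and cover the recording.
#'
#' @param n_samples recording length in samples.
#' @param batch_len window length (must exceed 4M).
#' @param M template length in samples.
#' @return An object of class `batch_plan`: data.frame with 0-based
#'   half-open `start`, `end`, `emit_start`, `emit_end`.
#' @export
plan_batches <- function(n_samples, batch_len, M) {
  if (batch_len <= 4 * M)
    stop(sprintf("batch_len (%d) must exceed 4M = %d", batch_len, 4 * M))
  step <- batch_len - 2L * M
  starts <- 0
  while (utils::tail(starts, 1) + batch_len < n_samples)
    starts <- c(starts, utils::tail(starts, 1) + step)
  ends <- pmin(starts + batch_len, n_samples)
  W <- length(starts)
  emit_start <- starts + M
  emit_end <- ends - M
  emit_start[1] <- 0
  emit_end[W] <- n_samples
  plan <- data.frame(start = starts, end = ends,
                     emit_start = emit_start, emit_end = emit_end)
  class(plan) <- c("batch_plan", "data.frame")
  attr(plan, "M") <- M
  plan
}

# cross-correlation of every (pca component, channel) pair with the batch:
# F[s, (c-1)*P + p] = sum_m U[p, m] * x[s - center - 1 + m, c],
# valid for s in [center+1, T-center]; invalid border rows are zeroed.
project_batch <- function(x, basis, M) {
  T <- nrow(x); C <- ncol(x); P <- nrow(basis)
  center <- (M - 1L) %/% 2L
  L <- stats::nextn(T + M, c(2, 3, 5))
  uf <- lapply(seq_len(P), function(p)
    stats::fft(c(basis[p, ], numeric(L - M))))
  Fm <- matrix(0, T, P * C)
  valid <- (center + 1L):(T - center)
  for (c in seq_len(C)) {
    xf <- stats::fft(c(x[, c], numeric(L - T)))
    for (p in seq_len(P)) {
      cc <- Re(stats::fft(xf * Conj(uf[[p]]), inverse = TRUE)) / L
      Fm[valid, (c - 1L) * P + p] <- cc[valid - center]
    }
  }
  Fm
}

# flattened full-channel template features used for the convolution
# (templates lie in the span of the basis, so the feature product equals
# direct convolution with the stored templates)
template_feature_matrix <- function(bank) {
  K <- dim(bank$templates)[1]; M <- dim(bank$templates)[2]
  C <- dim(bank$templates)[3]; P <- nrow(bank$pca_basis)
  W <- matrix(0, P * C, K)
  for (k in seq_len(K)) {
    W[, k] <- as.vector(bank$pca_basis %*% matrix(bank$templates[k, , ], M, C))
  }
  W
}

# direct (brute-force) convolution of a batch with every template over the
# valid region; the independent oracle for the feature-product route
direct_convolution <- function(x, templates) {
  K <- dim(templates)[1]; M <- dim(templates)[2]
  T <- nrow(x); center <- (M - 1L) %/% 2L
  conv <- matrix(0, T, K)
  for (s in (center + 1L):(T - center)) {
    seg <- x[(s - center):(s + center), , drop = FALSE]
    for (k in seq_len(K))
      conv[s, k] <- sum(seg * templates[k, , ])
  }
  conv
}

#' Run the matching-pursuit detection loop on one preprocessed batch
#'
#' The batch is projected onto the temporal PCA basis and cross-correlated
#' with the template features as a matrix product.  Up to `max_passes`
#' passes then: square the rectified convolution normalized by template
#' energy (border samples zeroed), find per-template temporal local maxima
#' by max-pooling over a 2M+1 window, accept candidates whose statistic
#' exceeds the learned threshold, compute each amplitude as the
#' least-squares coefficient of the template against the current residual,
#' and subtract the spike from both the residual and every template's
#' convolution trace via the precomputed pairwise cross-correlations.
#' The loop stops early when a pass accepts nothing.
#'
#' @param prebatch preprocessed samples x channels matrix.
#' @param bank a [template_bank()].
#' @param max_passes pass limit (default 50).
#' @param trace_conv if TRUE, keep the convolution buffer and residual
#'   after every pass (for consistency checks on small instances).
#' @return list with `events` (data.frame `time`, `template`, `amplitude`,
#'   time local to the batch), `features` (per-event n_pcs x C PCA feature
#'   matrix extracted from the residual before subtraction), `passes`,
#'   and, when traced, `trace` (per pass: `conv`, `residual`).
#' @export
run_matching_pursuit <- function(prebatch, bank, max_passes = 50L,
                                 trace_conv = FALSE) {
  x <- as.matrix(prebatch)
  K <- dim(bank$templates)[1]; M <- dim(bank$templates)[2]
  C <- dim(bank$templates)[3]
  if (ncol(x) != C) stop("batch channel count does not match bank")
  T <- nrow(x); center <- (M - 1L) %/% 2L
  if (T < M) stop("batch shorter than template")
  basis <- bank$pca_basis
  W <- template_feature_matrix(bank)
  energies <- vapply(seq_len(K), function(k) bank$pair_cc[k, k, M], 0)
  thr <- rep_len(bank$detect_threshold, K)
  Fm <- project_batch(x, basis, M)
  conv <- Fm %*% W
  valid_lo <- center + 1L; valid_hi <- T - center
  tmpl_flat <- lapply(seq_len(K), function(k) matrix(bank$templates[k, , ], M, C))

  ev_t <- integer(0); ev_k <- integer(0); ev_a <- numeric(0)
  feats <- list()
  trace <- if (trace_conv) list() else NULL
  subtract_at <- function(t0, k, amount) {
    rows <- (t0 - center):(t0 + center)
    x[rows, ] <<- x[rows, , drop = FALSE] - amount * tmpl_flat[[k]]
    lo <- max(valid_lo, t0 - (M - 1L)); hi <- min(valid_hi, t0 + (M - 1L))
    lags <- (lo:hi) - t0 + M
    conv[lo:hi, ] <<- conv[lo:hi, ] -
      amount * t(matrix(bank$pair_cc[, k, lags], K))
  }
  # exact joint refit of a small overlap group: each event may move by
  # +/- 2 samples; for every lag configuration the amplitudes solve the
  # joint least-squares system built from the pairwise template
  # cross-correlations (negative amplitudes clamped out), and the
  # configuration with the largest residual-energy reduction wins.  The
  # current configuration is in the search space, so the refit never
  # increases the residual.
  joint_refit <- function(idx) {
    n <- length(idx)
    for (j in idx) if (ev_a[j] != 0) subtract_at(ev_t[j], ev_k[j], -ev_a[j])
    ks <- ev_k[idx]
    base_t <- ev_t[idx]
    lag_grid <- expand.grid(rep(list(-2L:2L), n))
    best <- NULL
    for (g in seq_len(nrow(lag_grid))) {
      ts <- base_t + as.integer(lag_grid[g, ])
      if (any(ts < valid_lo | ts > valid_hi)) next
      b <- vapply(seq_len(n), function(i) conv[ts[i], ks[i]], 0)
      G <- matrix(0, n, n)
      for (i in seq_len(n)) for (j2 in seq_len(n)) {
        dlag <- ts[i] - ts[j2]
        G[i, j2] <- if (abs(dlag) <= M - 1L)
          bank$pair_cc[ks[i], ks[j2], M + dlag] else 0
      }
      act <- seq_len(n)
      a <- rep(0, n)
      for (it in 1:3) {
        if (!length(act)) break
        sol <- tryCatch(solve(G[act, act, drop = FALSE], b[act]),
                        error = function(e) NULL)
        if (is.null(sol)) { a[act] <- pmax(b[act] / diag(G)[act], 0); break }
        a[act] <- sol
        neg <- act[sol < 0]
        if (!length(neg)) break
        a[neg] <- 0
        act <- setdiff(act, neg)
      }
      red <- 2 * sum(a * b) - as.numeric(t(a) %*% G %*% a)
      if (is.null(best) || red > best$red)
        best <- list(red = red, ts = ts, a = a)
    }
    if (!is.null(best)) {
      for (i in seq_len(n)) {
        j <- idx[i]
        ev_t[j] <<- best$ts[i]; ev_a[j] <<- best$a[i]
        if (best$a[i] > 0) subtract_at(best$ts[i], ev_k[j], best$a[i])
      }
    }
  }
  # monotone coordinate descent over a set of events: remove each event,
  # re-pick its best time within +/- 2 samples from the updated
  # convolution, re-fit its amplitude; every step maximally reduces the
  # residual energy for that event, so overlapping spikes converge to
  # their joint least-squares times and amplitudes
  polish_events <- function(idx, sweeps = 3L) {
    for (sweep_i in seq_len(sweeps)) {
      moved <- FALSE
      for (j in idx) {
        if (ev_a[j] != 0) subtract_at(ev_t[j], ev_k[j], -ev_a[j])
        ts <- ev_t[j] + (-2L:2L)
        ts <- ts[ts >= valid_lo & ts <= valid_hi]
        best <- ts[which.max(conv[ts, ev_k[j]])]
        a_new <- max(conv[best, ev_k[j]] / energies[ev_k[j]], 0)
        if (best != ev_t[j] || abs(a_new - ev_a[j]) > 1e-9) moved <- TRUE
        ev_t[j] <<- best; ev_a[j] <<- a_new
        if (a_new > 0) subtract_at(best, ev_k[j], a_new)
      }
      if (!moved) break
    }
  }
  pass <- 0L
  repeat {
    pass <- pass + 1L
    if (any(!is.finite(conv)))
      stop("non-finite convolution values at pass ", pass)
    # normalized detection statistic: squared rectified amplitude
    # (ReLU(conv)/energy)^2, so the threshold is an amplitude floor
    # uniform across templates
    stat <- sweep(pmax(conv, 0), 2L, energies, "/")^2
    if (valid_lo > 1L) stat[1:(valid_lo - 1L), ] <- 0
    if (valid_hi < T) stat[(valid_hi + 1L):T, ] <- 0
    # per-template local maxima by max-pooling (window 2M+1): first the
    # cheap +/- 1 local-max test vectorized, then the full window check
    # on the few survivors
    cand_t <- integer(0); cand_k <- integer(0); cand_s <- numeric(0)
    for (k in seq_len(K)) {
      v <- stat[, k]
      idx <- which(v > thr[k])
      if (!length(idx)) next
      idx <- idx[v[idx] >= v[pmax(idx - 1L, 1L)] &
                   v[idx] >= v[pmin(idx + 1L, T)]]
      if (!length(idx)) next
      is_max <- vapply(idx, function(t) {
        lo <- max(1L, t - M); hi <- min(T, t + M)
        v[t] >= max(v[lo:hi])
      }, TRUE)
      idx <- idx[is_max]
      cand_t <- c(cand_t, idx)
      cand_k <- c(cand_k, rep(k, length(idx)))
      # greedy processing order by explained energy a^2 * E
      cand_s <- c(cand_s, stat[idx, k] * energies[k])
    }
    accepted <- 0L
    if (length(cand_t)) {
      ord <- order(cand_s, decreasing = TRUE)
      for (i in ord) {
        t0 <- cand_t[i]; k <- cand_k[i]
        cur <- conv[t0, k]
        if (cur <= 0 || (cur / energies[k])^2 <= thr[k]) next
        a <- cur / energies[k]
        ev_t <- c(ev_t, t0); ev_k <- c(ev_k, k); ev_a <- c(ev_a, a)
        subtract_at(t0, k, a)
        # immediately refit the events overlapping the new one, so the
        # remaining candidates of this pass are re-checked against a
        # residual with correctly placed neighbors
        near <- which(abs(ev_t - t0) <= 2L * M)
        if (length(near) > 1L) {
          if (length(near) <= 3L) joint_refit(near) else polish_events(near)
        }
        accepted <- accepted + 1L
      }
    }
    # global polish between passes
    if (accepted > 0L && length(ev_t) > 1L)
      polish_events(seq_along(ev_t))
    if (trace_conv)
      trace[[pass]] <- list(conv = conv, residual = x)
    if (accepted == 0L || pass >= max_passes) break
  }
  if (length(ev_t)) {   # the polish can zero out or starve an event;
    # the survivors must still clear the acceptance threshold
    pos <- ev_a > 0 & ev_a^2 > thr[ev_k]
    ev_t <- ev_t[pos]; ev_k <- ev_k[pos]; ev_a <- ev_a[pos]
  }
  ev <- if (length(ev_t)) {
    ord <- order(ev_t)
    ev_t <- ev_t[ord]; ev_k <- ev_k[ord]; ev_a <- ev_a[ord]
    # per-event features from the final residual plus the event's own
    # fitted contribution: isolates each spike from its overlap partners
    feats <- lapply(seq_along(ev_t), function(j) {
      rows <- (ev_t[j] - center):(ev_t[j] + center)
      basis %*% (x[rows, , drop = FALSE] + ev_a[j] * tmpl_flat[[ev_k[j]]])
    })
    data.frame(time = as.numeric(ev_t), template = ev_k,
               amplitude = ev_a)
  } else {
    feats <- list()
    data.frame(time = numeric(0), template = integer(0),
               amplitude = numeric(0))
  }
  list(events = ev, features = feats, passes = pass, trace = trace,
       residual = x)
}

#' Localize a spike and assign it to a cluster
#'
#' Position is the mass-weighted average of channel positions, with mass
#' the PCA feature energy per channel over the accepted template's local
#' neighborhood; the cluster is the nearest centroid (Euclidean, over the
#' same neighborhood's feature dimensions), ties broken by lowest id.
#' All-zero mass falls back to the template peak-channel position.
#'
#' @param event list or one-row data.frame with `time`, `template`,
#'   `amplitude`.
#' @param residual_features n_pcs x C feature matrix for the event.
#' @param bank a [template_bank()].
#' @return list (`time`, `template`, `cluster`, `amplitude`, `x`, `y`,
#'   `fallback` flag).
#' @export
localize_and_assign <- function(event, residual_features, bank) {
  k <- as.integer(event$template)
  P <- nrow(bank$pca_basis); C <- ncol(residual_features)
  dists <- channel_distances(bank$geometry)
  nb <- which(dists[bank$peak_channels[k], ] <= bank$neighborhood_radius_um)
  Fm <- residual_features
  mass <- colSums(Fm[, nb, drop = FALSE]^2)
  fallback <- FALSE
  if (sum(mass) <= 0) {
    pos <- c(bank$geometry$x[bank$peak_channels[k]],
             bank$geometry$y[bank$peak_channels[k]])
    fallback <- TRUE
  } else {
    pos <- c(sum(mass * bank$geometry$x[nb]) / sum(mass),
             sum(mass * bank$geometry$y[nb]) / sum(mass))
  }
  # nearest centroid over the neighborhood's feature dimensions
  dims <- as.vector(outer(seq_len(P), (nb - 1L) * P, "+"))
  f <- as.vector(Fm)[dims]
  cm <- bank$centroids[, dims, drop = FALSE]
  d2 <- rowSums(sweep(cm, 2L, f)^2)
  cl <- which.min(d2)  # first minimum = lowest id on ties
  list(time = event$time, template = k, cluster = as.integer(cl),
       amplitude = event$amplitude, x = pos[1], y = pos[2],
       fallback = fallback)
}

#' Suppress duplicate detections per template
#'
#' Within each template, of any two events closer than `min_isi_samples`
#' the larger-amplitude one survives; applied greedily in descending
#' amplitude order.  Events separated by exactly `min_isi_samples` both
#' survive (strict inequality).
#'
#' @param events data.frame with at least `time`, `template`, `amplitude`,
#'   sorted by time.
#' @param min_isi_samples suppression window.
#' @return The surviving rows, sorted by time.
#' @export
dedup_events <- function(events, min_isi_samples) {
  if (!nrow(events)) return(events)
  keep <- rep(TRUE, nrow(events))
  for (k in unique(events$template)) {
    idx <- which(events$template == k)
    if (length(idx) < 2L) next
    ord <- idx[order(events$amplitude[idx], decreasing = TRUE)]
    taken <- numeric(0)
    for (i in ord) {
      if (length(taken) && any(abs(taken - events$time[i]) < min_isi_samples)) {
        keep[i] <- FALSE
      } else {
        taken <- c(taken, events$time[i])
      }
    }
  }
  out <- events[keep, , drop = FALSE]
  out[order(out$time), , drop = FALSE]
}

#' Sort a recording by streaming matching pursuit
#'
#' Iterates the batch plan: each window is preprocessed (with up to
#' `context_samples` of neighboring recording on each side as filter
#' context, cropped afterwards), matched against the bank, and only
#' events inside the window's emit range are kept; events are then
#' localized, cluster-assigned and deduplicated.  With `realtime_budget`
#' set (a throughput factor: seconds of data processed per second), a
#' simulated processing clock abandons any window that could not finish
#' within two window durations of its acquisition; skipped spans are
#' reported in the output.
#'
#' @param recording a [raw_recording()].
#' @param bank a [template_bank()].
#' @param batch_len window length in samples (default 30000).
#' @param realtime_budget optional throughput factor (NULL = offline, no
#'   skipping; 0 = nothing can be processed).
#' @param context_samples filter context per window edge (default 512).
#' @return A [sorted_output()]; `skips` lists skipped 0-based sample spans.
#' @export
sort_stream <- function(recording, bank, batch_len = 30000,
                        realtime_budget = NULL, context_samples = 512L) {
  M <- dim(bank$templates)[2]
  n <- nrow(recording$data)
  fs <- recording$fs
  plan <- plan_batches(n, min(batch_len, n), M)
  if (min(batch_len, n) <= 4 * M) stop("recording too short for batch_len")
  uv_gain <- recording$gain
  all_events <- list()
  skips <- data.frame(start = numeric(0), end = numeric(0))
  clock <- 0
  for (w in seq_len(nrow(plan))) {
    s <- plan$start[w]; e <- plan$end[w]
    win_dur <- (e - s) / fs
    if (!is.null(realtime_budget)) {
      avail <- e / fs
      dur <- if (realtime_budget > 0) win_dur / realtime_budget else Inf
      start_t <- max(clock, avail)
      if (!is.finite(dur) || (start_t + dur) - avail > 2 * win_dur) {
        skips <- rbind(skips,
                       data.frame(start = plan$emit_start[w],
                                  end = plan$emit_end[w]))
        next
      }
      clock <- start_t + dur
    }
    ctx_l <- min(context_samples, s)
    ctx_r <- min(context_samples, n - e)
    seg <- recording$data[(s + 1L - ctx_l):(e + ctx_r), , drop = FALSE] * uv_gain
    pre <- preprocess_batch(seg, bank$preproc)
    pre <- pre[(ctx_l + 1L):(ctx_l + (e - s)), , drop = FALSE]
    mp <- run_matching_pursuit(pre, bank)
    ev <- mp$events
    if (!nrow(ev)) next
    gtime <- s + ev$time          # 1-based global sample index
    inside <- gtime - 1 >= plan$emit_start[w] & gtime - 1 < plan$emit_end[w]
    if (!any(inside)) next
    for (i in which(inside)) {
      loc <- localize_and_assign(
        list(time = gtime[i], template = ev$template[i],
             amplitude = ev$amplitude[i]), mp$features[[i]], bank)
      all_events[[length(all_events) + 1L]] <- loc
    }
  }
  if (length(all_events)) {
    df <- data.frame(
      time = vapply(all_events, `[[`, 0, "time"),
      template = vapply(all_events, `[[`, 0L, "template"),
      cluster = vapply(all_events, `[[`, 0L, "cluster"),
      amplitude = vapply(all_events, `[[`, 0, "amplitude"),
      x = vapply(all_events, `[[`, 0, "x"),
      y = vapply(all_events, `[[`, 0, "y"))
    df <- df[order(df$time), , drop = FALSE]
    df <- dedup_events(df, bank$min_isi_samples)
    sorted_output(df$time, df$cluster, df$template, df$amplitude,
                  cbind(df$x, df$y), fs = fs,
                  n_clusters = nrow(bank$centroids), skips = skips)
  } else {
    sorted_output(numeric(0), integer(0), integer(0), numeric(0),
                  matrix(numeric(0), ncol = 2), fs = fs,
                  n_clusters = nrow(bank$centroids), skips = skips)
  }
}
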