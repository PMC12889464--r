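#' Ground-truth unit
#'
#' Simulator-side description of one neuron: its spatiotemporal template,
#' baseline firing rate, refractory period, direction tuning and the
#' trough-to-peak width of its peak-channel waveform.
#'
#' @param unit_id integer id.
#' @param template M x C waveform in uV, M odd, trough at the center sample
#'   of the peak channel.
#' @param peak_channel 1-based channel index of the largest waveform.
#' @param rate_hz baseline firing rate.
#' @param refractory_ms absolute refractory period (> 0).
#' @param tuning list with `pref_deg` (preferred direction), `kappa`
#'   (concentration, >= 0) and `depth` (modulation depth).
#' @param waveform_width_us trough-to-peak time of the peak-channel
#'   waveform in microseconds.
#' @return An object of class `ground_truth_unit`.
#' @export
ground_truth_unit <- function(unit_id, template, peak_channel, rate_hz,
                              refractory_ms, tuning, waveform_width_us) {
  template <- as.matrix(template)
  if (nrow(template) %% 2L == 0L) stop("template length M must be odd")
  if (!all(is.finite(template))) stop("template must be finite")
  if (refractory_ms <= 0) stop("refractory_ms must be > 0")
  if (tuning$kappa < 0) stop("tuning kappa must be >= 0")
  structure(list(unit_id = as.integer(unit_id), template = template,
                 peak_channel = as.integer(peak_channel),
                 rate_hz = rate_hz, refractory_ms = refractory_ms,
                 tuning = tuning, waveform_width_us = waveform_width_us),
            class = "ground_truth_unit")
}

# biphasic difference-of-Gaussians temporal kernel; trough at the center
# sample, rebound peak `delta_samples` later
biphasic_kernel <- function(M, delta_samples, rebound = 0.4) {
  t <- seq_len(M) - (M + 1L) / 2L
  s1 <- max(1, 0.4 * delta_samples)
  s2 <- max(1.5, 0.6 * delta_samples)
  k <- -exp(-t^2 / (2 * s1^2)) +
    rebound * exp(-(t - delta_samples)^2 / (2 * s2^2))
  k / max(abs(k))
}

#' Generate synthetic spike templates
#'
#' Each template is a biphasic temporal kernel placed on a random peak
#' channel with amplitude decaying exponentially with channel distance.
#' The trough-to-peak width (us) is drawn from `width_range_us`, so both
#' fast-spiking (< 200 us) and regular-spiking classes can be produced by
#' choosing the range.
#'
#' @param geometry a [probe_geometry()].
#' @param K number of templates (>= 1).
#' @param seed RNG seed; same seed gives identical templates.
#' @param shape_params list with `amp_range` uV (default c(80, 150)),
#'   `decay_um` spatial decay constant (25), `width_range_us` (c(100, 500)),
#'   `M` samples (61), `rebound` second-phase ratio (0.4),
#'   `max_per_channel` allowed unit density per channel (3).
#' @param fs sampling rate used to convert widths to samples.
#' @return List of K M x C template matrices (uV), with attributes
#'   `peak_channel` and `width_us` on each.
#' @export
make_templates <- function(geometry, K, seed = 1,
                           shape_params = list(), fs = 30000) {
  p <- utils::modifyList(list(amp_range = c(80, 150), decay_um = 25,
                              width_range_us = c(100, 500), M = 61L,
                              rebound = 0.4, max_per_channel = 3), shape_params)
  C <- n_channels(geometry)
  if (K < 1L) stop("K must be >= 1")
  if (K > C * p$max_per_channel)
    stop(sprintf("K = %d exceeds %d channels x density %g", K, C, p$max_per_channel))
  dists <- channel_distances(geometry)
  set.seed(seed)
  # ground-truth units must be mutually distinguishable for benchmarking:
  # peak channels are drawn without replacement while channels last, and
  # widths are stratified (jittered grid) across the range so that no two
  # units share both location and waveform shape
  peaks <- if (K <= C) sample.int(C, K) else
    c(sample.int(C, C), sample.int(C, K - C, replace = TRUE))
  widths <- seq(p$width_range_us[1], p$width_range_us[2], length.out = K)
  if (K > 1L) {
    jit <- diff(p$width_range_us) / (4 * K)
    widths <- sample(widths) + stats::runif(K, -jit, jit)
    widths <- pmin(pmax(widths, p$width_range_us[1]), p$width_range_us[2])
  }
  lapply(seq_len(K), function(k) {
    peak <- peaks[k]
    amp <- stats::runif(1, p$amp_range[1], p$amp_range[2])
    width_us <- widths[k]
    delta <- width_us * fs / 1e6
    kern <- biphasic_kernel(p$M, delta, p$rebound)
    spatial <- amp * exp(-dists[peak, ] / p$decay_um)
    tmpl <- outer(kern, spatial)
    attr(tmpl, "peak_channel") <- peak
    attr(tmpl, "width_us") <- width_us
    tmpl
  })
}

#' Build a full synthetic unit population
#'
#' Convenience wrapper around [make_templates()] that attaches firing
#' rates, refractory periods and von Mises direction tuning to each
#' template, yielding a list of [ground_truth_unit()]s.
#'
#' @inheritParams make_templates
#' @param rate_range_hz baseline rate range (default c(5, 15)).
#' @param refractory_ms refractory period (default 2.5 ms).
#' @param kappa_range tuning concentration range (default c(1.5, 4)).
#' @param depth_range modulation depth range (default c(1, 3)).
#' @return list of [ground_truth_unit()].
#' @export
make_units <- function(geometry, K, seed = 1, shape_params = list(),
                       fs = 30000, rate_range_hz = c(5, 15),
                       refractory_ms = 2.5, kappa_range = c(1.5, 4),
                       depth_range = c(1, 3)) {
  templates <- make_templates(geometry, K, seed, shape_params, fs)
  set.seed(seed + 1000003L)
  lapply(seq_len(K), function(k) {
    tuning <- list(pref_deg = stats::runif(1, 0, 360) %% 360,
                   kappa = stats::runif(1, kappa_range[1], kappa_range[2]),
                   depth = stats::runif(1, depth_range[1], depth_range[2]))
    ground_truth_unit(
      unit_id = k, template = templates[[k]],
      peak_channel = attr(templates[[k]], "peak_channel"),
      rate_hz = stats::runif(1, rate_range_hz[1], rate_range_hz[2]),
      refractory_ms = refractory_ms, tuning = tuning,
      waveform_width_us = attr(templates[[k]], "width_us"))
  })
}

#' Build a trial/presentation table
#'
#' Trials follow the fixation-task structure: three stimulus presentations
#' per trial, each 0.25 s, separated by 0.15 s, drawn from twelve motion
#' directions in 30 degree steps.  Each row is one presentation.
#'
#' @param n_trials number of trials (3 presentations each).
#' @param fs sampling rate.
#' @param start_s time of the first trial onset (default 2 s).
#' @param stim_s,isi_s presentation duration and inter-stimulus interval.
#' @param iti_s inter-trial interval after the last presentation.
#' @param seed seed for the direction shuffle.
#' @return data.frame with `onset_sample` (1-based), `direction_deg`,
#'   `condition`; attribute `stim_samples` holds the presentation length.
#' @export
make_trials <- function(n_trials, fs = 30000, start_s = 2, stim_s = 0.25,
                        isi_s = 0.15, iti_s = 0.5, seed = 1) {
  set.seed(seed)
  n_pres <- 3L * n_trials
  dirs <- rep(seq(0, 330, by = 30), length.out = n_pres)
  dirs <- sample(dirs)
  onsets <- numeric(n_pres)
  t0 <- start_s
  for (tr in seq_len(n_trials)) {
    for (j in 1:3) {
      onsets[(tr - 1L) * 3L + j] <- t0
      t0 <- t0 + stim_s + isi_s
    }
    t0 <- t0 - isi_s + iti_s
  }
  out <- data.frame(onset_sample = round(onsets * fs) + 1,
                    direction_deg = dirs, condition = "stim")
  attr(out, "stim_samples") <- round(stim_s * fs)
  out
}

# von Mises rate multiplier during a presentation of direction theta
tuning_gain <- function(theta_deg, tuning) {
  d <- (theta_deg - tuning$pref_deg) * pi / 180
  1 + tuning$depth * exp(tuning$kappa * (cos(d) - 1))
}

# inhomogeneous Poisson by thinning with sequential refractory deletion
sim_train <- function(rate_fun, rate_max, from_s, to_s, refractory_s) {
  span <- to_s - from_s
  if (span <= 0 || rate_max <= 0) return(numeric(0))
  n <- stats::rpois(1, rate_max * span)
  if (n == 0L) return(numeric(0))
  t <- sort(stats::runif(n, from_s, to_s))
  keep <- stats::runif(n) < rate_fun(t) / rate_max
  t <- t[keep]
  if (!length(t)) return(numeric(0))
  out <- numeric(length(t)); m <- 0L; last <- -Inf
  for (ti in t) {
    if (ti - last >= refractory_s) {
      m <- m + 1L; out[m] <- ti; last <- ti
    }
  }
  out[seq_len(m)]
}

#' Simulate ground-truth spike trains
#'
#' Each unit fires as an inhomogeneous Poisson process with refractory
#' deletion.  During a presentation of direction theta the rate is
#' `rate_hz * (1 + depth * exp(kappa * (cos(theta - pref) - 1)))`;
#' elsewhere it is the baseline.  An optional multiplicative gain trace
#' modulates selected units (used by [simulate_state_session()]).
#'
#' @param units list of [ground_truth_unit()].
#' @param duration_s recording duration.
#' @param trials presentation table from [make_trials()] (or NULL).
#' @param fs sampling rate.
#' @param seed RNG seed; fixed seed gives identical trains.
#' @param edge_margin_s no spikes closer than this to either end (keeps
#'   every ground-truth spike fully renderable; default 0.01 s).
#' @param gain_trace optional data.frame (`t`, `gain`) step function.
#' @param gain_unit_ids unit ids the gain trace applies to.
#' @return An object of class `ground_truth`: list with `units`, `spikes`
#'   (per-unit sorted spike times in samples, 1-based), `trials`, `fs`,
#'   `duration_s`, `state` (the gain trace or NULL).
#' @export
simulate_trains <- function(units, duration_s, trials = NULL, fs = 30000,
                            seed = 1, edge_margin_s = 0.01,
                            gain_trace = NULL, gain_unit_ids = integer(0)) {
  if (!is.null(trials) && nrow(trials)) {
    stim_samp <- attr(trials, "stim_samples")
    if (is.null(stim_samp)) stim_samp <- round(0.25 * fs)
    last_end <- max(trials$onset_sample) + stim_samp
    if (last_end > duration_s * fs)
      stop("duration does not cover all trials")
  }
  set.seed(seed)
  spikes <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    if (u$rate_hz < 0) stop("rates must be >= 0")
    stim_gain <- function(t_s) {
      g <- rep(1, length(t_s))
      if (!is.null(trials) && nrow(trials)) {
        on_s <- (trials$onset_sample - 1) / fs
        stim_s <- (if (is.null(attr(trials, "stim_samples")))
          round(0.25 * fs) else attr(trials, "stim_samples")) / fs
        idx <- findInterval(t_s, on_s)
        hit <- idx >= 1 & (t_s - on_s[pmax(idx, 1)]) < stim_s
        if (any(hit))
          g[hit] <- tuning_gain(trials$direction_deg[idx[hit]], u$tuning)
      }
      g
    }
    state_gain <- function(t_s) {
      if (is.null(gain_trace) || !(u$unit_id %in% gain_unit_ids))
        return(rep(1, length(t_s)))
      gain_trace$gain[pmax(findInterval(t_s, gain_trace$t), 1L)]
    }
    rate_fun <- function(t_s) u$rate_hz * stim_gain(t_s) * state_gain(t_s)
    gmax <- if (!is.null(gain_trace) && (u$unit_id %in% gain_unit_ids))
      max(gain_trace$gain) else 1
    rate_max <- u$rate_hz * (1 + u$tuning$depth) * gmax
    t_s <- sim_train(rate_fun, rate_max, edge_margin_s,
                     duration_s - edge_margin_s, u$refractory_ms / 1000)
    spikes[[i]] <- round(t_s * fs) + 1
    # rounding to samples must not break the refractory invariant
    if (length(spikes[[i]]) > 1L) {
      isi_min <- max(1, floor(u$refractory_ms / 1000 * fs))
      keep <- c(TRUE, diff(spikes[[i]]) >= isi_min)
      spikes[[i]] <- spikes[[i]][keep]
    }
  }
  structure(list(units = units, spikes = spikes, trials = trials, fs = fs,
                 duration_s = duration_s, state = gain_trace),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d units, %.1f s, %d spikes%s\n",
              length(x$units), x$duration_s,
              sum(lengths(x$spikes)),
              if (is.null(x$trials)) "" else
                sprintf(", %d presentations", nrow(x$trials))))
  invisible(x)
}

#' Render a ground-truth recording
#'
#' Superposes each unit's template at its spike times (trough aligned to
#' the spike sample), optionally jitters per-spike amplitude, adds
#' Gaussian noise, and quantizes to int16 at a gain chosen so the largest
#' template uses about 25% of the integer range.  Spikes whose template
#' would overhang the recording edge are dropped and counted in the
#' `dropped_spikes` attribute.
#'
#' @param ground_truth a [simulate_trains()] result.
#' @param geometry a [probe_geometry()].
#' @param noise_sd noise SD in uV (>= 0).
#' @param amp_jitter per-spike amplitude jitter half-width in `[0, 1)`;
#'   scales are uniform on `1 +/- amp_jitter`.
#' @param seed RNG seed.
#' @param gain uV per count; default from the template amplitudes.
#' @param correlated_noise if TRUE, noise is spatially smoothed across
#'   channels with a Gaussian kernel of scale `noise_corr_um` (and
#'   rescaled to keep the per-channel SD at `noise_sd`).
#' @param noise_corr_um spatial correlation scale of the noise.
#' @return A [raw_recording()]; attribute `dropped_spikes` counts edge
#'   drops per unit, attribute `float_data` is NULL unless
#'   `keep_float = TRUE`.
#' @param keep_float keep the pre-quantization uV matrix as an attribute
#'   (for exactness checks on small renders).
#' @export
render_recording <- function(ground_truth, geometry, noise_sd = 15,
                             amp_jitter = 0.1, seed = 1, gain = NULL,
                             correlated_noise = FALSE, noise_corr_um = 30,
                             keep_float = FALSE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (amp_jitter < 0 || amp_jitter >= 1) stop("amp_jitter must be in [0, 1)")
  gt <- ground_truth
  fs <- gt$fs
  T <- round(gt$duration_s * fs)
  C <- n_channels(geometry)
  set.seed(seed)
  x <- matrix(0, T, C)
  dropped <- integer(length(gt$units))
  for (i in seq_along(gt$units)) {
    u <- gt$units[[i]]
    M <- nrow(u$template); center <- (M - 1L) %/% 2L
    st <- gt$spikes[[i]]
    ok <- st - center >= 1 & st + center <= T
    dropped[i] <- sum(!ok)
    scales <- if (amp_jitter > 0)
      stats::runif(length(st), 1 - amp_jitter, 1 + amp_jitter)
    else rep(1, length(st))
    for (j in which(ok)) {
      rows <- (st[j] - center):(st[j] + center)
      x[rows, ] <- x[rows, ] + scales[j] * u$template
    }
  }
  if (any(dropped > 0))
    message(sum(dropped), " spike(s) dropped at recording edges")
  if (noise_sd > 0) {
    noise <- matrix(stats::rnorm(T * C, sd = noise_sd), T, C)
    if (correlated_noise) {
      Wn <- exp(-channel_distances(geometry)^2 / (2 * noise_corr_um^2))
      noise <- noise %*% t(Wn)
      noise <- sweep(noise, 2L, sqrt(rowSums(Wn^2)), "/")
    }
    x <- x + noise
  }
  if (is.null(gain)) {
    peak <- max(vapply(gt$units, function(u) max(abs(u$template)), 0))
    gain <- (peak / 0.25) / 32767
  }
  q <- round(x / gain)
  if (any(abs(q) > 32767)) stop("quantization clipped; increase gain")
  rec <- raw_recording(q, fs = fs, gain = gain, geometry = geometry)
  attr(rec, "dropped_spikes") <- dropped
  if (keep_float) attr(rec, "float_data") <- x
  rec
}

#' Build a mixed fast-spiking / regular-spiking population
#'
#' Convenience builder for closed-loop benchmarks: `n_fs` units with
#' narrow waveforms (trough-to-peak below 200 us) and `n_rs` units with
#' broad waveforms, with unit ids renumbered consecutively.
#'
#' @param geometry a [probe_geometry()].
#' @param n_fs,n_rs subpopulation sizes (defaults 6 and 4).
#' @param seed RNG seed.
#' @param fs_width_us,rs_width_us width ranges (defaults c(110, 180) and
#'   c(320, 480)).
#' @param fs_rate_hz,rs_rate_hz baseline rate ranges.
#' @return list of [ground_truth_unit()].
#' @export
closedloop_population <- function(geometry, n_fs = 6L, n_rs = 4L, seed = 1,
                                  fs_width_us = c(110, 180),
                                  rs_width_us = c(320, 480),
                                  fs_rate_hz = c(10, 15),
                                  rs_rate_hz = c(6, 10)) {
  fs_units <- make_units(geometry, n_fs, seed = seed,
                         shape_params = list(width_range_us = fs_width_us),
                         rate_range_hz = fs_rate_hz)
  rs_units <- make_units(geometry, n_rs, seed = seed + 7L,
                         shape_params = list(width_range_us = rs_width_us),
                         rate_range_hz = rs_rate_hz)
  out <- c(fs_units, rs_units)
  for (i in seq_along(out)) out[[i]]$unit_id <- as.integer(i)
  out
}

#' Take the leading seconds of a recording
#'
#' @param rec a [raw_recording()].
#' @param seconds duration to keep from the start.
#' @return A [raw_recording()] over the first `seconds`.
#' @export
first_seconds <- function(rec, seconds) {
  n <- min(nrow(rec$data), round(seconds * rec$fs))
  raw_recording(rec$data[seq_len(n), , drop = FALSE], fs = rec$fs,
                gain = rec$gain, geometry = rec$geometry)
}

# two-state Markov gain trace on a dt grid
markov_gain_trace <- function(duration_s, dt = 0.01, levels = c(1, 2.5),
                              dwell_s = c(1.2, 0.8)) {
  n <- ceiling(duration_s / dt)
  state <- integer(n); state[1] <- 1L
  p_up <- dt / dwell_s[1]; p_dn <- dt / dwell_s[2]
  u <- stats::runif(n)
  for (i in 2:n) {
    state[i] <- if (state[i - 1L] == 1L) {
      if (u[i] < p_up) 2L else 1L
    } else {
      if (u[i] < p_dn) 1L else 2L
    }
  }
  data.frame(t = (seq_len(n) - 1L) * dt, gain = levels[state])
}

#' Simulate a session with a fluctuating population state
#'
#' Generates a spontaneous recording in which a latent two-state Markov
#' gain multiplies the firing rate of the fast-spiking subpopulation
#' (units with waveform width < 200 us), together with a closed-loop trial
#' schedule (fixation start times; a random subset are control trials).
#' The latent gain trace is recorded in the returned ground truth, so a
#' 2 SD trigger rule applied to the sorted rates selects genuinely
#' elevated states.
#'
#' @param units list of [ground_truth_unit()].
#' @param geometry a [probe_geometry()].
#' @param state_params list: `duration_s` (total), `baseline_s` (state-free
#'   lead-in used for baseline statistics, default 30), `levels` gain
#'   levels (c(1, 2.5)), `dwell_s` mean dwell times low/high (c(1.2, 0.8)),
#'   `dt` gain grid (0.01 s), `n_trials` (200), `trial_pitch_s` (1.5),
#'   `control_frac` (1/3), `fixation_max_s` (1).
#' @param seed RNG seed.
#' @param noise_sd,amp_jitter passed to [render_recording()].
#' @return list with `recording` (a [raw_recording()]) and `ground_truth`
#'   (with `state` = the gain trace and `trials` = the fixation schedule:
#'   `fix_start_sample`, `direction_deg`, `is_control`).
#' @export
simulate_state_session <- function(units, geometry, state_params = list(),
                                   seed = 1, noise_sd = 15, amp_jitter = 0.1) {
  p <- utils::modifyList(list(duration_s = NULL, baseline_s = 30,
                              levels = c(1, 2.5), dwell_s = c(1.2, 0.8),
                              dt = 0.01, n_trials = 200, trial_pitch_s = 1.5,
                              control_frac = 1 / 3, fixation_max_s = 1),
                         state_params)
  fs <- 30000
  if (is.null(p$duration_s))
    p$duration_s <- p$baseline_s + p$n_trials * p$trial_pitch_s + 2
  set.seed(seed)
  # the baseline epoch shares the state process: baseline statistics must
  # sample the natural state distribution, or the 2 SD trigger threshold
  # would sit inside the ordinary fluctuation range
  trace <- markov_gain_trace(p$duration_s, p$dt, p$levels, p$dwell_s)
  fs_ids <- vapply(units, function(u) u$waveform_width_us < 200, TRUE)
  gain_ids <- vapply(units[fs_ids], function(u) u$unit_id, 0L)
  gt <- simulate_trains(units, p$duration_s, trials = NULL, fs = fs,
                        seed = seed + 1L, gain_trace = trace,
                        gain_unit_ids = gain_ids)
  set.seed(seed + 2L)
  n_tr <- p$n_trials
  trials <- data.frame(
    fix_start_sample = round((p$baseline_s +
      (seq_len(n_tr) - 1L) * p$trial_pitch_s) * fs) + 1,
    direction_deg = sample(rep(seq(0, 330, by = 30), length.out = n_tr)),
    is_control = stats::runif(n_tr) < p$control_frac)
  gt$trials <- trials
  attr(gt$trials, "fixation_max_s") <- p$fixation_max_s
  rec <- render_recording(gt, geometry, noise_sd = noise_sd,
                          amp_jitter = amp_jitter, seed = seed + 3L)
  list(recording = rec, ground_truth = gt)
}
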