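# build a bank whose two templates have controlled trough-to-peak widths
width_bank <- function(width1_us, width2_us) {
  geometry <- tiny_geom(8L)
  t1 <- make_templates(geometry, 1, seed = 81,
                       shape_params = list(width_range_us = rep(width1_us, 2)))[[1]]
  t2 <- make_templates(geometry, 1, seed = 82,
                       shape_params = list(width_range_us = rep(width2_us, 2)))[[1]]
  K <- 2L; M <- nrow(t1); C <- 8L
  templates <- array(0, dim = c(K, M, C))
  templates[1, , ] <- t1; templates[2, , ] <- t2
  Z <- rbind(t(t1), t(t2))
  sv <- svd(Z, nu = 0)
  P <- sum(sv$d > 1e-10 * sv$d[1])
  basis <- t(sv$v[, seq_len(P), drop = FALSE])
  proj <- crossprod(basis)
  for (k in 1:K) templates[k, , ] <- proj %*% templates[k, , ]
  peaks <- vapply(1:K, function(k)
    which.max(apply(abs(templates[k, , ]), 2, max)), 0L)
  tf <- array(0, dim = c(K, P, C)); cen <- matrix(0, K, P * C)
  for (k in 1:K) {
    Fm <- basis %*% templates[k, , ]
    tf[k, , ] <- Fm; cen[k, ] <- as.vector(Fm)
  }
  template_bank(templates, basis, tf, compute_pair_cc(templates), 0.05, cen,
                1:K, 15L, preproc_spec(30000, 8), geometry, peaks)
}

test_that("waveform widths split FS and RS at a strict 200 us boundary", {
  bank <- width_bank(150, 400)
  cls <- classify_waveforms(bank)
  expect_equal(cls$label, c("FS", "RS"))
  expect_lt(cls$trough_to_peak_us[1], 200)
  # 200 us at 30 kHz is exactly 6 samples: widths quantize to multiples
  # of 1/30 ms, so a 6-sample separation must classify as RS (strict <)
  M <- 61L; C <- 4L
  geometry <- tiny_geom(C)
  tm <- array(0, dim = c(1, M, C))
  tm[1, 31, 1] <- -1; tm[1, 37, 1] <- 0.5    # peak 6 samples after trough
  bank2 <- template_bank(tm, matrix(c(rep(0, 30), -1, rep(0, 5), 0.5,
                                      rep(0, 24)) / sqrt(1.25), 1, M),
                         array(0, dim = c(1, 1, C)), compute_pair_cc(tm),
                         0.05, matrix(0, 1, C), 1L, 15L,
                         preproc_spec(30000, C), geometry, 1L)
  cls2 <- classify_waveforms(bank2)
  expect_equal(cls2$trough_to_peak_us, 200)
  expect_equal(cls2$label, "RS")
  # a monophasic template warns and lands in RS
  tm3 <- tm; tm3[1, 37, 1] <- -0.2
  bank3 <- bank2; bank3$templates <- tm3
  expect_warning(cls3 <- classify_waveforms(bank3), "monophasic")
  expect_equal(cls3$label, "RS")
})

# synthetic sorted output with a given FS-population rate profile
rate_profile_sorted <- function(rate_fun, duration_s, fs = 30000,
                                n_units = 4L, seed = 1) {
  set.seed(seed)
  tmax <- duration_s
  times <- numeric(0); clusters <- integer(0)
  for (u in seq_len(n_units)) {
    t <- 0
    while (t < tmax) {
      r <- max(rate_fun(t), 1e-9)
      t <- t + rexp(1, r)
      if (t < tmax) {
        times <- c(times, round(t * fs) + 1)
        clusters <- c(clusters, u)
      }
    }
  }
  ord <- order(times)
  sorted_output(times[ord], clusters[ord], clusters[ord],
                rep(1, length(times)), cbind(numeric(length(times)),
                                             numeric(length(times))),
                fs = fs, n_clusters = n_units)
}

test_that("the 2 SD rule triggers on rate steps and never on flat rates", {
  fs <- 30000
  cfg <- trigger_config()
  trials <- data.frame(fix_start_sample = seq(10 * fs, by = 2 * fs,
                                              length.out = 20) + 1,
                       direction_deg = rep(seq(0, 330, 60),
                                           length.out = 20),
                       is_control = FALSE)
  # deterministic session: baseline counts alternate 2/3 spikes per
  # 100 ms window (sd > 0), fixation windows hold exactly 1 spike per
  # 50 ms window (20 Hz, far below mean + 2 SD)
  base_t <- unlist(lapply(0:99, function(w) {
    n <- if (w %% 2 == 0) 2 else 3
    w * 3000 + seq_len(n) * 700
  }))
  fix_t <- unlist(lapply(seq_len(nrow(trials)), function(i)
    trials$fix_start_sample[i] + seq(0, by = 1500, length.out = 40) + 200))
  mk_sorted <- function(times) {
    times <- sort(times)
    sorted_output(times, rep(1L, length(times)), rep(1L, length(times)),
                  rep(1, length(times)), matrix(0, length(times), 2),
                  fs = fs, n_clusters = 1L)
  }
  flat <- mk_sorted(c(base_t, fix_t))
  tt <- run_trigger_session(flat, NULL, fs_units = 1L, cfg, trials,
                            seed = 4)
  expect_true(all(tt$condition == "non_triggered"))
  expect_true(all(tt$onset_sample == trials$fix_start_sample + fs))
  # a strong burst 300 ms into trial 1 triggers in that window
  burst <- trials$fix_start_sample[1] + 0.3 * fs + seq_len(15) * 60
  tt2 <- run_trigger_session(mk_sorted(c(base_t, fix_t, burst)), NULL,
                             fs_units = 1L, cfg, trials, seed = 5)
  expect_equal(tt2$condition[1], "triggered")
  expect_true(tt2$trigger_latency_ms[1] >= 300 &&
                tt2$trigger_latency_ms[1] <= 400)
  expect_true(all(tt2$condition[-1] == "non_triggered"))
  # an infinite threshold never triggers
  cfg_inf <- trigger_config(threshold_sd = Inf)
  tt3 <- run_trigger_session(mk_sorted(c(base_t, fix_t, burst)), NULL,
                             fs_units = 1L, cfg_inf, trials, seed = 6)
  expect_true(all(tt3$condition == "non_triggered"))
  # a zero-variance baseline is refused
  const <- mk_sorted(seq(1, 10 * fs, by = fs / 10))
  expect_error(run_trigger_session(const, NULL, 1L, cfg, trials, seed = 8),
               "SD is zero")
})

test_that("trigger decisions depend only on the FS-labeled units", {
  fs <- 30000
  cfg <- trigger_config()
  trials <- data.frame(fix_start_sample = seq(10 * fs, by = 2 * fs,
                                              length.out = 15) + 1,
                       direction_deg = 0, is_control = FALSE)
  set.seed(9)
  base <- rate_profile_sorted(function(t) 15 + 10 * sin(t), 45, n_units = 2L,
                              seed = 10)
  # add RS units as clusters 3 and 4
  rs <- rate_profile_sorted(function(t) 30, 45, n_units = 2L, seed = 11)
  comb <- sorted_output(
    c(base$times, rs$times)[order(c(base$times, rs$times))],
    c(base$clusters, rs$clusters + 2L)[order(c(base$times, rs$times))],
    c(base$templates, rs$templates + 2L)[order(c(base$times, rs$times))],
    rep(1, length(base$times) + length(rs$times)),
    matrix(0, length(base$times) + length(rs$times), 2),
    fs = fs, n_clusters = 4L)
  t1 <- run_trigger_session(comb, NULL, fs_units = 1:2, cfg, trials, seed = 12)
  # perturb the RS trains (clusters 3-4) entirely: FS spikes identical,
  # RS spikes replaced by arbitrary new trains
  keep <- comb$clusters <= 2L
  set.seed(13)
  fs_t <- comb$times[keep]; fs_c <- comb$clusters[keep]
  rs_t <- sort(sample.int(45 * fs, 2000)); rs_c <- rep(3:4, 1000)
  ord <- order(c(fs_t, rs_t))
  comb2 <- sorted_output(c(fs_t, rs_t)[ord], c(fs_c, rs_c)[ord],
                         c(fs_c, rs_c)[ord], rep(1, length(ord)),
                         matrix(0, length(ord), 2), fs = fs, n_clusters = 4L)
  t2 <- run_trigger_session(comb2, NULL, fs_units = 1:2, cfg, trials,
                            seed = 12)
  expect_equal(t1$condition, t2$condition)
  expect_equal(t1$onset_sample, t2$onset_sample)
})

test_that("pre-stimulus analysis computes rates, normalization and exclusions", {
  fs <- 30000
  # unit 1: pre-stim 40 Hz, evoked 80 Hz (normalized 2); unit 2: zero
  # pre-stimulus activity, evoked only
  onsets <- seq(5 * fs, by = 2 * fs, length.out = 40) + 1
  cond <- rep(c("triggered", "non_triggered"), each = 20)
  mk_times <- function(on, i, pre = TRUE) {
    n_pre <- if (pre) { if (i %% 2 == 0) 3 else 5 } else 0   # mean 4 / 0.1 s
    n_ev <- if (i %% 2 == 0) 14 else 18                      # mean 16 / 0.2 s
    c(if (n_pre) on - seq_len(n_pre) * 400 else numeric(0),
      on + 0.05 * fs + seq_len(n_ev) * 300)
  }
  t1 <- sort(unlist(lapply(seq_along(onsets), function(i)
    mk_times(onsets[i], i, pre = TRUE))))
  t2 <- sort(unlist(lapply(seq_along(onsets), function(i)
    mk_times(onsets[i], i, pre = FALSE))))
  allt <- c(t1, t2); cl <- c(rep(1L, length(t1)), rep(2L, length(t2)))
  ord <- order(allt)
  so <- sorted_output(allt[ord], cl[ord], cl[ord], rep(1, length(allt)),
                      matrix(0, length(allt), 2), fs = fs, n_clusters = 2L)
  trials <- data.frame(onset_sample = onsets, condition = cond)
  classes <- data.frame(template = 1:2, trough_to_peak_us = c(150, 400),
                        label = c("FS", "RS"))
  res <- analyze_prestim(so, trials, classes)
  u1 <- res$unit_summary[res$unit_summary$unit == 1, ]
  expect_equal(u1$prestim_hz, c(40, 40), tolerance = 1e-9)
  expect_equal(u1$evoked_hz, c(80, 80), tolerance = 1e-9)
  expect_equal(u1$normalized, c(2, 2), tolerance = 1e-9)
  # zero pre-stimulus unit excluded from the normalized summary only
  u2 <- res$unit_summary[res$unit_summary$unit == 2, ]
  expect_true(all(is.na(u2$normalized)))
  expect_true(all(u2$evoked_hz > 0))
  # identical trial statistics across conditions: no detectable effect
  expect_true(all(res$condition_tests$p_prestim > 0.2))
})

test_that("exceedance curves compare conditions over a common threshold grid", {
  rates <- list(triggered = c(10, 12, 15, 20), control = c(2, 3, 5, 9))
  ec <- exceedance_curve(rates, thresholds = c(0, 5, 10, 15))
  expect_equal(ec$triggered, c(1, 1, 0.75, 0.25))
  expect_equal(ec$control, c(1, 0.25, 0, 0))
  expect_true(all(ec$triggered >= ec$control))
})
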