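test_that("template widths convert to the expected trough-to-peak samples", {
  geom <- tiny_geom(8L)
  tmpl <- make_templates(geom, K = 3, seed = 1,
                         shape_params = list(width_range_us = c(150, 150)),
                         fs = 30000)
  for (tm in tmpl) {
    pk <- attr(tm, "peak_channel")
    w <- tm[, pk]
    trough <- which.min(w)
    peak <- trough + which.max(w[trough:length(w)]) - 1L
    # 150 us at 30 kHz is 4.5 samples
    expect_true((peak - trough) %in% 4:5)
  }
})

test_that("template amplitude decays strictly with channel distance", {
  geom <- tiny_geom(8L)
  tmpl <- make_templates(geom, K = 2, seed = 3, fs = 30000)
  dists <- as.matrix(dist(cbind(geom$x, geom$y)))
  for (tm in tmpl) {
    pk <- attr(tm, "peak_channel")
    amp_by_ch <- apply(abs(tm), 2, max)
    d <- dists[pk, ]
    ord <- order(d)
    # strictly decreasing over strictly increasing distances
    dd <- d[ord]; aa <- amp_by_ch[ord]
    strict <- dd[-1] > dd[-length(dd)]
    expect_true(all(aa[-1][strict] < aa[-length(aa)][strict]))
  }
})

test_that("template generation is deterministic and bounded by density", {
  geom <- tiny_geom(4L)
  t1 <- make_templates(geom, K = 3, seed = 9)
  t2 <- make_templates(geom, K = 3, seed = 9)
  expect_equal(t1, t2)
  expect_error(make_templates(geom, K = 13, seed = 1), "density")
})

test_that("homogeneous trains have Poisson-scale counts and obey refractoriness", {
  geom <- tiny_geom(4L)
  u <- ground_truth_unit(1L, make_templates(geom, 1, seed = 1)[[1]],
                         peak_channel = 1L, rate_hz = 10,
                         refractory_ms = 2.5,
                         tuning = list(pref_deg = 0, kappa = 0, depth = 0),
                         waveform_width_us = 200)
  gt <- simulate_trains(list(u), duration_s = 100, fs = 30000, seed = 11)
  n <- length(gt$spikes[[1]])
  # 5 SD of a Poisson(1000) count (refractory deletion trims ~2.5%)
  expect_lt(abs(n - 1000), 5 * sqrt(1000) + 25)
  expect_true(all(diff(gt$spikes[[1]]) >= floor(2.5e-3 * 30000)))
})

test_that("direction tuning of simulated trains matches the generating rate", {
  geom <- tiny_geom(4L)
  tm <- make_templates(geom, 1, seed = 2)[[1]]
  trials <- make_trials(n_trials = 240, fs = 30000, seed = 5)
  mk <- function(kappa, depth, pref) {
    u <- ground_truth_unit(1L, tm, 1L, rate_hz = 20, refractory_ms = 1,
                           tuning = list(pref_deg = pref, kappa = kappa,
                                         depth = depth),
                           waveform_width_us = 200)
    dur <- (max(trials$onset_sample) + 30000) / 30000
    simulate_trains(list(u), duration_s = dur, trials = trials, fs = 30000,
                    seed = 21)
  }
  rate_by_dir <- function(gt) {
    sapply(sort(unique(trials$direction_deg)), function(dd) {
      on <- trials$onset_sample[trials$direction_deg == dd]
      mean(vapply(on, function(o)
        sum(gt$spikes[[1]] >= o & gt$spikes[[1]] < o + 0.25 * 30000), 0)) / 0.25
    })
  }
  # kappa = 0: stimulus rate independent of direction (oracle: the
  # generating rate function is flat across directions)
  flat <- rate_by_dir(mk(0, 2, 90))
  expect_lt(diff(range(flat)) / mean(flat), 0.35)
  # depth = 2, kappa = 4: empirical peak within one 30-degree step of pref
  tuned <- rate_by_dir(mk(4, 2, 120))
  dirs <- sort(unique(trials$direction_deg))
  peak_dir <- dirs[which.max(tuned)]
  dd <- min(abs(peak_dir - 120), 360 - abs(peak_dir - 120))
  expect_lte(dd, 30)
  # and the curve correlates with the generating profile
  oracle <- 20 * (1 + 2 * exp(4 * (cos((dirs - 120) * pi / 180) - 1)))
  expect_gt(cor(tuned, oracle), 0.9)
})

test_that("zero-noise rendering reproduces the template exactly", {
  geom <- tiny_geom(4L)
  tm <- make_templates(geom, 1, seed = 4, shape_params = list(M = 21L))[[1]]
  u <- ground_truth_unit(1L, tm, attr(tm, "peak_channel"), 5, 2,
                         list(pref_deg = 0, kappa = 0, depth = 0), 200)
  gt <- manual_ground_truth(list(u), list(1000), duration_s = 0.1)
  rec <- render_recording(gt, geom, noise_sd = 0, amp_jitter = 0, seed = 1,
                          keep_float = TRUE)
  seg <- attr(rec, "float_data")[990:1010, ]
  expect_equal(seg, unclass(tm)[, ], ignore_attr = TRUE)
  # quantized data agree to within half a count
  segq <- rec$data[990:1010, ] * rec$gain
  expect_lt(max(abs(segq - tm)), rec$gain / 2 + 1e-12)
})

test_that("rendered noise has the requested per-channel SD", {
  geom <- tiny_geom(4L)
  u <- ground_truth_unit(1L, make_templates(geom, 1, seed = 1)[[1]], 1L, 5, 2,
                         list(pref_deg = 0, kappa = 0, depth = 0), 200)
  gt <- manual_ground_truth(list(u), list(numeric(0)), duration_s = 60)
  rec <- render_recording(gt, geom, noise_sd = 5, amp_jitter = 0, seed = 2,
                          gain = 0.01)
  sds <- apply(rec$data * rec$gain, 2, sd)
  expect_true(all(abs(sds - 5) / 5 < 0.05))
})

test_that("overlapping spikes superpose linearly (brute-force oracle)", {
  geom <- tiny_geom(4L)
  tms <- make_templates(geom, 2, seed = 6, shape_params = list(M = 21L))
  us <- lapply(1:2, function(k)
    ground_truth_unit(k, tms[[k]], attr(tms[[k]], "peak_channel"), 5, 2,
                      list(pref_deg = 0, kappa = 0, depth = 0), 200))
  gt <- manual_ground_truth(us, list(500, 508), duration_s = 0.05)
  rec <- render_recording(gt, geom, noise_sd = 0, amp_jitter = 0, seed = 1,
                          keep_float = TRUE)
  x <- attr(rec, "float_data")
  oracle <- matrix(0, nrow(x), 4)
  for (k in 1:2) {
    rows <- (gt$spikes[[k]] - 10):(gt$spikes[[k]] + 10)
    oracle[rows, ] <- oracle[rows, ] + unclass(tms[[k]])[, ]
  }
  expect_equal(x, oracle)
})

test_that("edge spikes are dropped with a count", {
  geom <- tiny_geom(4L)
  tm <- make_templates(geom, 1, seed = 4, shape_params = list(M = 21L))[[1]]
  u <- ground_truth_unit(1L, tm, 1L, 5, 2,
                         list(pref_deg = 0, kappa = 0, depth = 0), 200)
  gt <- manual_ground_truth(list(u), list(c(5, 500)), duration_s = 0.05)
  expect_message(rec <- render_recording(gt, geom, noise_sd = 0,
                                         amp_jitter = 0, seed = 1),
                 "dropped")
  expect_equal(attr(rec, "dropped_spikes"), 1L)
})

test_that("state sessions are reproducible and track the latent gain", {
  geom <- tiny_geom(4L)
  units <- make_units(geom, K = 3, seed = 5,
                      shape_params = list(width_range_us = c(120, 180)),
                      rate_range_hz = c(15, 25))
  sp <- list(duration_s = 40, baseline_s = 5, n_trials = 10,
             levels = c(1, 2.5))
  s1 <- simulate_state_session(units, geom, sp, seed = 7)
  s2 <- simulate_state_session(units, geom, sp, seed = 7)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_equal(s1$ground_truth$state, s2$ground_truth$state)
  # oracle: firing rate in high-gain epochs exceeds low-gain epochs by
  # roughly the gain ratio (all units here are FS-width, all modulated)
  gt <- s1$ground_truth
  trace <- gt$state
  all_sp <- unlist(gt$spikes) / 30000
  occ_hi <- sum(trace$gain > 1) * 0.01
  occ_lo <- sum(trace$gain == 1) * 0.01
  in_hi <- sum(trace$gain[pmax(findInterval(all_sp, trace$t), 1)] > 1)
  rate_hi <- in_hi / occ_hi
  rate_lo <- (length(all_sp) - in_hi) / occ_lo
  expect_gt(rate_hi / rate_lo, 1.7)
})

test_that("a unit gain of one reduces the state session to plain trains", {
  geom <- tiny_geom(4L)
  units <- make_units(geom, K = 2, seed = 5,
                      shape_params = list(width_range_us = c(120, 180)))
  sp <- list(duration_s = 30, baseline_s = 2, n_trials = 5, levels = c(1, 1))
  s <- simulate_state_session(units, geom, sp, seed = 9)
  plain <- simulate_trains(units, 30, fs = 30000, seed = 10)
  r_state <- sum(lengths(s$ground_truth$spikes)) / 30
  r_plain <- sum(lengths(plain$spikes)) / 30
  expect_lt(abs(r_state - r_plain) / r_plain, 0.2)
})
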