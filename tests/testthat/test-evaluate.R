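test_that("match scores follow the 1 - FP - FM definition", {
  a <- sort(sample.int(300000, 200)) ; a <- a[c(TRUE, diff(a) > 40)]
  # identical trains
  m <- match_units(list(a), list(a), tol_samples = 15)
  expect_equal(m$assignment$score, 1)
  expect_equal(m$assignment$FP, 0)
  # half the spikes deleted from the reference side
  b <- a[seq_along(a) %% 2 == 1]
  m2 <- match_units(list(b), list(a), tol_samples = 15)
  expect_equal(m2$assignment$FP, 0)
  expect_equal(m2$assignment$FM, 1 - length(b) / length(a), tolerance = 1e-9)
  # 9 of 10 matched sits exactly at the 0.8 boundary and counts as matched
  x <- seq(1000, by = 1000, length.out = 10)
  y <- x; y[10] <- y[10] + 100   # push one far out of tolerance
  m3 <- match_units(list(x), list(y), tol_samples = 15)
  expect_equal(m3$assignment$score, 0.8)
  expect_equal(nrow(m3$matched), 1L)
  # empty trains force FP or FM to 1
  m4 <- match_units(list(numeric(0)), list(a), tol_samples = 15)
  expect_equal(m4$assignment$FM, 1)
  m5 <- match_units(list(a), list(numeric(0)), tol_samples = 15)
  expect_equal(m5$assignment$FP, 1)
})

test_that("greedy pairing is one-to-one by descending score", {
  a1 <- seq(1000, by = 500, length.out = 50)
  a2 <- a1 + 3
  b <- a1
  m <- match_units(list(a1, a2), list(b), tol_samples = 15)
  expect_equal(nrow(m$assignment), 1L)       # only one reference unit
  expect_equal(m$assignment$unit_a, 1L)      # the better-scoring candidate
})

test_that("PSTH comparison recovers correlation structure", {
  fs <- 30000
  onsets <- seq(1, by = 2 * fs, length.out = 40)
  set.seed(61)
  train <- sort(unlist(lapply(onsets, function(o)
    o + round(runif(20, 0, 0.25 * fs)))))
  p <- psth_compare(train, train, onsets, fs = fs)
  expect_equal(p$pearson_r, 1.0)
  # independent unmodulated Poisson trains decorrelate
  t1 <- sort(sample.int(onsets[40] + 2 * fs, 3000))
  t2 <- sort(sample.int(onsets[40] + 2 * fs, 3000))
  p2 <- psth_compare(t1, t2, onsets, fs = fs)
  expect_lt(abs(p2$pearson_r), 0.3)
  # constant PSTHs have undefined correlation, reported as missing
  empty <- psth_compare(numeric(0), numeric(0), onsets, fs = fs)
  expect_true(is.na(empty$pearson_r))
})

test_that("von Mises fits recover noiseless generating parameters", {
  dirs <- seq(0, 330, 30)
  fs <- 30000
  trials <- data.frame(onset_sample = seq(1e4, by = 3e4,
                                          length.out = 12 * 20),
                       direction_deg = rep(dirs, 20))
  rate <- 40 + 120 * exp(2.5 * (cos((trials$direction_deg - 90) * pi / 180) - 1))
  # deterministic spike counts matching the model exactly
  train <- sort(unlist(lapply(seq_len(nrow(trials)), function(i) {
    n <- round(rate[i] * 0.2)
    trials$onset_sample[i] + 0.05 * fs + seq_len(n) * 30
  })))
  fit <- fit_tuning(train, trials, response_window = c(0.05, 0.25), fs = fs)
  expect_true(fit$well_fit)
  expect_gt(fit$r_squared, 0.99)
  expect_lt(abs(fit$pref_deg - 90), 1)
  # direction-independent rates are rejected by the r^2 > 0.6 rule
  flat <- sort(unlist(lapply(seq_len(nrow(trials)), function(i)
    trials$onset_sample[i] + 0.05 * fs + seq_len(3) * 70)))
  fit2 <- fit_tuning(flat, trials, fs = fs)
  expect_false(fit2$well_fit)
  expect_lte(ifelse(is.na(fit2$r_squared), 0, fit2$r_squared), 0.6)
})

test_that("decoding is perfect on separable counts and chance on permuted labels", {
  set.seed(71)
  n_per <- 8L
  labels <- factor(rep(seq(0, 330, 30), each = n_per))
  n_tr <- length(labels)
  # unit i fires iff direction i
  counts <- array(0, dim = c(n_tr, 12, 2))
  for (i in seq_len(n_tr))
    counts[i, as.integer(labels[i]), ] <- 10 + rnorm(2)
  res <- decode_timecourse(counts, labels, seed = 42)
  expect_equal(res$accuracy, rep(1, 2))
  # permuted labels: accuracy near 1/12 (small version of the
  # full-session chance check)
  set.seed(72)
  counts2 <- array(rpois(n_tr * 12 * 2, 5), dim = c(n_tr, 12, 2))
  res2 <- decode_timecourse(counts2, sample(labels), seed = 42)
  expect_lt(abs(mean(res2$accuracy) - 1 / 12), 0.10)
})

test_that("duplicating every trial leaves fold-mean accuracy unchanged in expectation", {
  set.seed(73)
  labels <- factor(rep(seq(0, 330, 30), each = 6))
  n_tr <- length(labels)
  counts <- array(rpois(n_tr * 4 * 1, 4), dim = c(n_tr, 4, 1))
  for (i in seq_len(n_tr))
    counts[i, 1, 1] <- counts[i, 1, 1] + as.integer(labels[i])
  accs <- vapply(1:6, function(s)
    decode_timecourse(counts, labels, seed = s)$accuracy, 0)
  counts2 <- array(counts[rep(seq_len(n_tr), 2), , , drop = FALSE],
                   dim = c(2 * n_tr, 4, 1))
  labels2 <- factor(rep(labels, 2))
  accs2 <- vapply(1:6, function(s)
    decode_timecourse(counts2, labels2, seed = s)$accuracy, 0)
  expect_lt(abs(mean(accs) - mean(accs2)), 0.12)
})

test_that("dropping curves rise with unit count on tuned data and stay flat at chance", {
  set.seed(74)
  labels <- factor(rep(seq(0, 330, 30), each = 10))
  n_tr <- length(labels)
  n_units <- 20L
  prefs <- seq(0, 330, length.out = n_units)
  rates <- outer(as.numeric(as.character(labels)), prefs,
                 function(th, p) 3 + 6 * exp(2 * (cos((th - p) * pi / 180) - 1)))
  counts <- matrix(rpois(length(rates), rates), n_tr, n_units)
  dc <- dropping_curve(counts, labels, seed = 75, step = 10, n_draws = 3,
                       n_folds = 5)
  expect_equal(dc$n_units, c(10, 20))
  expect_gte(dc$accuracy[2] + 0.05, dc$accuracy[1])   # non-decreasing
  expect_gt(dc$accuracy[2], 1 / 12 + 0.1)
  # uninformative units sit at the chance floor
  flat <- matrix(rpois(n_tr * n_units, 5), n_tr, n_units)
  dc0 <- dropping_curve(flat, labels, seed = 76, step = 10, n_draws = 3,
                        n_folds = 5)
  expect_lt(abs(dc0$accuracy[2] - 1 / 12), 0.08)
})

test_that("the asymptote model obeys its algebraic identities", {
  for (p in list(c(0.7, 0.3, 5, 100), c(0.95, 0.9, 1, 900))) {
    expect_equal(asymptote_model(0, p[1], p[2], p[3], p[4]), 1 / 12)
    expect_equal(asymptote_model(1e9, p[1], p[2], p[3], p[4]), p[1],
                 tolerance = 1e-12)
  }
})

test_that("the asymptote fit recovers noiseless parameters and falls back gracefully", {
  k <- seq(10, 400, by = 10)
  y <- asymptote_model(k, A = 0.72, w = 0.5, tau1 = 10, tau2 = 200)
  fit <- fit_asymptote(data.frame(n_units = k, accuracy = y))
  expect_true(fit$converged)
  expect_lt(abs(fit$A - 0.72), 0.001)
  # degenerate curve triggers the mean-of-last-3 fallback
  bad <- data.frame(n_units = seq(10, 60, 10),
                    accuracy = c(NaN, NaN, NaN, 0.5, 0.6, 0.7))
  fb <- fit_asymptote(bad)
  expect_true(fb$fallback_used)
  expect_equal(fb$A, mean(c(0.5, 0.6, 0.7)))
})

test_that("asymptote recovery stays within 0.01 under SEM-scale noise", {
  set.seed(77)
  k <- seq(10, 400, by = 10)
  clean <- asymptote_model(k, A = 0.72, w = 0.5, tau1 = 10, tau2 = 200)
  errs <- vapply(seq_len(100), function(i) {
    sem <- 0.01
    y <- clean + rnorm(length(k), sd = sem)
    f <- fit_asymptote(data.frame(n_units = k, accuracy = y,
                                  sem = rep(sem, length(k))))
    abs(f$A - 0.72)
  }, 0)
  expect_lte(median(errs), 0.01)
})

test_that("paired session comparisons behave like the signed-rank test", {
  a <- c(0.70, 0.72, 0.68, 0.74, 0.71, 0.69)
  r0 <- compare_methods(a, a)
  expect_equal(r0$mean_difference, 0)
  expect_equal(r0$p_value, 1)
  expect_true(r0$all_zero)
  # all-positive distinct differences: the exact two-sided signed-rank p
  # for n = 6 is 2/2^6 (enumeration over sign assignments)
  shift <- c(0.04, 0.05, 0.06, 0.045, 0.055, 0.065)
  r1 <- compare_methods(a + shift, a)
  expect_equal(r1$mean_difference, mean(shift), tolerance = 1e-12)
  expect_equal(r1$p_value, 2 / 2^6)
  # antisymmetry
  r2 <- compare_methods(a, a + shift)
  expect_equal(r2$mean_difference, -r1$mean_difference)
  expect_equal(r2$p_value, r1$p_value)
  expect_error(compare_methods(a[1:3], a[1:3]), "at least 5")
})
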