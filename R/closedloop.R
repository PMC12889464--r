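#' Classify templates as fast-spiking or regular-spiking
#'
#' Waveform width is the trough-to-peak time on each template's
#' maximum-amplitude channel, converted to microseconds at the bank's
#' sampling rate.  Widths strictly below 200 us are fast-spiking (FS);
#' everything else, including monophasic templates (no positive peak
#' after the trough, flagged with a warning), is regular-spiking (RS).
#'
#' @param bank a [template_bank()].
#' @param fs_threshold_us FS/RS boundary (default 200; strict `<`).
#' @return data.frame with `template`, `trough_to_peak_us`, `label`.
#' @export
classify_waveforms <- function(bank, fs_threshold_us = 200) {
  K <- dim(bank$templates)[1]
  fs <- bank$preproc$fs
  out <- do.call(rbind, lapply(seq_len(K), function(k) {
    tm <- matrix(bank$templates[k, , ], dim(bank$templates)[2])
    ch <- which.max(apply(abs(tm), 2L, max))
    w <- tm[, ch]
    trough <- which.min(w)
    after <- w[seq(trough, length(w))]
    if (max(after) <= 0) {
      warning(sprintf("template %d is monophasic; classified RS", k))
      width <- Inf
    } else {
      peak <- trough + which.max(after) - 1L
      width <- (peak - trough) / fs * 1e6
    }
    data.frame(template = k, trough_to_peak_us = width,
               label = if (width < fs_threshold_us) "FS" else "RS")
  }))
  out
}

#' Trigger configuration
#'
#' @param baseline_window_ms baseline rate window (default 100).
#' @param eval_window_ms trigger evaluation cadence/window (default 50,
#'   non-overlapping).
#' @param threshold_sd trigger threshold in baseline SDs (default 2).
#' @param fixation_max_s maximum fixation duration (default 1).
#' @return list of validated parameters.
#' @export
trigger_config <- function(baseline_window_ms = 100, eval_window_ms = 50,
                           threshold_sd = 2, fixation_max_s = 1) {
  cfg <- list(baseline_window_ms = baseline_window_ms,
              eval_window_ms = eval_window_ms,
              threshold_sd = threshold_sd, fixation_max_s = fixation_max_s)
  if (any(unlist(cfg[1:2]) <= 0) || fixation_max_s <= 0)
    stop("trigger windows and fixation duration must be positive")
  cfg
}

# mean FS-population firing rate (Hz per unit) in [from, to) samples
population_rate <- function(times, clusters, fs_units, from, to, fs) {
  n <- sum(clusters %in% fs_units & times >= from & times < to)
  n / length(fs_units) / ((to - from) / fs)
}

#' Run the closed-loop trigger paradigm over a session
#'
#' Baseline mean and SD of the FS-population rate are computed in
#' `baseline_window_ms` windows over the baseline span.  During each
#' trial's fixation the FS rate is evaluated in consecutive
#' `eval_window_ms` windows of the live-sorted events; the first window
#' whose rate exceeds `mean + threshold_sd * SD` triggers stimulus onset
#' at the end of that window, otherwise onset falls at the end of the
#' fixation period (non-triggered).  Control trials bypass the rule and
#' present at a uniformly random time within the fixation period.
#'
#' @param recording_or_sorted a [raw_recording()] (sorted here via
#'   [sort_stream()]) or an already-sorted [sorted_output()].
#' @param bank a [template_bank()] (used for sorting; may be NULL when a
#'   sorted output is supplied).
#' @param fs_units integer cluster ids forming the trigger population.
#' @param config a [trigger_config()].
#' @param trials_spec data.frame with `fix_start_sample`, `direction_deg`,
#'   `is_control` (see [simulate_state_session()]).
#' @param seed seed for the control-trial onset draw.
#' @param baseline_span c(from, to) samples of the baseline epoch
#'   (default: recording start to the first fixation).
#' @return An object of class `trial_table`: data.frame with per-trial
#'   `onset_sample`, `condition` (triggered / non_triggered / control),
#'   `trigger_latency_ms` (NA unless triggered), `direction_deg`;
#'   attributes `baseline_mean_hz`, `baseline_sd_hz`, `sorted`.
#' @export
run_trigger_session <- function(recording_or_sorted, bank, fs_units, config,
                                trials_spec, seed = 1,
                                baseline_span = NULL) {
  if (!length(fs_units)) stop("fs_units must be nonempty")
  sorted <- if (inherits(recording_or_sorted, "sorted_output")) {
    recording_or_sorted
  } else {
    sort_stream(recording_or_sorted, bank)
  }
  fs <- sorted$fs
  if (is.null(baseline_span))
    baseline_span <- c(0, min(trials_spec$fix_start_sample) - 1)
  if (min(trials_spec$fix_start_sample) <= baseline_span[2])
    warning("baseline span overlaps the first trial")
  bw <- config$baseline_window_ms / 1000 * fs
  b_starts <- seq(baseline_span[1], baseline_span[2] - bw, by = bw)
  if (length(b_starts) < 2L) stop("baseline span too short")
  b_rates <- vapply(b_starts, function(s)
    population_rate(sorted$times, sorted$clusters, fs_units, s, s + bw, fs), 0)
  mu_b <- mean(b_rates); sd_b <- stats::sd(b_rates)
  if (sd_b == 0)
    stop("baseline rate SD is zero; use a longer or noisier baseline epoch")
  thr <- mu_b + config$threshold_sd * sd_b
  ew <- config$eval_window_ms / 1000 * fs
  fix_len <- config$fixation_max_s * fs
  n_windows <- floor(fix_len / ew)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(trials_spec)), function(i) {
    f0 <- trials_spec$fix_start_sample[i]
    if (isTRUE(trials_spec$is_control[i])) {
      onset <- f0 + round(stats::runif(1, 0.1, config$fixation_max_s) * fs)
      return(data.frame(onset_sample = onset, condition = "control",
                        trigger_latency_ms = NA_real_,
                        direction_deg = trials_spec$direction_deg[i]))
    }
    onset <- f0 + fix_len; cond <- "non_triggered"; lat <- NA_real_
    for (w in seq_len(n_windows)) {
      s <- f0 + (w - 1) * ew
      r <- population_rate(sorted$times, sorted$clusters, fs_units,
                           s, s + ew, fs)
      if (r > thr) {
        onset <- s + ew
        cond <- "triggered"
        lat <- (onset - f0) / fs * 1000
        break
      }
    }
    data.frame(onset_sample = onset, condition = cond,
               trigger_latency_ms = lat,
               direction_deg = trials_spec$direction_deg[i])
  })
  tt <- do.call(rbind, rows)
  class(tt) <- c("trial_table", "data.frame")
  attr(tt, "baseline_mean_hz") <- mu_b
  attr(tt, "baseline_sd_hz") <- sd_b
  attr(tt, "sorted") <- sorted
  tt
}

#' @export
print.trial_table <- function(x, ...) {
  tab <- table(x$condition)
  cat("Closed-loop trial table:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  baseline %.2f +/- %.2f Hz\n",
              attr(x, "baseline_mean_hz"), attr(x, "baseline_sd_hz")))
  invisible(x)
}

#' Pre-stimulus and evoked firing-rate summaries by condition
#'
#' Per unit and condition: mean pre-stimulus rate (-100 to 0 ms), mean
#' evoked rate (response window), and the normalized response
#' (evoked / pre-stimulus; units with zero pre-stimulus rate are excluded
#' from the normalized summary only).  Condition contrasts use two-sided
#' Mann-Whitney U tests on the per-trial rates pooled over units; the FS
#' vs RS contrast compares the units' normalized differences.
#'
#' @param sorted a [sorted_output()].
#' @param trials a `trial_table` (needs `onset_sample`, `condition`).
#' @param classes data.frame from [classify_waveforms()] mapping the
#'   sorted cluster ids to FS/RS (column `template` is matched against
#'   cluster ids via the bank's template-to-cluster identity map).
#' @param prestim_window,response_window windows in seconds relative to
#'   onset (defaults c(-0.1, 0) and c(0.05, 0.25)).
#' @return list with `unit_summary` (per unit x condition rates),
#'   `condition_tests` (pairwise Mann-Whitney on per-trial pre-stimulus
#'   and evoked rates), `normalized_fs_rs_test`.
#' @export
analyze_prestim <- function(sorted, trials, classes,
                            prestim_window = c(-0.1, 0),
                            response_window = c(0.05, 0.25)) {
  conds <- unique(trials$condition)
  if (length(conds) < 2L) stop("need at least 2 conditions")
  if (any(table(trials$condition) < 5L))
    stop("every condition needs at least 5 trials")
  fs <- sorted$fs
  trains <- cluster_trains(sorted)
  rate_in <- function(train, onset, win) {
    rel <- (train - onset) / fs
    sum(rel >= win[1] & rel < win[2]) / diff(win)
  }
  unit_rows <- list(); trial_rows <- list()
  for (u in seq_along(trains)) {
    lab <- classes$label[match(u, classes$template)]
    for (cond in conds) {
      on <- trials$onset_sample[trials$condition == cond]
      pre <- vapply(on, function(o) rate_in(trains[[u]], o, prestim_window), 0)
      ev <- vapply(on, function(o) rate_in(trains[[u]], o, response_window), 0)
      unit_rows[[length(unit_rows) + 1L]] <- data.frame(
        unit = u, label = lab, condition = cond,
        prestim_hz = mean(pre), evoked_hz = mean(ev),
        normalized = if (mean(pre) > 0) mean(ev) / mean(pre) else NA_real_)
      trial_rows[[length(trial_rows) + 1L]] <- data.frame(
        unit = u, label = lab, condition = cond,
        prestim_hz = pre, evoked_hz = ev)
    }
  }
  unit_summary <- do.call(rbind, unit_rows)
  per_trial <- do.call(rbind, trial_rows)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  condition_tests <- do.call(rbind, lapply(pairs, function(p) {
    a <- per_trial[per_trial$condition == p[1], ]
    b <- per_trial[per_trial$condition == p[2], ]
    data.frame(
      cond_a = p[1], cond_b = p[2],
      p_prestim = suppressWarnings(
        stats::wilcox.test(a$prestim_hz, b$prestim_hz)$p.value),
      p_evoked = suppressWarnings(
        stats::wilcox.test(a$evoked_hz, b$evoked_hz)$p.value))
  }))
  # FS vs RS on per-unit normalized differences (first two conditions)
  nd <- function(lbl) {
    s <- unit_summary[unit_summary$label %in% lbl &
                        !is.na(unit_summary$normalized), ]
    a <- s$normalized[s$condition == conds[1]]
    b <- s$normalized[s$condition == conds[2]]
    u <- intersect(s$unit[s$condition == conds[1]],
                   s$unit[s$condition == conds[2]])
    s1 <- s[s$condition == conds[1], ]; s2 <- s[s$condition == conds[2], ]
    s1$normalized[match(u, s1$unit)] - s2$normalized[match(u, s2$unit)]
  }
  fs_d <- nd("FS"); rs_d <- nd("RS")
  normalized_fs_rs_test <- if (length(fs_d) >= 2L && length(rs_d) >= 2L)
    suppressWarnings(stats::wilcox.test(fs_d, rs_d)$p.value) else NA_real_
  list(unit_summary = unit_summary, per_trial = per_trial,
       condition_tests = condition_tests,
       normalized_fs_rs_test = normalized_fs_rs_test)
}

#' Exceedance curve of pre-stimulus rates
#'
#' Fraction of trials whose pre-stimulus population rate exceeds each
#' threshold, per condition; used to compare triggered against control
#' trials.
#'
#' @param rates named list of per-trial rate vectors by condition.
#' @param thresholds rate thresholds; default 25 points spanning 0 to the
#'   pooled 97.5th percentile.
#' @return data.frame `threshold` x one fraction column per condition.
#' @export
exceedance_curve <- function(rates, thresholds = NULL) {
  if (is.null(thresholds)) {
    pool <- unlist(rates)
    thresholds <- seq(0, stats::quantile(pool, 0.975), length.out = 25)
  }
  out <- data.frame(threshold = thresholds)
  for (nm in names(rates))
    out[[nm]] <- vapply(thresholds, function(th) mean(rates[[nm]] > th), 0)
  out
}

#' Per-trial pre-stimulus population rate
#'
#' @param sorted a [sorted_output()].
#' @param onsets onset samples.
#' @param fs_units cluster ids of the population.
#' @param window seconds relative to onset (default c(-0.1, 0)).
#' @return numeric vector, one mean population rate (Hz/unit) per trial.
#' @export
prestim_rates <- function(sorted, onsets, fs_units, window = c(-0.1, 0)) {
  fs <- sorted$fs
  vapply(onsets, function(o)
    population_rate(sorted$times, sorted$clusters, fs_units,
                    o + window[1] * fs, o + window[2] * fs, fs), 0)
}
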