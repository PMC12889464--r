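#' Spike-train agreement between two unit sets
#'
#' For each candidate pair the two trains are greedily matched one-to-one
#' within `+/- tol_samples`; FP is the fraction of the test train left
#' unmatched, FM the fraction of the reference train left unmatched, and
#' the match score is `1 - FP - FM`.  Units are then paired across the two
#' sets greedily by descending score, one-to-one; pairs with score >= 0.8
#' count as matched.
#'
#' @param trains_a list of sorted spike-time vectors (test set).
#' @param trains_b list of sorted spike-time vectors (reference set).
#' @param tol_samples matching tolerance (default 15, 0.5 ms at 30 kHz).
#' @return An object of class `match_result`: list with `pairs` (all
#'   scored candidate pairs), `assignment` (the greedy one-to-one
#'   pairing), `matched` (assigned pairs with score >= 0.8).
#' @export
match_units <- function(trains_a, trains_b, tol_samples = 15) {
  if (tol_samples < 0) stop("tol_samples must be >= 0")
  score_pair <- function(a, b) {
    na <- length(a); nb <- length(b)
    if (na == 0L && nb == 0L)
      return(c(FP = NA_real_, FM = NA_real_, score = NA_real_, n_match = 0))
    if (na == 0L) return(c(FP = 0, FM = 1, score = 0, n_match = 0))
    if (nb == 0L) return(c(FP = 1, FM = 0, score = 0, n_match = 0))
    i <- 1L; j <- 1L; m <- 0L
    while (i <= na && j <= nb) {
      d <- a[i] - b[j]
      if (abs(d) <= tol_samples) {
        m <- m + 1L; i <- i + 1L; j <- j + 1L
      } else if (d < 0) i <- i + 1L else j <- j + 1L
    }
    fp <- (na - m) / na; fm <- (nb - m) / nb
    c(FP = fp, FM = fm, score = 1 - fp - fm, n_match = m)
  }
  pairs <- do.call(rbind, lapply(seq_along(trains_a), function(i) {
    do.call(rbind, lapply(seq_along(trains_b), function(j) {
      s <- score_pair(trains_a[[i]], trains_b[[j]])
      data.frame(unit_a = i, unit_b = j, FP = s["FP"], FM = s["FM"],
                 score = s["score"], row.names = NULL)
    }))
  }))
  ord <- order(pairs$score, decreasing = TRUE, na.last = TRUE)
  used_a <- logical(length(trains_a)); used_b <- logical(length(trains_b))
  take <- logical(nrow(pairs))
  for (r in ord) {
    i <- pairs$unit_a[r]; j <- pairs$unit_b[r]
    if (!used_a[i] && !used_b[j]) {
      take[r] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  assignment <- pairs[take, , drop = FALSE]
  assignment <- assignment[order(assignment$unit_a), , drop = FALSE]
  matched <- assignment[!is.na(assignment$score) & assignment$score >= 0.8, ,
                        drop = FALSE]
  structure(list(pairs = pairs, assignment = assignment, matched = matched),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Unit matching: %d x %d units, %d assigned pairs, %d matched (score >= 0.8)\n",
              length(unique(x$pairs$unit_a)), length(unique(x$pairs$unit_b)),
              nrow(x$assignment), nrow(x$matched)))
  if (nrow(x$assignment))
    cat(sprintf("  median assigned score %.3f\n",
                stats::median(x$assignment$score, na.rm = TRUE)))
  invisible(x)
}

#' Sliding-window PSTHs and their correlation
#'
#' Trial-averaged firing rate in sliding windows (`bin_ms` wide, stepped
#' every `step_ms`) around each onset, for two spike trains; returns both
#' PSTHs (Hz) and their Pearson correlation.  A zero-variance PSTH makes
#' the correlation undefined (NA).
#'
#' @param train_a,train_b spike-time vectors in samples.
#' @param onsets stimulus onset samples.
#' @param window c(from_s, to_s) around onset (default c(-0.5, 1.5)).
#' @param bin_ms,step_ms window width and step (defaults 100, 10).
#' @param fs sampling rate.
#' @return list with `t_s` (window centers relative to onset), `psth_a`,
#'   `psth_b` (Hz), `pearson_r`.
#' @export
psth_compare <- function(train_a, train_b, onsets, window = c(-0.5, 1.5),
                         bin_ms = 100, step_ms = 10, fs = 30000) {
  if (length(onsets) < 1L) stop("need at least one onset")
  starts <- seq(window[1], window[2] - bin_ms / 1000, by = step_ms / 1000)
  if (length(starts) < 2L) stop("need at least two time bins")
  rate <- function(train) {
    acc <- numeric(length(starts))
    for (on in onsets) {
      rel <- (train - on) / fs
      rel <- rel[rel >= window[1] & rel <= window[2]]
      if (length(rel))
        acc <- acc + vapply(starts, function(s)
          sum(rel >= s & rel < s + bin_ms / 1000), 0)
    }
    acc / length(onsets) / (bin_ms / 1000)
  }
  pa <- rate(train_a); pb <- rate(train_b)
  r <- if (stats::sd(pa) == 0 || stats::sd(pb) == 0) NA_real_ else
    stats::cor(pa, pb)
  list(t_s = starts + bin_ms / 2000, psth_a = pa, psth_b = pb, pearson_r = r)
}

#' Bin spike counts around stimulus onsets
#'
#' @param trains list of per-unit spike-time vectors (samples).
#' @param onsets presentation onset samples.
#' @param window c(from_s, to_s) relative to onset (default c(-0.5, 1.5)).
#' @param bin_ms,step_ms sliding-window width and step (100, 10 gives the
#'   standard decoding bins; step_ms = bin_ms gives disjoint bins).
#' @param fs sampling rate.
#' @return n_trials x n_units x n_bins count array; attribute `t_s` holds
#'   bin centers relative to onset (s).
#' @export
bin_counts <- function(trains, onsets, window = c(-0.5, 1.5), bin_ms = 100,
                       step_ms = 100, fs = 30000) {
  starts <- seq(window[1], window[2] - bin_ms / 1000 + 1e-9,
                by = step_ms / 1000)
  arr <- array(0L, dim = c(length(onsets), length(trains), length(starts)))
  for (u in seq_along(trains)) {
    tr <- trains[[u]]
    for (i in seq_along(onsets)) {
      rel <- (tr - onsets[i]) / fs
      rel <- rel[rel >= window[1] & rel < window[2] + bin_ms / 1000]
      if (length(rel))
        arr[i, u, ] <- vapply(starts, function(s)
          sum(rel >= s & rel < s + bin_ms / 1000), 0)
    }
  }
  attr(arr, "t_s") <- starts + bin_ms / 2000
  arr
}

#' Fit a von Mises direction-tuning curve
#'
#' Mean rate per direction in the response window, then a bounded
#' nonlinear least-squares fit of
#' `r(theta) = b + a * exp(kappa * (cos(theta - mu) - 1))` with `mu`
#' initialized at the argmax direction.  Fits with `r^2 <= 0.6` (or fit
#' failure) are flagged not well fit.
#'
#' @param train spike times in samples.
#' @param trials presentation table (`onset_sample`, `direction_deg`);
#'   all 12 directions must be present.
#' @param response_window c(from_s, to_s) after onset (default
#'   c(0.05, 0.25)).
#' @param fs sampling rate.
#' @return An object of class `von_mises_fit`: list with `curve`
#'   (direction, mean rate, sem), `baseline`, `amplitude`, `pref_deg`,
#'   `kappa`, `r_squared`, `well_fit`.
#' @export
fit_tuning <- function(train, trials, response_window = c(0.05, 0.25),
                       fs = 30000) {
  dirs <- sort(unique(trials$direction_deg))
  if (length(dirs) < 12L) stop("all 12 directions must be present")
  dur <- diff(response_window)
  rate_per <- vapply(seq_len(nrow(trials)), function(i) {
    rel <- (train - trials$onset_sample[i]) / fs
    sum(rel >= response_window[1] & rel < response_window[2]) / dur
  }, 0)
  curve <- do.call(rbind, lapply(dirs, function(d) {
    v <- rate_per[trials$direction_deg == d]
    data.frame(direction_deg = d, rate = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  fit <- NULL
  mu0 <- curve$direction_deg[which.max(curve$rate)]
  a0 <- max(curve$rate) - min(curve$rate)
  st <- list(b = min(curve$rate), a = max(a0, 1e-3), kappa = 2, mu = mu0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ b + a * exp(kappa * (cos((direction_deg - mu) * pi / 180) - 1)),
      data = curve, start = st,
      lower = c(b = 0, a = 0, kappa = 0, mu = -360),
      upper = c(b = Inf, a = Inf, kappa = 100, mu = 720),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(curve = curve, baseline = NA_real_, amplitude = NA_real_,
                pref_deg = NA_real_, kappa = NA_real_,
                r_squared = NA_real_, well_fit = FALSE)
    class(out) <- "von_mises_fit"
    return(out)
  }
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((curve$rate - mean(curve$rate))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  well <- !is.na(r2) && r2 > 0.6 && co["a"] > 1e-9
  out <- list(curve = curve, baseline = unname(co["b"]),
              amplitude = unname(co["a"]),
              pref_deg = unname(co["mu"]) %% 360,
              kappa = unname(co["kappa"]),
              r_squared = r2, well_fit = well)
  class(out) <- "von_mises_fit"
  out
}

#' @export
print.von_mises_fit <- function(x, ...) {
  if (is.na(x$pref_deg)) {
    cat("von Mises tuning fit: failed (not well fit)\n")
  } else {
    cat(sprintf(
      "von Mises tuning fit: pref %.1f deg, kappa %.2f, baseline %.2f Hz, amplitude %.2f Hz, r2 = %.3f%s\n",
      x$pref_deg, x$kappa, x$baseline, x$amplitude, x$r_squared,
      if (x$well_fit) "" else " (not well fit)"))
  }
  invisible(x)
}

#' @export
coef.von_mises_fit <- function(object, ...) {
  c(baseline = object$baseline, amplitude = object$amplitude,
    pref_deg = object$pref_deg, kappa = object$kappa)
}

#' @export
predict.von_mises_fit <- function(object, direction_deg = seq(0, 330, 30), ...) {
  object$baseline + object$amplitude *
    exp(object$kappa * (cos((direction_deg - object$pref_deg) * pi / 180) - 1))
}

# seeded stratified fold assignment
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# class-balanced downsampling of training indices
balance_classes <- function(idx, labels) {
  tab <- table(labels[idx])
  n_min <- min(tab)
  unlist(lapply(names(tab), function(cl) {
    sub <- idx[labels[idx] == cl]
    if (length(sub) > n_min) sample(sub, n_min) else sub
  }), use.names = FALSE)
}

# multinomial logistic regression accuracy for one fold
fit_fold_accuracy <- function(X, labels, train_idx, test_idx, C_reg = 1) {
  train_idx <- balance_classes(train_idx, labels)
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sdv <- apply(X[train_idx, , drop = FALSE], 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  df_tr <- data.frame(y = factor(labels[train_idx]),
                      Xs[train_idx, , drop = FALSE])
  fit <- nnet::multinom(y ~ ., data = df_tr, decay = 1 / C_reg,
                        maxit = 200, trace = FALSE, MaxNWts = 100000)
  pred <- predict(fit, newdata = data.frame(Xs[test_idx, , drop = FALSE]))
  mean(as.character(pred) == as.character(labels[test_idx]))
}

#' Time-resolved population decoding
#'
#' Per time bin: stratified cross-validation of a multinomial logistic
#' regression on the spike-count vectors, with class-balanced
#' downsampling of each training fold and per-feature standardization
#' fitted on the training fold.
#'
#' @param counts n_trials x n_units x n_bins array (see [bin_counts()]).
#' @param labels direction label per trial (12 classes).
#' @param seed RNG seed for folds and downsampling (default 42).
#' @param n_folds folds (default 5).
#' @param C_reg inverse regularization strength (default 1).
#' @return data.frame with `bin`, `t_s` (if the array carries bin times),
#'   `accuracy` (fold mean) and `sem` (across folds).
#' @export
decode_timecourse <- function(counts, labels, seed = 42, n_folds = 5,
                              C_reg = 1) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 12L) stop("12 direction classes are required")
  if (min(table(labels)) < n_folds)
    stop("every class needs at least n_folds trials")
  n_bins <- dim(counts)[3]
  set.seed(seed)
  fold <- stratified_folds(labels, n_folds)
  out <- data.frame(bin = seq_len(n_bins), accuracy = NA_real_,
                    sem = NA_real_)
  t_s <- attr(counts, "t_s")
  for (b in seq_len(n_bins)) {
    X <- matrix(counts[, , b], nrow = dim(counts)[1])
    acc <- vapply(seq_len(n_folds), function(f)
      fit_fold_accuracy(X, labels, which(fold != f), which(fold == f),
                        C_reg), 0)
    out$accuracy[b] <- mean(acc)
    out$sem[b] <- stats::sd(acc) / sqrt(n_folds)
  }
  if (!is.null(t_s)) out$t_s <- t_s
  out
}

#' Neuron dropping curve
#'
#' Decoding accuracy as a function of the number of units: for k = 10,
#' 20, ... up to the unit count, draw `n_draws` random unit subsets, and
#' for each subset z-score each unit's rates across trials and run
#' stratified cross-validated multinomial regression with class-balanced
#' training folds; summarize as mean +/- SEM across draws.
#'
#' @param counts n_trials x n_units matrix of response-window rates.
#' @param labels direction label per trial.
#' @param seed RNG seed.
#' @param step unit-count increment (default 10).
#' @param n_draws subsets per unit count (default 5).
#' @param n_folds folds (default 20).
#' @param C_reg inverse regularization (default 1).
#' @return An object of class `dropping_curve`: data.frame with
#'   `n_units`, `accuracy`, `sem`.
#' @export
dropping_curve <- function(counts, labels, seed = 1, step = 10L,
                           n_draws = 5L, n_folds = 20L, C_reg = 1) {
  labels <- as.factor(labels)
  n_units <- ncol(counts)
  if (n_units < 10L) stop("need at least 10 units")
  if (min(table(labels)) < n_folds)
    stop("every class needs at least n_folds trials")
  ks <- seq(step, n_units, by = step)
  set.seed(seed)
  res <- do.call(rbind, lapply(ks, function(k) {
    accs <- vapply(seq_len(n_draws), function(d) {
      units <- sample.int(n_units, k)
      X <- counts[, units, drop = FALSE]
      X <- scale(X)
      X[!is.finite(X)] <- 0
      fold <- stratified_folds(labels, n_folds)
      mean(vapply(seq_len(n_folds), function(f)
        fit_fold_accuracy(X, labels, which(fold != f), which(fold == f),
                          C_reg), 0))
    }, 0)
    data.frame(n_units = k, accuracy = mean(accs),
               sem = stats::sd(accs) / sqrt(n_draws))
  }))
  class(res) <- c("dropping_curve", "data.frame")
  res
}

#' Two-term saturating exponential accuracy model
#'
#' `y(k) = c + (A - c) * (1 - w * exp(-k/tau1) - (1 - w) * exp(-k/tau2))`
#' with chance level c fixed.  `y(0) = c` and `y(k) -> A` as k grows.
#'
#' @param k unit counts.
#' @param A asymptotic accuracy; `w` mixing weight; `tau1`, `tau2` rise
#'   constants; `c` chance level (default 1/12).
#' @param w,tau1,tau2,c model parameters.
#' @return accuracy at each k.
#' @export
asymptote_model <- function(k, A, w, tau1, tau2, c = 1 / 12) {
  c + (A - c) * (1 - w * exp(-k / tau1) - (1 - w) * exp(-k / tau2))
}

#' Fit the saturating asymptote model to a dropping curve
#'
#' Weighted bounded nonlinear least squares with initial guesses (max
#' observed accuracy, 0.5, 10, 200), A constrained to [chance, 1], w to
#' [0, 1], taus to [1e-6, 1e6]; SEMs act as inverse weights (weight
#' 1/sem^2) when they are all positive.  On failure the asymptote falls
#' back to the mean of the last 3 curve points.
#'
#' @param curve a [dropping_curve()] (or data.frame with `n_units`,
#'   `accuracy`, optional `sem`).
#' @param chance chance level c (default 1/12, fixed).
#' @return An object of class `asymptote_fit`: list with `A`, `w`,
#'   `tau1`, `tau2`, `c`, `converged`, `fallback_used`, `curve`.
#' @export
fit_asymptote <- function(curve, chance = 1 / 12) {
  if (nrow(curve) < 5L) stop("need at least 5 curve points")
  k <- curve$n_units; y <- curve$accuracy
  w8 <- if (!is.null(curve$sem) && all(is.finite(curve$sem)) &&
            all(curve$sem > 0)) 1 / curve$sem^2 else rep(1, length(k))
  st <- list(A = max(y), w = 0.5, tau1 = 10, tau2 = 200)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ asymptote_model(k, A, w, tau1, tau2, c = chance),
      data = data.frame(k = k, y = y), start = st, weights = w8,
      lower = c(A = chance, w = 0, tau1 = 1e-6, tau2 = 1e-6),
      upper = c(A = 1, w = 1, tau1 = 1e6, tau2 = 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(A = mean(utils::tail(y, 3L)), w = NA_real_,
                tau1 = NA_real_, tau2 = NA_real_, c = chance,
                converged = FALSE, fallback_used = TRUE, curve = curve)
  } else {
    co <- stats::coef(fit)
    out <- list(A = unname(co["A"]), w = unname(co["w"]),
                tau1 = unname(co["tau1"]), tau2 = unname(co["tau2"]),
                c = chance, converged = TRUE, fallback_used = FALSE,
                curve = curve)
  }
  class(out) <- "asymptote_fit"
  out
}

#' @export
print.asymptote_fit <- function(x, ...) {
  if (x$fallback_used) {
    cat(sprintf("Asymptote fit: did not converge; fallback A = %.4f (mean of last 3 points)\n", x$A))
  } else {
    cat(sprintf("Asymptote fit: A = %.4f, w = %.3f, tau1 = %.1f, tau2 = %.1f units (c = %.4f fixed)\n",
                x$A, x$w, x$tau1, x$tau2, x$c))
  }
  invisible(x)
}

#' @export
coef.asymptote_fit <- function(object, ...) {
  c(A = object$A, w = object$w, tau1 = object$tau1, tau2 = object$tau2,
    c = object$c)
}

#' @export
predict.asymptote_fit <- function(object, k, ...) {
  asymptote_model(k, object$A, object$w, object$tau1, object$tau2, object$c)
}

#' @export
plot.dropping_curve <- function(x, ...) {
  plot(x$n_units, x$accuracy, type = "b", pch = 16,
       xlab = "units", ylab = "decoding accuracy",
       ylim = c(0, max(x$accuracy + x$sem, na.rm = TRUE)), ...)
  graphics::arrows(x$n_units, x$accuracy - x$sem, x$n_units,
                   x$accuracy + x$sem, angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 1 / 12, lty = 2)
  invisible(x)
}

#' Paired comparison of asymptotic accuracies
#'
#' Two-sided Wilcoxon signed-rank test on paired per-session differences.
#'
#' @param asymptotes_a,asymptotes_b equal-length numeric vectors (one
#'   asymptotic accuracy per session).
#' @return list with `statistic`, `p_value`, `mean_difference`,
#'   `all_zero` flag (p reported as 1 when every difference is zero).
#' @export
compare_methods <- function(asymptotes_a, asymptotes_b) {
  if (length(asymptotes_a) != length(asymptotes_b))
    stop("paired lists must have equal length")
  if (length(asymptotes_a) < 5L) stop("need at least 5 paired sessions")
  d <- asymptotes_a - asymptotes_b
  if (all(d == 0))
    return(list(statistic = NA_real_, p_value = 1,
                mean_difference = 0, all_zero = TRUE))
  wt <- stats::wilcox.test(asymptotes_a, asymptotes_b, paired = TRUE,
                           exact = length(d) < 50)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       mean_difference = mean(d), all_zero = FALSE)
}
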