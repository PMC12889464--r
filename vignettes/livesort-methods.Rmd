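---
title: "Live spike sorting by streaming template matching pursuit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Live spike sorting by streaming template matching pursuit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Problem and pipeline

Conventional spike-sorting workflows are offline: a session is recorded to
disk, sorted afterwards, and only then analyzed.  That precludes
closed-loop experiments that react to the activity of *identified single
neurons* while the animal is still in the rig.  `livesort` implements the
alternative workflow: a training segment of a multichannel extracellular
recording is sorted offline once to learn a *template bank*, after which
incoming data are decomposed live, batch by batch, against those fixed
templates.  The package also ships a ground-truth simulator and a
validation suite so that every stage can be exercised and scored without
any real recording.

A session proceeds as:

1. `make_units()` / `simulate_trains()` / `render_recording()` —
   synthesize a recording with known spikes (or read a real one with
   `read_raw()`),
2. `learn_templates()` — learn the `template_bank` on the training
   segment,
3. `sort_stream()` — streaming matching-pursuit sorting,
4. `match_units()`, `psth_compare()`, `fit_tuning()`,
   `decode_timecourse()`, `dropping_curve()`, `fit_asymptote()` —
   validation against ground truth or an offline reference,
5. `classify_waveforms()`, `run_trigger_session()`, `analyze_prestim()` —
   the closed-loop paradigm.

## The online preprocessing chain

Every batch passes through five steps in a fixed order: per-channel mean
subtraction; common median referencing (CMR: the per-sample median across
channels is subtracted from every channel); zero-phase FFT high-pass at
300 Hz; left-multiplication by the spatial whitening matrix; and
left-multiplication by the drift-correction matrix (identity by default —
live drift tracking is future work).

Numerical choices:

* The high-pass transition band is a raised cosine over 300 ± 75 Hz,
  applied zero-phase in the frequency domain after reflection padding
  (512 samples per side by default).  The band edges are pinned by a
  regression test.
* Whitening is symmetric (ZCA-style), estimated channel-block-wise within
  a 100 µm neighborhood, with diagonal regularization
  `eps = 1e-6 × mean(diag(cov))` by default.
* In `learn_templates()` the whitening covariance is estimated from
  **deflection-masked** samples of the filtered training data.  Spikes
  are sparse but energetic; a covariance that includes them makes ZCA
  suppress the spike subspace itself, which distorts and spuriously
  correlates the whitened waveforms.
* The learner additionally projects the channel-common spatial direction
  `W·1` out of the whitening matrix.  CMR is a median and therefore *not
  additive*: when two spikes superimpose, the preprocessed signal differs
  from the sum of the individually preprocessed spikes by a term that is
  channel-constant at each sample.  After whitening that term lies
  exactly along `W·1`, so nulling this single spatial direction restores
  exact additivity of spike superpositions — without it, overlap sites
  shed small artifact events.  A corollary (tested) is that the full
  chain is positively homogeneous but not additive, while the median-free
  sub-chain is fully linear.

## Template learning

`learn_templates()` is a deliberately simple, fully documented stand-in
for a production offline sorter.  Pipeline: preprocess the training
segment → detect threshold crossings (per-channel robust SD via MAD × 5,
floored at 5 % of the largest deflection) with spatiotemporal
non-maximum suppression (one event per template-length window within
3 × the 100 µm feature neighborhood — the whitened footprint of a spike
is wider than its raw footprint) → extract M = 61-sample snippets
(trough at the center sample) → temporal PCA → average-linkage
clustering of masked PCA features with a noise-adaptive cut (2 × the
75th-percentile nearest-neighbor distance) → cluster medians become
templates.

Robustness decisions that matter in practice:

* **Medians, not means.**  Roughly 10 % of snippets contain a second
  spike; per-sample medians ignore them.
* **Member re-alignment.**  Each member is re-aligned (± 2 samples) to a
  provisional cluster median before the final median, since detected
  trough times can sit one sample off when the true trough falls near a
  half-sample.
* **Composite rejection.**  Coincident spike pairs form small clusters
  whose "template" is a superposition.  Clusters are accepted
  largest-first; a cluster whose median is > 90 % explainable by a
  lagged least-squares combination of already-accepted templates is
  discarded (`explained_fraction()`), as are clusters whose median does
  not itself clear the detection threshold or whose energy is below
  0.5 % of the strongest template (noise fragments).
* **Capture-driven basis size.**  The final temporal basis is the SVD of
  the accepted cluster medians, grown from `n_pcs = 6` components until
  every template retains ≥ 99.5 % of its energy (cap 24).  A fixed small
  basis cannot represent ten distinct waveform shapes, and the
  unrepresented part of a big spike projects onto *shifted* copies of
  other templates, producing spurious sub-threshold-looking events.
  Templates are stored projected onto this basis so that the engine's
  feature-space convolution is exactly a convolution with the stored
  templates.
* **Per-template detection thresholds.**  The detection statistic is the
  squared rectified amplitude `(max(conv, 0)/‖T‖²)²`.  The learned
  threshold is, per template, the 0.999 quantile of that statistic's
  max-pooled maxima on spike-free stretches, floored at 0.05 (i.e.
  events below ~22 % of a template's amplitude are never accepted).
  Weak templates have larger noise-driven amplitude maxima, so the
  calibration is per matched filter.

The bank records templates, the PCA basis, masked template features,
pairwise template cross-correlations (`pair_cc[i,j,lag+M] = Σ T_i[m]·
T_j[m+lag]`, with the zero-lag diagonal equal to each template's
energy), PCA-space cluster centroids, the template→cluster map, the
preprocessing spec and the geometry.  `import_bank()` can instead
populate a bank from a phy-layout directory.

## Streaming matching pursuit

`plan_batches()` tiles the recording into windows that overlap by exactly
2M samples; window k owns the emit range `[start+M, end−M)` (first and
last windows extended to the recording edges), and the emit ranges
partition the recording, so boundary spikes are detected by both
neighbors but emitted once.  Border zeroing of the detection statistic
uses the convolution-validity margin (M−1)/2 per batch end; a wider
border would orphan part of the emit range.  In `sort_stream()` each
window is preprocessed with up to 512 samples of neighboring recording as
filter context (cropped afterwards), which keeps streamed output
identical to single-batch output.

`run_matching_pursuit()` projects the batch onto the temporal basis
(FFT cross-correlation per component and channel), forms all template
convolutions as one matrix product, and iterates up to 50 passes:
rectify-square-normalize, find per-template temporal local maxima by
max-pooling over a 2M+1 window, accept candidates above threshold in
order of explained energy (re-checking each against the updated
convolution), compute the amplitude as the least-squares coefficient
`⟨residual, T⟩/‖T‖²` (clamped positive), and subtract the spike from the
residual and — via `pair_cc` — from every template's convolution trace.
A pass that accepts nothing ends the loop.

Greedy single-spike fits are biased wherever templates overlap, so two
joint-refinement mechanisms run on the accepted set: an exact joint
refit of small overlap groups (≤ 3 events within 2M of each other; every
±2-sample lag configuration is scored with closed-form joint amplitudes
from `pair_cc`, negative amplitudes clamped out, and the best
residual-energy reduction wins — the current configuration is in the
search space, so the refit never worsens the fit), and a monotone
coordinate-descent polish (remove an event, re-pick its best time within
±2 samples, re-fit) for larger groups and globally between passes.
Events whose refined amplitude no longer clears the threshold are
dropped.

Spike positions are mass-weighted channel positions with mass the
per-channel PCA feature energy over the accepted template's 100 µm
neighborhood; features are extracted from the final residual plus the
event's own fitted contribution, which isolates each spike from its
overlap partners before nearest-centroid cluster assignment (Euclidean
over the neighborhood's feature dimensions, ties to the lowest id).
Duplicates are suppressed per template: within `min_isi_samples`
(default 15, 0.5 ms) the larger amplitude survives, greedily in
amplitude order, with strict inequality at the boundary.

With `realtime_budget` set (a throughput factor), a simulated processing
clock abandons any window that could not finish within two window
durations of its acquisition; skipped spans are reported, never silently
lost, and `realtime_budget = 0` skips everything.

## The simulator

The simulator generates the study conditions for every benchmark in the
package:

* **Templates** are biphasic difference-of-Gaussians kernels (trough at
  the center sample, rebound 0.4 of the trough) on a random peak
  channel, with amplitude decaying as `exp(−d/25 µm)` across channels.
  Amplitudes are uniform on 80–150 µV, trough-to-peak widths stratified
  (jittered grid) across 100–500 µs, and peak channels drawn without
  replacement while channels last: ground-truth units in a validation
  simulator must be mutually distinguishable, as in hybrid ground-truth
  benchmarking.
* **Trains** are inhomogeneous Poisson with refractory deletion
  (default 2.5 ms), baseline rates 5–15 Hz.  During a 0.25 s stimulus
  the rate is `base × (1 + depth·exp(κ(cos(θ−pref)−1)))`; trials present
  three stimuli of 0.25 s separated by 0.15 s, at twelve directions in
  30° steps.
* **Rendering** superposes templates at spike times (per-spike amplitude
  jitter ±10 % by default), adds Gaussian noise — i.i.d. per channel by
  default, with an optional spatially correlated mode (Gaussian kernel
  over channel distance) to exercise whitening — and quantizes to int16
  at a gain that puts the largest template at ~25 % of the integer
  range.  The default noise SD is 15 µV against 80–150 µV spike peaks,
  a mid-range extracellular SNR; this default is a documented choice of
  the simulator, not a measured property of any particular recording
  system.  Zero-noise rendering is exactly the template superposition
  before quantization.
* **State sessions** (`simulate_state_session()`) multiply the
  fast-spiking subpopulation's rates by a latent two-state Markov gain
  (levels 1 and 2.5, mean dwell 1.2 s low / 0.8 s high, 10 ms grid) and
  lay out a closed-loop trial schedule (a 30 s baseline epoch, then 200
  fixation starts at 1.5 s pitch, one third control trials).  The
  baseline epoch shares the state process: the 2 SD trigger threshold is
  meant to sit above the ordinary fluctuation range, so the baseline
  statistics must sample the natural state distribution.

What the simulator does *not* emulate: electrode drift, bursting with
amplitude attenuation, spatio-temporally structured (non-separable)
noise, biophysical waveform diversity beyond the kernel family, and
probe-scale channel counts.  Benchmarks passing here therefore show the
pipeline's correctness under its stated model, not parity with sorters
on real tissue.

## Validation suite

* `match_units()` greedily pairs spikes within ±15 samples (0.5 ms),
  computes FP (unmatched test fraction) and FM (unmatched reference
  fraction), scores `1 − FP − FM`, and pairs units one-to-one greedily
  by descending score; score ≥ 0.8 counts as matched.  One-sided empty
  trains force FP or FM to 1.
* `psth_compare()` uses 100 ms windows stepped by 10 ms over −0.5 to
  +1.5 s; zero-variance PSTHs yield a missing correlation rather than a
  number.
* `fit_tuning()` fits `b + a·exp(κ(cos(θ−µ)−1))` by bounded
  Levenberg–Marquardt (µ initialized at the argmax direction); fits with
  r² ≤ 0.6 are flagged not well fit.  This parametrization makes `a`
  the peak-over-baseline modulation.
* `decode_timecourse()` runs, per time bin, stratified 5-fold
  cross-validation of a multinomial logistic regression
  (`nnet::multinom`, weight decay 1/C with C = 1) with class-balanced
  downsampling and per-feature standardization fitted on each training
  fold.  Chance for twelve directions is 8.33 %.
* `dropping_curve()` subsamples units in steps of 10 with 5 seeded
  draws, z-scores rates per unit, and uses 20-fold stratified CV;
  `fit_asymptote()` fits
  `y(k) = c + (A−c)(1 − w·e^{−k/τ₁} − (1−w)·e^{−k/τ₂})` with c = 1/12
  fixed, starts (max accuracy, 0.5, 10, 200), bounds A ∈ [c, 1],
  w ∈ [0, 1], τ ∈ [10⁻⁶, 10⁶], inverse-SEM weights (weight 1/SEM²) when
  SEMs are available, and falls back to the mean of the last three
  points if the fit fails.  `y(0) = c` and `y(∞) = A` hold identically.
* `compare_methods()` is the two-sided Wilcoxon signed-rank test on
  paired per-session asymptotes; all-zero differences report p = 1 with
  a flag.

## Closed loop

`classify_waveforms()` measures each template's trough-to-peak time on
its maximum-amplitude channel; widths strictly below 200 µs are
fast-spiking (200 µs is exactly 6 samples at 30 kHz), everything else —
including monophasic templates, with a warning — regular-spiking.
`run_trigger_session()` computes baseline mean and SD of the
FS-population rate in 100 ms windows, then evaluates consecutive
(exactly) 50 ms windows during each fixation; the first window exceeding
mean + 2 SD triggers stimulus onset at that window's end, otherwise the
stimulus falls at 1 s (non-triggered).  Control trials bypass the rule
and present at a uniform random time in the fixation period.  The
trigger depends only on FS-labeled clusters — perturbing RS trains
leaves the trial table unchanged (tested).  `analyze_prestim()`
summarizes pre-stimulus (−100–0 ms) and evoked (50–250 ms, the stimulus
duration minus onset latency) rates per unit and condition, normalizes
evoked by pre-stimulus rate (units with zero pre-stimulus activity are
excluded from the normalized summary only), and runs pairwise
Mann-Whitney tests across conditions and between the FS and RS
normalized differences.

## Benchmark problem sizes

The packaged tests and the acceptance script use: a 60 s, 16-channel,
10-unit session for ground-truth recovery (zero-noise for the exactness
check, the default SNR for the matched-unit criterion); a 480-
presentation (40 per direction), 50-unit session for decoding; a
3-template, 3000-sample instance for the subtraction oracle; and a
200-trial state-fluctuating 8-channel session for the closed loop.
These sizes were chosen so that each benchmark carries enough events for
its statistic while an entire validation run stays comfortably on a
single CPU core.

## Known limitations

The learner is not a replacement for a production offline sorter: it has
no drift tracking, no manual curation hooks, and its clustering is tuned
for well-separated synthetic units.  Matching pursuit resolves overlaps
only up to the joint-refit search (±2 samples, groups of three); dense
synchronous assemblies can still be mis-decomposed.  The adaptive-skip
clock is simulated, not wall-clock; real-time performance engineering
(GPU kernels, pinned memory, socket acquisition) is out of scope.
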