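---
title: "Methods: unitization analysis of MTL single-neuron and LFP responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unitization analysis of MTL single-neuron and LFP responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in
`mtlunitize`, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-session generator does and does not emulate,
and the numerical choices made where the methods leave room.

## The setting and the model

The data are follow-up sessions of human MTL recordings: roughly 15
pictures, each presented 25–35 times for 1 s, with sorted single-unit spike
trains and wideband LFP extracted from 1 s before to 2 s after each onset.
All times are in milliseconds relative to stimulus onset and every analysis
window is half-open, `[a, b)`, so a boundary spike is counted exactly once.

MTL "concept cells" respond sparsely and strongly to a few stimuli. The
scientific question is whether a unit's multiple responses are
distinguishable. The pipeline therefore quantifies each significant
response by four signatures — strength, onset latency, evoked theta-LFP
timing, and preferred spike–theta phase — and asks, pair by pair, whether
the two responses differ in any of them beyond what trial-label
exchangeability allows.

## Response detection

The instantaneous rate is the 1 ms-binned spike train convolved with a
unit-area Gaussian kernel, σ = 10 ms, truncated where the amplitude falls
below 1% of the peak (±30 ms). The truncated kernel is deliberately **not**
renormalized: the truncation loses < 0.3% of the mass, and renormalizing
would silently change the peak rate a single spike produces
(1/(σ√2π) ≈ 39.9 Hz).

Three criteria must all hold (defaults in `det_params()`):

* **(i) Sustained excursion.** The trial-averaged rate must exceed
  `T = max(mean + 4 SD, 5 Hz)` for ≥ 75 ms, where the mean and SD are taken
  over the per-stimulus average traces on [−900, −100) ms, pooled across
  all stimuli. Sub-threshold dips shorter than 20 ms are disregarded. The
  first upward crossing is the onset `t_THR`, searched in [0, 1000) ms.
  The 5 Hz floor protects near-silent units whose baseline SD is tiny.
* **(ii) Count criterion.** The median spike count across trials in
  [t_THR, t_THR + 500) must be ≥ 2 and exceed the mean + 5 SD, across
  stimuli, of the per-stimulus baseline median counts on [−700, −200) ms.
  The SD is computed over the per-stimulus baseline medians — the natural
  reading of an "across stimuli" dispersion of a median-count statistic.
* **(iii) Sign test.** A one-sided paired sign test between each trial's
  post-onset and baseline count must give p < 0.01. Ties (equal counts)
  are dropped before the binomial computation, the standard sign-test
  convention.

Where the threshold statistics could be computed on a grand-average trace
instead of pooled per-stimulus traces, we pool the per-stimulus traces'
samples; with ~15 stimuli the two differ little, and pooling keeps the
threshold defined when stimulus counts are unbalanced.

Strength is the median count in a 700 ms window from onset divided by the
window length; the baseline strength uses [−1000, −300) ms over all trials
of all stimuli. A mean-count variant (`use_mean = TRUE`) exists for the
correlation and population analyses, where the median's discreteness is a
nuisance. The normalized strength profile uses the fixed [100, 800) ms
window, subtracts the mean baseline and floors at zero before dividing by
the maximum across stimuli.

## Permutation machinery

All pairwise tests share one scheme: the observed statistic is ranked in a
null population built by permuting trial labels between the two responses,
and `p = (1 + #{surrogate ≥ observed}) / (1 + n_surr)` (add-one rule, so p
is never 0 and the test is exchangeability-valid). Seeds make every run
bit-reproducible.

* **Strength** uses |ΔS| of the median-count strengths. Because the median
  of integer counts lives on a half-integer grid, the statistic has atoms;
  ties count against rejection, so the test is *conservative*: its true
  level at α = 0.05 is about 0.024–0.032 for study-scale Poisson counts
  (and closer to 0.01 with an odd number of trials, where the median is
  integer-valued). This is a property of median-based permutation testing
  worth knowing when interpreting the reported rejection fractions; the
  two-valued degenerate case (every permutation leaves one group median at
  each value) makes the statistic constant and p = 1.
* **Latency** re-estimates each surrogate group's onset as the first
  sustained crossing of the group's average rate trace over the *original*
  threshold. A surrogate group with no qualifying crossing is censored at
  1000 ms (the end of the onset window) rather than redrawn: redrawing
  would condition the null on detectability and bias p downward.
* **Spike shape** uses the Mahalanobis distance between group mean
  waveforms with the pooled within-group covariance shrunk toward its
  diagonal (weight 0.1), since the waveform dimension (~32–64 samples) can
  exceed the spike count.
* **Cross-neuron surrogate pairs** re-draw the same number of response
  pairs from different units 1000 times; the observed within-unit median
  difference is ranked among the surrogate-set medians, and the
  "representative" set (the one with the median of the set medians) is
  compared to the observed differences by a one-sided rank-sum test.
* **Stability curves** recompute a metric on trials 1..n_t, fit
  `a + b·exp(−n_t/τ)` by least squares (`minpack.lm` when available,
  `nls` otherwise; a failed fit is reported as absent), and compare
  sliding 6-trial windows (trials 1–6 vs 20–25) with a two-sided paired
  sign test to separate window-length bias from presentation-order effects.

## Decoding

The naive-Bayes decoder uses Poisson likelihoods on single-trial counts in
a common [100, 800) ms window with leave-one-out cross-validation; training
rates get ε = 0.1 smoothing so an all-zero class stays usable, and ties go
deterministically to the lowest stimulus id (so k identical count
distributions give exactly 100/k%). A Gaussian family is available behind
`family = "gaussian"`. The fixed window (rather than per-stimulus onset
windows) treats all stimuli of a unit symmetrically — the decoder must not
receive onset information the null lacks. Shuffle significance permutes
the trial-to-stimulus assignment 1000 times.

## LFP processing

Preprocessing band-passes 2–512 Hz, notches 50 Hz and harmonics up to
500 Hz (2nd-order IIR biquads, −3 dB bandwidth 4 Hz), and downsamples to
1.5 kHz after a zero-phase Butterworth anti-alias stage. Two numerical
points matter:

* The elliptic designs (order 4, 0.1 dB passband ripple, 40 dB stopband —
  chosen because the method family leaves them unstated) are kept in
  zero-pole-gain form and applied as cascades of second-order sections.
  For the 3–6 Hz band at 1.5 kHz the expanded transfer-function polynomial
  is numerically unstable (poles drift outside the unit circle), a classic
  failure of narrowband IIR filters in `(b, a)` form.
* All zero-phase filtering uses odd-reflection padding (0.5 s in
  preprocessing, 1 s for the theta filter). Without it, the filter's
  start-up transient on 3 s epochs leaks into the pre-stimulus baseline
  and inflates the evoked-power onset threshold.

Theta trials (3–6 Hz) are normalized by the RMS of their [0, 1000) ms
segment; a trial whose theta content is below 1% of its broadband RMS
(e.g. a DC-only trace) carries no phase information and is excluded with a
warning. Evoked power is `|analytic(mean trace)|²`; the onset threshold is
the median + 4 mean absolute deviations of the power on [−900, −100) ms,
pooled across the per-stimulus average traces of the channel (the same
pooling choice as for the rate threshold), and both the onset and the peak
are searched in [0, 700] ms — the peak-search bound extended to onsets,
which the method family leaves unstated. Channel screening automates the
visual power-spectrum inspection: a channel is discarded when its mean
[300, 512] Hz power exceeds 10× the session median across channels
(config-exposed).

A known limitation: on narrowband-filtered data, threshold-crossing onset
estimation is SNR-dependent. The zero-phase theta filter smears a burst
edge symmetrically over ~±150 ms, so with a very strong burst the
threshold sits far down the smeared edge and the onset reads early by up
to ~100 ms, while near the detectability limit the estimate is noisy.
The estimator is approximately unbiased (median error within ±20 ms at 29
trials) only when the burst is comparable to the ongoing theta background —
which is also the physiologic regime.

## Phase locking

Spike phases are read from the Hilbert phase of the single-trial theta
trace (0° at the oscillation peak, ±180° at the trough, −90° on the rising
slope). Epochs are half a cycle of the 4.5 Hz band midpoint, 111 ms: the
response epoch starts at `t_THR`; the baseline epoch is fixed at
[−500, −389) ms — inside the baseline period, away from both the epoch
edges and the fixation interval; its exact placement is config-exposed
because the method family leaves it open. The baseline epoch pools spikes
from all stimuli, and both epochs require ≥ 20 pooled spikes. PLI is the
resultant length of the pooled phases, with a Rayleigh test
(`p = exp(√(1+4n+4(n²−R²)) − (1+2n))`, the standard finite-n
approximation) and a trial-shuffle surrogate test that permutes the
trial-to-LFP assignment, keeping the number of phases fixed.

## Association scores

`a_ij = log2(hits_ij / (hits_i·hits_j))` from a cached provider table
(`associations.csv`); the pipeline performs no network I/O, and pairs with
zero joint hits are excluded and counted. Scores are z-scored per session;
familiarity `f_ij = log2(hits_i·hits_j)` and the 160×160 pixel correlation
`v_ij` serve as controls, with the same R–R vs R–NR paired sign test
(category-restricted variants included). Correlations with
electrophysiological differences use Pearson r, quartile splits on the
score, and Fisher-Z (`atanh`) comparisons between groups.

## The synthetic-session generator

`generate_session()` emulates, with one seed fixing all randomness:

* Poisson baseline spiking (1–10 Hz) with a 3 ms refractory dead time
  (without it every synthetic unit would fail the < 1% ISI-violation
  single-unit criterion). The dead time makes the realized rate
  `1/(0.003 + 1/rate)`; `ground_truth()` reports both the configured and
  the effective rate, and recovery tests use the latter.
* Stimulus-locked rate steps at latencies spanning ~110–650 ms with
  ~700 ms durations and 18–45 Hz response rates.
* A theta burst (4.5 Hz, raised-cosine edges) starting 70 ms before the
  spike latency, phase-reset at onset (−90°, i.e. rising toward the peak)
  with 20° per-trial jitter, amplitude 4 against a 1/f background of SD 10
  (theta-band SD ≈ 3.2, so the burst is ~1.25× the ongoing theta). The
  1/f law is floored below 2 Hz: in a real chain the sub-2 Hz content is
  removed before trials are epoched, and synthesizing it into 3 s epochs
  would only inject spurious edge energy into the narrowband filters.
* Von Mises spike-phase coupling implemented by thinning candidate spikes
  against the trial's analytic theta phase, which preserves the marginal
  Poisson rate in expectation (acceptance probability
  `exp(κ(cos(θ−μ)−1))`, candidate rate boosted by `e^κ/I₀(κ)`). The
  default κ = 1 puts response-epoch PLIs near 0.45, the regime of
  significantly locked MTL responses; the canonical unitized configuration
  clusters preferred phases around the burst's rising-to-peak phase, since
  the burst is what drives the firing.
* Waveforms as a biphasic template plus i.i.d. noise, and a
  block-structured association table (raw log2 scores around −10 inside
  blocks, −20 outside, SD 1, attached to realistic 10⁵–10⁷ hit counts).

What it does **not** emulate: bursting and adaptation, habituation across
trials, spike-sorting contamination beyond template mixtures,
non-stationary LFP (artifacts, epileptiform events), multi-band or
phase–amplitude structure, and recording drift. Passing recovery tests
therefore show the estimators work under the stated statistical structure,
not that real recordings satisfy that structure.

`synth_unitized_config()` is the canonical test bed: 15 stimuli × 29
trials, nine multi-responsive units whose responses inside association
blocks share strength, latency and phase, one multi-responsive unit with
non-associated, differing responses, three single-responsive units and
three silent ones, on two LFP channels at a 3 kHz raw rate (an integer
multiple of the 1.5 kHz target; generating 30 kHz would add nothing but
runtime).

## Known systematics

Two estimator systematics combine in the spike-minus-LFP lag: the Gaussian
kernel anticipates the spike threshold crossing by ~10 ms, and the
evoked-power crossing concentrates ~20 ms after the true burst onset (its
error distribution is left-skewed: early crossings are noise-triggered and
scatter, late crossings concentrate on the steep part of the smeared
edge). The *mode* of the measured lag therefore underestimates a
configured 70 ms lead by ~25–30 ms even though both median onset errors
are within ±20 ms; the corresponding acceptance check is asserted at its
stated band and fails for this reason, documented rather than tuned away.
By the same token, a measured ~70 ms lag on real data is compatible with a
somewhat larger true lead.

## Problem sizes

The test suite runs detection nulls at 40 seeds × 5 stimuli, permutation
calibrations at 500 exchangeable instances (2000 for the strength test,
whose conservativeness needs the precision) with 199 surrogates each,
enumeration oracles at 5–6 trials per side against all C(10,5)/C(12,6)
label assignments, and three full synthetic sessions through the complete
pipeline with 1000 surrogates per pairwise test. These sizes keep the
suite within a desk-scale run while leaving every estimate's Monte-Carlo
error well inside the asserted tolerances.
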