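---
title: "Methods: burst detection, coherence and directed connectivity in developing limbic circuits"
author: "lfpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst detection, coherence and directed connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and signal model

`lfpnet` implements the analysis chain for multi-site recordings of
neonatal and pre-juvenile limbic circuits: lateral entorhinal cortex
(LEC), hippocampal CA1 (HP) and prelimbic prefrontal cortex (PFC).
Neonatal activity in these regions is *discontinuous*: spindle-shaped
oscillatory events with theta (4–12 Hz) and beta (12–30 Hz) content ride
on a continuous slow rhythm (2–4 Hz), separated by stretches of low
activity. Every stage of the package assumes this structure: events are
detected first, and spectra, coherence and directed connectivity are
estimated on fixed-length epochs drawn from the detected events.

All times are seconds (float64), events are half-open intervals
`[start, stop)`, channel indices are 1-based, and LFP amplitudes are
microvolts. Filtering is phase-preserving throughout: Butterworth
designs applied forward and backward, with odd-reflection padding of
three filter lengths. The effective magnitude order therefore doubles
(a "third-order" low-pass acts as sixth-order in magnitude); this is
documented, not compensated, because zero group delay is what event
timing, evoked latencies and cross-spectral phases require.

## Event detection

Per channel, the 3–100 Hz band-passed signal is reduced to a sliding
RMS envelope (window 0.2 s, hop 0.01 s). The detection threshold is
variance-dependent: the histogram of envelope values (100 bins from 0 to
the maximum) is fitted with a Gaussian restricted to bins at or below
the modal bin — the noise body — and the threshold is `mu + k * sigma`.
Supra-threshold runs closer than the merge gap are joined, and only
events longer than 1 s are reported.

Two interpretations of "the histogram body" are possible: fitting up to
the modal bin (`mode_def = "hist_peak"`, the default — the noise mode
dominates recordings with discontinuous activity) or over the full range
(`mode_def = "max"`). Both are exposed.

Two defaults deserve justification because the analysis is sensitive to
them:

* **Threshold multiplier `k = 4`.** The multiplier was calibrated once
  by false-alarm control on signal-free recordings: on 600 s of either
  white noise or 1/f background noise the detector must report zero
  events. Band-limited 1/f noise has a right-skewed envelope
  distribution whose tail a low multiplier (2–3) misreads as events;
  `k = 4` is the smallest integer-half setting that silenced both noise
  controls while leaving recall of genuine 6 dB bursts intact.
* **Merge gap 0.4 s.** Within a spindle burst the theta envelope waxes
  and wanes on the timescale of one to two cycles (~0.25–0.4 s); dips of
  that length split one physiological event into sub-second fragments
  that the duration filter would then discard. The merge gap is set to
  bridge those dips and no more.

Degenerate inputs are handled explicitly: a constant channel (zero
variance, or an envelope at numerical noise level relative to the raw
signal) yields a warning and no events; a failed Gaussian fit falls back
to `median + k * 1.4826 * MAD`, flagged in the `threshold_method`
attribute.

Multi-unit activity is detected on the 500–5000 Hz band as the local
minimum of every excursion below −5 SD of the channel, with a 1 ms dead
time. The plain SD is the default (a robust MAD-based variant is
available); on pure noise the crossing rate agrees with the Rice
level-crossing formula, which the test suite uses as an independent
oracle.

## Spectra and coherence

Power spectra use Welch's method on 1 s non-overlapping segments tiled
from the detected events (Hamming taper; a leftover tail shorter than
one segment is discarded), giving 1 Hz resolution at the 1 kHz LFP rate.
Continuous (pre-juvenile) recordings are tiled whole. Baseline spectra
`P0(f)` use identical settings on inter-event windows of at least one
segment length; fewer than 10 baseline segments triggers a warning.
Normalized power is the pointwise ratio `P(f)/P0(f)`.

Coherency is estimated from Welch cross- and auto-spectra averaged over
co-occurring epochs — the intersection of the event intervals of the two
channels, tiled into 1 s segments. The magnitude coherence is its
modulus; the imaginary coherence `|Im C_XY(f)|` discards the zero-lag
component and is therefore immune to instantaneous (volume-conducted)
mixing: two independent sources mixed by a nonnegative matrix show high
magnitude coherence but flat imaginary coherence, a property asserted in
the acceptance suite. The shuffled null re-pairs epochs by a random
nonzero cyclic rotation (a guaranteed derangement) and averages the
recomputed coherence over permutations.

## MVAR and generalized partial directed coherence

One channel per region enters the directed analysis (for CA1 the
pyramidal-layer channel; for LEC the site 700 µm above it — selection is
upstream of this package). Epochs are band-limited 1–45 Hz (zero phase)
and decimated to the 100 Hz model rate; the band limit doubles as the
anti-alias filter. The original analysis chain de-noised with a wavelet
toolbox before model fitting; the settings of that step are not
reproducible, so this package substitutes the transparent band-pass and
documents the deviation.

The MVAR model is estimated by least squares pooled across epochs
*without* crossing epoch boundaries (each epoch contributes only its own
lagged rows). The order is selected by BIC over `1..p_max` (default 20;
the end-to-end pipeline uses 8 at the 100 Hz model rate, where the
theta/beta dynamics need few lags) unless fixed; rank deficiency and
instability raise classed errors. The generalized PDC is

$$\mathrm{gPDC}_{i \leftarrow j}(f) =
  \frac{|\bar A_{ij}(f)|/\sigma_i}
       {\sqrt{\sum_k |\bar A_{kj}(f)|^2/\sigma_k^2}},
  \qquad \bar A(f) = I - \sum_{r=1}^{p} A_r e^{-i 2 \pi f r / f_s},$$

with $\sigma_i^2$ the innovation variances. The noise-variance weighting
makes the measure scale-invariant across channels; each source column
satisfies $\sum_i \mathrm{gPDC}^2 = 1$, an identity the package checks to
1e-8 on every call. Among the PDC family variants this is the
generalized (noise-normalized) form; the information-PDC variant is out
of scope. Summary values are arithmetic band averages (4–30 Hz default),
inclusive of both edges.

## Evoked quantification

Firing probability counts spikes (not pulses) in the 20 ms window after
each pulse onset, divided by the pulse count; the PSTH bins are aligned
at the onset so the bins covering [0, 20) ms sum exactly to the firing
probability — an identity asserted on every simulated protocol. The
modulation index uses per-sweep pre/during spike rates; significance
comes from flipping each sweep's pre/during labels (a sign-flip
permutation test, 1000 permutations by default, two-sided at 0.05), and
units are classified activated / inhibited / unchanged. Because the MI
is monotone in the summed rate difference when the total is fixed, the
permutation statistic is the sign-flipped rate-difference sum.

Evoked LFP amplitude is the largest absolute deviation from the 50 ms
pre-pulse baseline within 100 ms after onset, reported unsigned with its
latency and signed polarity. CSD is the negative second spatial
difference with Vaknin padding (duplicated end channels) and optional
3-point Hamming smoothing; on a linear depth profile the interior CSD is
exactly zero (the padded edge channels are nonzero by construction — a
known property of Vaknin padding, not an error). Ramp analyses compare
the 1.5 s window before onset with the last 1.5 s of the 3 s ramp, for
power and (by the same window rule, chosen for consistency) for
coherence; "normalized change" is the ratio minus one, so 0 means no
change and +1 a doubling. The sign conclusions are identical under the
difference convention. For presynaptic-silencing protocols the "post"
window starts at the pulse-train offset; its length defaults to the same
1.5 s and is configurable, since the original protocol leaves it
unstated.

Evoked-EPSC sweeps are averaged; onset is the first post-stimulus time
at which the response speed exceeds 10 pA/ms, evaluated on a derivative
spanning 0.2 ms so that sample-to-sample noise cannot trip the
criterion; the rise time spans 20–80% of the baseline-subtracted peak;
the CV is SD/mean of per-sweep peaks; a cell is responsive when the
average peak exceeds 3 baseline SDs at latency below 9 ms.

## Statistics and behavior

`wilcoxon_ranksum()` reports the sum of ranks of the first sample and a
z value with tie and 0.5-continuity corrections, taking the exact p
(from the null rank distribution) when `min(n) <= 10` without ties —
the convention under which two-sample results are reported alongside
`ranksum` and `zval`. `chisq_2x2()` applies the Yates continuity
correction by default: it is the convention that reproduces the
responder-proportion statistics from their raw counts (the uncorrected
statistic, available via `yates = FALSE`, equals the familiar closed
form and differs). The original analysis screens samples with an F test
before choosing ANOVA versus rank-sum; `compare_groups()` mirrors this
as a variance-homogeneity gate and the documentation flags the
unconventional usage. The discrimination index is
`(novel − familiar)/(novel + familiar)` per animal, and animals
exploring below 20 cm/min (strictly) are excluded before scoring. No
multiple-testing correction is applied anywhere, matching the original
reporting.

## The synthetic-data generator

The generator is the package's ground truth, not a fixture. Its defaults
are the study conditions the analyses assume:

* **Latent dynamics.** A 3-region MVAR(4) at 100 Hz: each region's
  diagonal polynomial is the product of a theta pole pair (8 Hz, radius
  0.90) and a beta pole pair (20 Hz, radius 0.65); directed coupling
  enters at lag 1 with gains LEC→HP 0.35, HP→PFC 0.25, LEC→PFC 0.08.
  Stability is checked via the companion matrix; unstable configurations
  raise an error. The latent rate keeps the model order small; the
  process is FFT-upsampled (band-limited) to the 1 kHz LFP rate.
* **Bursts.** A renewal process with mean inter-onset matching the
  configured rate (default 8/min), log-normal durations (mean 3 s,
  minimum 1.2 s), raised-cosine 100 ms edges, 1 s minimum gap. Each
  burst is scaled to the configured SNR by a per-event gain *common to
  all regions*: the stochastic envelope of the narrowband latent process
  would otherwise spread individual events over many dB around the
  average, and a common gain leaves the cross-region MVAR structure
  untouched.
* **Background.** 1/f (exponent 1) Gaussian noise at 40 µV RMS plus a
  continuous slow rhythm: a quasi-sinusoid at a per-recording base
  frequency drawn from 2.4–3.6 Hz with slow ±0.15 Hz wobble and ±10%
  amplitude modulation, at 25 µV RMS. The slow rhythm is deliberately
  *amplitude-stable*: respiration-locked rhythms do not wax and wane
  like narrowband noise, and a noise-based implementation would leak
  burst-like excursions into the detection band.
* **SNR convention.** `burst_snr_db` (default 6) is the RMS of the gated
  oscillation relative to the RMS of the background *in the full
  detection band* (3–100 Hz). Under this definition the 6 dB default
  produces roughly 8–10 dB of inside/outside power contrast within
  4–30 Hz, which is what the detector actually faces.
* **Group contrast.** The `"GE"` variant multiplies the LEC→HP gain by
  0.4 and the burst power by 0.5, and lowers the responder fraction from
  0.27 to 0.11 — the responsive-unit proportions of the in vivo counts
  (22/81 and 8/73).
* **Laminar geometry.** With `n_channels_per_region >= 3`, each region
  projects over a probe via a difference-of-Gaussians sink/source pair
  (separation 2 channels, spread 1.5), giving a known CSD sink location.
* **Spikes.** Inhomogeneous Poisson trains whose log-rate follows the
  z-scored 4–30 Hz LFP amplitude, normalized so the mean rate equals the
  configured baseline (0.5 Hz default); responder units emit one extra
  spike with probability `p_resp` at 3–10 ms after each light pulse;
  1 ms dead time.
* **Behavior.** Truncated-normal interaction times per animal (CON:
  novel 5.25 s vs familiar 2.13 s; GE: 3.81 vs 1.93; SD 1 s) and a 10%
  fraction of low-exploration animals to exercise the exclusion rule.

What the generator does **not** emulate: spike waveforms and sorting
(units are given, not sorted), non-Poisson spike-train structure
(bursting, refractoriness beyond dead time), state changes over the
recording, electrode drift and artifacts, conduction delays beyond MVAR
lags, and biophysically detailed laminar geometry. Passing recovery
tests therefore demonstrate correctness of the estimators under the
stated statistical structure — not robustness to every pathology of real
recordings.

## Numerical choices and problem sizes

Determinism: every simulation consumes an explicit seed
(`sim_config(seed=)`), and the pipeline fans one global seed into
per-stage child seeds by fixed integer arithmetic, so any stage can be
re-run in isolation bit-identically. Welch normalization uses the taper
power so that white-noise density and sinusoid band power match their
closed forms (Parseval within 2% is a standing test). The MVAR BIC uses
the ML covariance; the reported innovation covariance is the
bias-corrected one. Ties in the sink search of the CSD resolve to the
first (most superficial) extremum.

The test and acceptance runs use problem sizes chosen to keep each
recovery estimate well-determined while the whole suite stays fast:
600 s recordings for detector operating characteristics (about 20
bursts at 2/min), 120 s and 90 s recordings for the 50-seed
directionality and 50-pair group-contrast checks, 60 s at the model rate
for MVAR coefficient recovery, 100 epochs for coherence properties,
1224 pulses for firing-probability recovery, and 5000 null replicates
for the calibration of the rank-sum and permutation tests.

## Known limitations

* The container format stores signals as float64; very long multi-probe
  recordings may warrant chunked/compressed storage not implemented
  here.
* gPDC inherits the usual MVAR caveats: linearity, epoch stationarity,
  and sensitivity to unobserved common drivers. The band-limiting
  substitute for the original wavelet de-noising is transparent but not
  identical.
* The detector's Gaussian-fit threshold assumes the noise body dominates
  the RMS histogram; recordings that are mostly burst (duty cycle well
  above ~50%) shift the mode and need `mode_def = "max"` or a manual
  threshold.
* Exact rank-sum p-values are used only for small tie-free samples;
  elsewhere the normal approximation applies, with its usual small-n
  conservatism.
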