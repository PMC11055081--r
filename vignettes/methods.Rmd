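---
title: "Validating video-based drowsiness scoring against EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating video-based drowsiness scoring against EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drowsEEG)
```

## The problem

Drivers with obstructive sleep apnea are at elevated risk of falling asleep
at the wheel. A camera pointed at the driver's face gives a cheap,
non-contact drowsiness signal: the eye aspect ratio (EAR), computed from
six eye landmarks per frame, collapses towards zero whenever the eye
closes. Two summary statistics of the per-frame open/closed sequence —
PERCLOS (the fraction of closed frames in a time window) and CLOSDUR (the
duration of an ongoing closure) — define drowsiness by the established
rule *PERCLOS ≥ 0.3 or CLOSDUR ≥ 2 s*, and wakefulness by both being
below. Video scoring alone, however, is fragile (lighting, eyewear, head
pose), so each scored episode is validated against the simultaneous EEG:
during drowsiness, low-frequency band power rises and alpha-range power
falls, and summary spectral features move accordingly.

`drowsEEG` implements the full chain — blink detection from EAR traces,
episode scoring, per-episode EEG feature extraction, episode-level
concordance, and channel/region sensitivity aggregation — plus a coupled
EAR + EEG simulator, because clinical recordings of this kind cannot be
redistributed. Every quantitative claim in this vignette is one the test
suite or the reproduction script actually computes.

## Blink detection from the EAR trace

The EAR of one eye with landmarks $p_1..p_6$ is

$$\mathrm{EAR} = \frac{\lVert p_2-p_6\rVert + \lVert p_3-p_5\rVert}{2\,\lVert p_1-p_4\rVert},$$

a dimensionless quantity invariant to translation, rotation and scale of
the landmark set. If both eyes are available the two ratios are averaged
(`compute_ear()`); the original method does not state which eye was used.

A fixed EAR threshold (conventionally 0.2) misclassifies subjects whose
open-eye baseline sits low or high. The adaptive detector instead tracks
a slow baseline — a median filter of length 17 frames followed by a
moving average of length 5 frames — and subtracts a constant offset of
0.04 EAR units to form a per-frame threshold. A frame is *closed* when
the **raw** EAR falls below the threshold. Comparing the raw signal is
essential: at 30 fps the 17-frame median spans ≈0.57 s and would erase
ordinary 100–400 ms blinks from the smoothed signal itself, so the
smoothed signal can only serve as the baseline. Maximal closed runs of at
least `min_blink_frames` (default 2, ≈67 ms, rejecting single-frame
noise; no minimum is stated in the source method) become blink events.

**Iterative baseline refinement.** A plain median/moving-average baseline
follows a *sustained* closure down within about half a median window,
after which the threshold sits just under the closed-eye level and the
rest of the closure is classified open. Multi-second closures — the very
events the 2-second CLOSDUR criterion needs — would then be truncated to
their onsets. The detector therefore refines the threshold iteratively:
frames currently below the threshold are treated as closed and replaced
by the last preceding open-eye value, the baseline is recomputed, and the
suspected-closed set grows monotonically until it stabilises (default cap
100 passes; each pass extends the detected closure by about half a median
window). With refinement disabled (`refine_iterations = 0`) the threshold
is exactly the filter composition `moving_average(median_filter(x)) - 0.04`,
and the truncation behaviour is observable — the test suite asserts both
regimes. The refinement is our reading of the method's "iterative
process [that] continuously refined the threshold"; the published
description does not spell out the mechanism.

```{r blink-example}
v <- rep(0.30, 600); v[200:289] <- 0.05   # one 3 s closure at 30 fps
detect_blinks(ear_trace(v, 30))$blinks
```

## Episode scoring

`segment_episodes()` turns the per-frame closed sequence into a table of
contiguous, strictly alternating wake/drowsy episodes:

* **PERCLOS track** — trailing 60 s sliding window, evaluated per frame
  and truncated at the session start. The 60 s window is the "within a
  minute" regulatory definition; the source method never states its
  window.
* **CLOSDUR rule, retroactive** — a closure run that reaches 2 s marks
  drowsiness from the run's *first* frame, so one closure is never split
  across an episode boundary. This is an offline-scoring choice.
* Maximal same-flag runs become episodes; an optional `min_episode`
  merges sub-minimum runs into their predecessor (off by default).

Raising either threshold can only shrink the drowsy flag set, so total
drowsy time is monotone non-increasing in both thresholds (tested).
Eye-closure degree is proxied by the blink detector's threshold crossing;
no separate 80%-closure estimator exists, matching the method being
reproduced.

## EEG preprocessing

Each channel is band-limited with a high-pass at 1 Hz and a low-pass at
30 Hz, both equiripple (Parks–McClellan) designs applied forward and
backward (zero phase) so episode boundaries are not delayed; a causal
single-pass mode is available.

The low-pass keeps the conventional order 25 (passband edge 30 Hz,
transition to 40 Hz): it converges cleanly and gives ≈29 dB stopband
attenuation per pass. The high-pass cannot be realised at order 25: a
1 Hz edge at a 200 Hz rate leaves every 26-tap equiripple design with
more than 25% passband ripple and essentially no DC rejection (we
measured the whole design grid; the best designs had DC gain ≈ passband
gain). The package therefore gives the high-pass its own default order,
350, with stopband [0, 0.5] Hz, passband from 1 Hz, and a 10:1 passband
weight: the EEG passband is flat within ±3% and DC is attenuated ≈11 dB
per pass (≈22 dB after the zero-phase double application). Both orders,
edges, transitions, weights and the zero-phase flag are configurable
(`preprocess_config()`).

## Per-episode features

Episodes are cut out of the filtered recording by
`round(t × sampling_rate)` (with a configurable constant video-to-EEG
clock offset, since the two clocks are reconciled only through recorded
start times), and each (episode, channel) segment yields ten features:

1. **Band powers** `psd_delta`, `psd_theta`, `psd_alpha` over the printed
   edges delta 1–4, theta 4–7.5, alpha 7.5–15 Hz (beta 15–30 Hz is used
   in synthesis and decomposition but is not a reported feature).
2. **Ratios** theta/alpha, delta/alpha, delta/theta.
3. **Spectral entropy** $H = -\sum_f n_f \log_2 n_f$ over the normalised
   PSD in 1–30 Hz, in bits, *not* normalised by $\log_2 L$.
4. **Spectral centroid** $C = \sum_k f_k X_k / \sum_k X_k$ (Hz),
   **spread** $\sqrt{\sum_k (f_k - C)^2 X_k / \sum_k X_k}$ (Hz), and
   **rolloff**: the smallest bin whose cumulative weight reaches fraction
   $C$ (default 0.9) of the total. The weights $X_k$ are PSD values by
   default; the source calls $X$ "amplitude" without defining it, so a
   `magnitude` option (square-root weights) is provided. Centroid in Hz
   versus in bin index differ only by a positive affine map on a uniform
   grid, so all episode comparisons are invariant to that choice
   (tested).

**PSD estimator.** Welch's method: Hann window, segment length
`min(episode length, 2 s)`, 50% overlap, segments zero-padded to 4× the
window before the FFT (0.125 Hz grid at 200 Hz). The source names no
estimator parameters; the 2 s/50% choice is conventional for episodes of
a few seconds. The zero-padding matters for one statistic: the rolloff is
the frequency of a discrete bin, and on a 0.5 Hz grid its values tie
across episodes often enough to visibly depress strict-inequality
comparisons (the zero-effect calibration below would sit ≈3 standard
errors low for rolloff, and only for rolloff). The finer grid restores
the behaviour expected of a continuous statistic. Episodes shorter than
`min_length` (default 1 s) yield missing feature rows rather than
unstable estimates.

**Wavelet route.** A level-3 discrete wavelet transform with the db2
wavelet maps detail/approximation coefficients to bands. At 200 Hz the
dyadic edges (0–12.5–25–50–100 Hz) cannot match the printed band edges,
which correspond to a 60 Hz rate (edges 15/7.5/3.75 Hz); the package
therefore resamples segments to 60 Hz (polyphase, anti-aliased) before
decomposing, and D1→beta, D2→alpha, D3→theta, A3→delta, with 3.75 Hz
approximating the printed 4 Hz theta/delta edge. This mismatch is a
property of the stated design, resolved here explicitly. The transform is
periodised and orthonormal: reconstruction is exact and coefficient
energy equals signal energy to 1e−10 relative on random segments
(tested; the implementation is coefficient-identical to the standard db2
periodisation convention). Welch integration is the default band-power
path, matching the "power within these specific ranges" phrasing; the
DWT path (`band_power_method = "dwt"`, mean square of a band's
reconstruction) is a config-selectable alternative. On white noise the
two routes agree within 25% at bands whose printed and dyadic edges
coincide (tested); note db2's 4-tap filters are gentle — a 10 Hz tone at
60 Hz puts ≈71% of its energy in D2, with the rest leaking into
neighbouring bands.

## Concordance and sensitivity

Each feature has a direction of change with drowsiness: the three
ratios, theta and delta power and the spread increase; alpha power,
entropy, centroid and rolloff decrease. A **drowsy** episode $i$ is
*concordant* on a channel when its value is on the drowsy side of **both**
neighbouring wake episodes $i-1$ and $i+1$ (single-sided at session
boundaries — the boundary episode is compared, not excluded). The source
never defines when a **wake** episode counts as concordant although its
counts include both classes; the package adopts the mirrored rule — wake
$j$ is concordant when its value is on the wake side of *every* adjacent
drowsy episode — as the symmetric completion, and makes it a
configuration point of `label_episodes()`. Over a channel set an episode
is concordant if *any* channel makes it so; enlarging the set therefore
never removes concordance (tested as an invariant). All comparisons are
strict inequalities, hence invariant under strictly increasing transforms
of a feature (tested).

Sensitivity of a channel is 100 × concordant/total episodes; the combine
sensitivity of a channel set applies the union rule; cross-subject
averages are arithmetic means. The printed combine formula's
parenthesisation reads literally as $1 - x \times 100$; since every
reported value is a percentage in [0, 100] it is implemented as
$(1-x)\times 100$. Regions are exactly the pairs F3/F4 (frontal), C3/C4
(central), O1/O2 (occipital). Reports round to one decimal and retain the
raw per-subject vectors. Per-subject (total, concordant) count pairs feed
a tie-corrected Spearman correlation with a two-sided t-approximate
p-value — the only reading that yields one coefficient per feature over a
cohort. The denominator of a channel's sensitivity counts *all* episodes
(wake and drowsy): the worked single-subject example (23 of 29 episodes,
79.3%, with 29 = 15 wake + 14 drowsy) fixes that choice.

## The simulator

`simulate_session()` generates a coupled EAR trace and six-channel EEG
with known episode structure. Defaults describe the emulated study
conditions: 3000 s session, 30 fps video, 200 Hz EEG; alternating wake
(uniform 60–180 s) and drowsy (20–90 s) segments; wake blinks Poisson at
12/min lasting 100–300 ms; drowsy closures 2–6 s targeting PERCLOS 0.4;
open/closed EAR levels 0.32/0.05 with 0.01 Gaussian noise and two-frame
transitions. These values are what a practitioner would call a typical
mildly drowsy driving session consistent with the scoring thresholds;
none is stated in the source beyond the rates, criteria and the session
length.

EEG synthesis sums, per channel, four band-limited Gaussian noise
components (frequency-domain brick-wall shaping of white noise) plus
broadband noise (s.d. 0.5). Per-band standard deviations switch between
wake targets (delta 10, theta 8, alpha 12, beta 6 µV²) and drowsy targets
(25, 16, 6, 6) scaled per channel by a gain on the *effect*
(`power = wake + gain × (drowsy − wake)`), largest on F4, then O2 —
mirroring the frontal/occipital dominance the validation narrative
reports. Calibration is empirical (measure-and-rescale): the simulator measures,
with the package's own Welch estimator, how much of each unit component
lands in every band — the Hann window leaks across band edges, mostly
from delta into theta — and solves the resulting 4×4 linear system so
the *measured* per-band powers hit the targets exactly in expectation.
Episode-level measurements then close the loop with the feature
extractor to within 15% (tested on 60 s segments; shorter episodes add
estimator variance but no bias). The ground truth
carries the episode table plus each feature's expected direction per
channel, computed from idealised flat-in-band spectra with the same
formulas the extractor uses — under the default targets the synthetic
spread *decreases* with drowsiness, so the simulator does not reproduce
the empirically reported spread trend, and tests assert only the
construction-driven directions. A single seed drives per-sub-generator
streams, so sessions are bit-reproducible.

What the simulator does **not** emulate: 1/f spectral shape, ocular and
EMG artifacts, non-stationarity within a state, inter-subject variability
beyond the seed. Passing the suites below therefore shows the *pipeline*
is correct and calibrated, not that the method generalises to clinical
recordings.

## Validation studies and their sizes

Two canned studies close the loop end to end; both are re-run from
scratch by `scripts/acceptance.R` and by the test suite.

**Zero-effect null (`run_null_study()`).** With drowsy and wake EEG
statistically identical and all episodes the same length (5 s — equal
lengths make the feature values exchangeable), the probability that an
interior drowsy episode beats both wake neighbours is exactly 1/3 for a
continuous feature. The study uses 2000 interior drowsy episodes on one
channel. Consecutive drowsy episodes share a wake neighbour, so pass
events are lag-1 correlated; integrating over the order statistics of
five iid uniforms gives covariance $2/15 - 1/9 = 1/45$, and the standard
error used is $\sqrt{(p(1-p) + 2/45)/n}$ — the correct s.e. of the
estimator under the tiling structure. All ten features must fall within
3 s.e. of 1/3.

**Strong effect (`run_strong_effect_study()`).** Three subjects × 200
episodes (wake 8–12 s, drowsy 5–9 s — scaled-down episode lengths keep
the cohort inexpensive while leaving ≥1000 Welch samples per episode).
Channel gains are spread (F4 = 1.0 down to C3/C4 = 0.15) because with
every gain near 1 the per-channel sensitivities all saturate at 100% and
the ranking claim is vacuous; with the spread configuration the
theta–alpha all-channel combine sensitivity must reach ≥95% and F4 must
rank strictly first. Both studies run the genuine pipeline (simulate →
filter → features → concordance → report) on the simulator's ground-truth
episode table; recovering that table from the EAR trace is validated
separately (a strong-closure session must be recovered episode-for-episode
with ≥95% drowsy-time recall), so each study measures one thing.

## Numerical choices and degenerate inputs

* Filter edge handling: truncated (shrinking) windows for both EAR
  filters — no padding, no fabricated data at session boundaries.
* DWT input lengths not divisible by 8 are extended by periodic wrap and
  trimmed after reconstruction; reconstruction of the original samples
  stays exact, and Parseval holds on the padded signal.
* All-zero spectra are errors for the spectral features (no silent 0/0);
  empty windows are errors for PERCLOS; degenerate eye width
  ($p_1 = p_4$) is an error for EAR.
* Episodes outside the recording raise an error naming the episode;
  missing per-episode features propagate as `NA` and fail concordance on
  that channel rather than being imputed.
* EDF export snaps physical min/max to their 8-character header encoding
  before quantisation so writer and reader use identical scaling;
  round-trips are exact to one 16-bit step of each channel's range.
* Timestamps are ISO-8601 with millisecond precision in files; internal
  time is seconds from recording start. EDF start times carry second
  resolution, as the format defines.

## Known limitations

* The wake-episode concordance rule and the exact PERCLOS window are this
  package's completions of an under-specified method; both are exposed as
  configuration.
* The printed per-feature correlation for theta–alpha appears in the
  source once as r = 0.9971 and once as r = 0.9942; reproducing either
  exactly is not possible without the original recordings, which are
  unavailable for ethical reasons.
* An order-25 equiripple high-pass at 1 Hz/200 Hz is unrealisable; the
  package's high-pass deviates (documented above) rather than shipping a
  filter with no stopband.
* db2's short filters leak across dyadic band edges; the Welch route is
  the default for band power partly for this reason.
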