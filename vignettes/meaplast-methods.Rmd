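---
title: "Models and methods behind meaplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meaplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaplast)
```

`meaplast` analyzes optogenetic learning experiments on dissociated cortical
cultures growing on multielectrode arrays (MEAs): networks expressing
channelrhodopsin-2 are stimulated with structured light while 252 electrodes
(a 16 × 16 grid at 200-µm pitch, corners unoccupied) record extracellular
spikes. This vignette documents the models the package implements, the
parameters that matter, and the design choices made where the underlying
procedures left the design open.

## Connectivity probing

A probing session stimulates every cell of a stimulation grid (16 × 16 over
the electrode field; 256 "dots") exactly `n_reps` times, a few dots at a
time, in random order. `makeProbingSchedule()` guarantees *exact* balance:
the multiset of position slots is shuffled, packed into frames of
`dots_per_frame`, and within-frame duplicates are repaired by swapping with
later slots — swaps preserve the multiset, so every position appears exactly
`n_reps` times no matter what. With the standard parameters (20 repetitions,
5 dots per 100-ms frame, 40 ms light-on) the movie has 1024 frames, 5120
position-stimulation events, and lasts ≈1.7 min.

For each (position, electrode) pair, both event trains are binarized into
1-ms bins and the cross-correlation histogram

$$\mathrm{cch}(\tau) = \sum_t i(t)\, j(t-\tau)$$

is computed over lags 0–100 ms (one frame; the searched range is a package
choice, as is marking only the stimulus *onset* bin in $j$ — one mark per
trial makes the peak count equal the responding-trial count in the
deterministic limit). The peak $k$ at lag $\tau_p$ is tested against a
Poisson null whose mean $\lambda$ is the average correlogram count over the
searched lags:

$$P(k) = \frac{e^{-\lambda}\lambda^k}{k!},$$

evaluated in log space. A connection is drawn when $P(k) < 10^{-6}$ *and*
the electrode responds (≥ 1 spike within $\tau_p \pm 5$ ms) in more than
half of the trials, resolved as $\ge \lceil n/2 \rceil$ so that 10 of 20
passes. The 5-ms response half-window is a package choice; the $10^{-6}$
threshold is the established empirical operating point (at $10^{-5}$
tonically firing channels acquire connections to nearly every position, at
$10^{-7}$ too few connections survive). Whether $P(k)$ should be the pmf or
the upper-tail probability is ambiguous in the source procedure's wording;
the pmf is the default, and `detectionParams(upper_tail = TRUE)` switches to
$P(X \ge k)$. Connection efficacy is the area under the 100-ms, 1-ms-binned
PSTH in spikes/trial; the CCH peak is additionally reported normalized to
100 trials.

Ties at the peak are broken toward the smallest lag. Empty series yield an
all-zero correlogram with $\lambda = 0$, and $P(k;0)$ uses the empty-null
convention (1 for $k = 0$, else 0).

## Efficacy changes, P/N/R

`compareMaps()` anchors on the connections detected in the *before* map and
recomputes the PSTH area for the same (pre, post) pairs on the after-session
— whether or not they are independently re-detected there, since depression
would otherwise bias the comparison toward survivors. The relative change is
$(A_{\mathrm{after}}-A_{\mathrm{before}})/A_{\mathrm{before}} \times 100\%$;
positive changes above 100% contribute 101 to the potentiation sum P (the
cap keeps single exploding ratios from dominating), negative changes sum to
N, and $R = P/|N|$ summarizes the network: $R > 1$ network-level LTP,
$R < 1$ LTD. When $N = 0$, R is reported as NaN, never infinity.
Connections with zero baseline area are skipped with a warning.

## Burstiness, SNB detection, quality control

The burstiness index pools all electrodes' spikes into 1-s bins and takes
the fraction $f$ of spikes in the 15% most active bins:
$\mathrm{BI} = (f - 0.15)/0.85$, 0 for non-bursting and 1 for maximally
bursting activity. The 1-s/15% convention implies a 6.7-s interburst
interval; for cultures bursting faster, `burstinessIndex(ibi_est_s = ...)`
raises the top fraction to $\mathrm{bin}/\mathrm{IBI}$ — our resolution of
"increase the 15% accordingly", preserving the one-burst-per-top-bin
occupancy logic.

The SNB detector (the underlying procedure for which is not prescribed
anywhere, so this is package design) thresholds the population rate in
10-ms bins at 5 × the median *nonzero* rate, additionally requires ≥ 25% of
electrodes active in the bin, merges burst bins within 100 ms and drops
intervals shorter than 100 ms. These defaults assume background activity
dominates the nonzero bins; very sparse recordings (a handful of electrodes
at < 0.5 Hz) can halve the effective threshold and fragment bursts.

Quality control excludes cultures with spontaneous SNB frequency above
0.2 Hz (too active) or below 0.05 Hz (too quiet), and — when an RDM
suppression ratio is available — cultures whose bursting the random-dot
movie failed to suppress ($R > 0.2$).

## Replay decoding and the familiarity metric

Pattern-evoked responses are binned at 10 ms over a 200-ms post-onset
window (the informative span is roughly 30–120 ms; the window adds margin).
Every bin of every trial becomes one SVM instance — its per-electrode count
vector labeled by the trial's pattern ("pooling all samples" sidesteps the
curse of dimensionality), including all-zero bins. The classifier is a
linear-kernel SVM with cost 1 and one-vs-one multiclass (the libsvm
defaults, via `e1071`); kernel and cost are exposed. Trials with an SNB
within 1 s *before* stimulus onset are removed as noisy; the package
additionally removes trials with a burst intersecting the response window
itself (`exclude_during = TRUE`), because in the simulator bursts are
independent of the stimulus and a burst riding on a response would enter
training as a pattern-labeled burst profile and corrupt replay decoding.

The trained classifier is applied to 10-ms bins of a continuous spontaneous
recording; a bin belongs to an SNB when its midpoint falls inside a
detected burst interval. The per-class ratios of classified SNB bins, and
likewise the per-pattern mean evoked firing rates, feed the normalized
familiarity metric

$$\Delta = \frac{(x_f - x_{c1}) + (x_f - x_{c2})}{2\,x_f},$$

where $x_f$ is the response to the familiar (trained) pattern. $\Delta > 0$
means the familiar pattern dominates; note $\Delta$ is unbounded below when
$x_f$ is small, so medians are the appropriate summary across runs.

`accuracyTimecourse()` validates the decoder on held-out trials (60/40
split, stratified per class, 10 reseeded splits for the SEM): with evoked
latencies near 30 ms, accuracy sits at chance in the pre-response bins and
rises well above 1/number-of-classes afterwards.

## The synthetic network

`GroundTruthNetwork` is a phenomenological generator, not a biophysical
model. It emulates exactly the statistical structure the analyses consume:

- **Background**: homogeneous Poisson per electrode (default 0.5 Hz).
- **SNBs**: onset gaps Normal(6.7 s, 1.5 s) truncated so bursts never
  overlap; 300-ms bursts during which every electrode fires Poisson at a
  within-burst rate (default 30–40 Hz) times its participation gain. The
  inverse of the mean gap puts the demo culture at ≈0.15 Hz, inside the QC
  band.
- **Evoked responses**: each connection fires at most one spike per
  stimulated frame, with probability `response_prob` (times the frame's
  intensity, capped at 1) at onset + Normal(latency mean, SD). The
  one-spike-per-trial rule keeps the binomial trial-response semantics
  exact. Per-connection latency means are jittered around 30 ms (SD 4 ms
  across connections); the per-trial SD defaults to 0.5 ms because the
  1-ms CCH binning requires sub-millisecond response jitter for peak counts
  to approach the trial count, as real probings show.
- **Plasticity**: the tetanus transform potentiates connections whose
  presynaptic cell the pattern lights *and* whose postsynaptic electrode
  receives at least `hub_threshold` lit inputs (multiplicative gain, capped
  at 1) — hub-clustered potentiation; in the bursty regime it instead
  depresses every connection uniformly, modeling the SNB-saturated outcome.
  The RDM transform multiplies all response probabilities by a depression
  factor (default 0.6) and lengthens the interburst interval (×3, burst
  suppression).
- **Replay bias**: per-electrode SNB gains proportional to the electrode's
  summed evoked drive from the stored pattern, normalized to mean 1 and
  mixed with a uniform component by a strength weight (default 0.8). With
  no bias, SNB firing is spatially uniform.

What the generator does *not* emulate: latency/excitability drift,
correlated background noise, burst waveform structure (onset propagation,
reverberation), electrode-specific noise floors, and any dependence of
burst timing on stimulation. Passing tests therefore demonstrate the
*analysis chain* is correct and calibrated against known ground truth — not
that real cultures behave this way.

Pattern drive differs between the three built-in line drawings (they light
different numbers of grid cells), so `runExperiment()` balances per-pattern
intensities against the network's summed drive before the baseline phase —
the in-silico counterpart of tuning projected luminance to balance baseline
responses. Without it, the familiarity metric measures pattern size, not
learning.

## The simulated paradigms

`runExperiment()` executes the two protocols with a CCH probing between
phases:

- conventional: CCH – baseline – CCH – 50-Hz tetanus (bursty regime) – CCH
  – testing – CCH;
- RDM-learning: CCH – baseline – CCH – RDM – CCH – 50-Hz tetanus
  (potentiating regime, replay bias armed) – CCH – testing – CCH.

Spontaneous recordings before baseline and immediately after learning
provide the SNB material for replay decoding (before: classifier trained on
baseline responses; after: classifier trained on testing responses).
Probings follow each treatment directly; the treatments themselves are
instantaneous transforms of the ground-truth state, so no settle recording
is simulated between phases.

## Problem sizes and defaults

End-to-end runs use a demonstration-scale culture — an 8 × 8 stimulation
grid over a 6 × 6 electrode array with 90 planted connections (response
probabilities 0.7–0.95), 20-repetition probings, 10 presentations per
pattern and 300-s spontaneous recordings — chosen so a full two-paradigm,
multi-seed comparison runs in minutes while every stage still operates well
above its detection floors (a probing yields ~2000 spikes; a spontaneous
recording ~45 bursts). The full 16 × 16 / 252-electrode geometry is
supported throughout and used for the schedule-arithmetic checks.

## Known limitations

- The detection pipeline targets strong, temporally precise connections;
  with per-trial latency jitter ≳ 1.5 ms at 1-ms binning the Poisson peak
  test loses power rapidly (real probings sharing this property is exactly
  why the correlogram works there).
- The SVM replay decoder extrapolates from evoked-response instances to
  much denser burst vectors; with unequal pattern footprints the densest
  class attracts a systematic share of burst bins. The per-class ratios are
  therefore only interpretable relative to a control (before-learning
  recording or unbiased simulation), which is how the package's own
  acceptance checks use them.
- `compareMaps()` anchors on the before-map; connections born after the
  treatment are invisible to P/N/R.
- Spike-sorted unit-level analysis, inhibitory (trough) detection and
  jitter-corrected CCH baselines are out of scope.
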