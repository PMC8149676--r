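---
title: "Detecting SO-spindle coupled memory reactivation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting SO-spindle coupled memory reactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepreplay)
```

# The scientific problem

During non-REM (NREM) sleep the cortex produces slow oscillations (SOs,
< 1.25 Hz alternations between a hyperpolarized *downstate* and a
depolarized *upstate*) and sleep spindles (transient 12-18 Hz
thalamo-cortical bursts). The two rhythms are temporally coupled: spindles
preferentially ride the rising flank and peak near the SO upstate. A central
hypothesis of systems consolidation is that this SO-spindle coupling opens a
window in which recently learned memories are endogenously reactivated, and
that the precision of the coupling (how close to the upstate the spindle
peaks) predicts how well memories survive sleep.

`sleepreplay` implements the complete analysis chain needed to test that
hypothesis in a nap study:

1. **Event detection** — SOs and spindles on the linked-mastoid NREM signal,
   and their pairing into SO-spindle complexes.
2. **Coupling** — the SO phase at the moment of maximal spindle amplitude,
   summarized per participant with circular statistics.
3. **Decoding** — classifiers trained on a wake localizer (two stimulus
   categories) and tested on sleep epochs time-locked to SO downstates
   (temporal generalization), against shuffled-label surrogates.
4. **Inference and behavior** — cluster-based permutation tests over
   decoding maps, d', cued recall and a retention index, and the
   participant-level (partial, circular-linear, rank) correlations between
   coupling, reactivation strength and retention.
5. **Synthetic data** — a generator that plants all of the above with known
   ground truth, so every stage is verifiable without any recordings.

# Event detection

SO detection band-pass filters the target channel (default Cz) at
0.3-1.25 Hz with a two-pass FIR filter whose length is three cycles of the
low cut-off (10 s of taps), applied forward and backward so the phase is
untouched. Candidate events are spans between successive
positive-to-negative zero crossings containing a trough followed by a peak,
restricted to movement-free N2/N3 sleep; events lasting 0.8-2 s are kept.

**Amplitude criterion.** Duration-only SO detection is not usable on
broadband signals: band-passed 1/f background produces zero-crossing spans
with durations inside 0.8-2 s at a rate of roughly 20 per minute, so without
an amplitude rule most "SOs" would be noise. We therefore apply, by default,
the canonical absolute criterion of the SO-detection literature — a
trough-to-peak amplitude of at least 75 uV on the filtered trace — with
relative alternatives (`"mean1.25"`, `"percentile"`) and `"none"` available.
`amplitude_criterion = "none"` reproduces pure duration-based detection and
is what the unit tests use to validate the zero-crossing logic in isolation.

Spindle detection filters at 12-18 Hz (same FIR convention, 0.25 s of
taps), computes a root-mean-square envelope in centered 200-ms windows over
each contiguous run of clean N2/N3 data (window centers whose full window
does not fit in the run are discarded — shrinking edge windows would
inflate the envelope variance at segment borders), and thresholds at the
75th percentile of the pooled N2/N3 RMS distribution (linear interpolation
between order statistics; percentile dialects shift thresholds, so the
definition matters). Supra-threshold runs lasting more than 0.5 and less
than 3 s are events. Because a percentile threshold is scale-free, slow
envelope excursions of the background occasionally stay above it for half a
second regardless of how quiet the recording is; a dual-threshold rule
(event peak RMS at least twice the detection threshold, `peak_factor = 2`)
removes these while leaving genuine bursts — whose peaks sit far above the
threshold — untouched. `peak_factor = 0` restores the literal
single-threshold rule.

Complex pairing asks, for every SO, whether a spindle follows its downstate
within 1.5 s. The spindle anchor is its onset by default (a spindle
"detected following the SO" reads most naturally as the detection start
falling in the window); the trough or the envelope-peak time can be chosen
instead, and when several spindles qualify the earliest is paired — a
deterministic tie-break. Unpaired SOs and spindles are returned separately
for control analyses.

The descriptive time-frequency map uses sliding-window Fourier power with a
Hanning taper of five cycles per frequency (1-30 Hz in 1-Hz steps), stepped
every 50 ms, averaged over events and z-scored across time per frequency.
Epochs must be long enough to hold five cycles of the lowest frequency;
that is why event epochs for this map are cut at +/- 4 s or more even when
the analysis window of interest is +/- 1.5 s.

# Coupling phase

Within +/- 2.5 s epochs locked to SO downstates, the SO phase comes from a
Hilbert transform of the 0.3-1.25 Hz two-pass Butterworth-filtered signal
(2nd order per pass; the filter family is fixed, the order is a
convention — it is exposed as an argument), and the spindle amplitude from
the Hilbert envelope of the 12-18 Hz filtered signal. Only samples within
+/- 1.5 s enter the search for the amplitude maximum, keeping clear of
filter edge transients. The phase convention is the analytic-signal one:
0 at the upstate (signal maximum), +/- pi at the downstate, -pi/2 at the
down-to-upstate transition.

Per participant, event phases are summarized by the circular mean and
resultant length R; uniformity is tested with the Rayleigh statistic
`z = n R^2` and its standard small-sample p approximation. Associations
between a circular and a linear variable use the squared-multiple-
correlation form of the circular-linear coefficient with a chi-square(2)
p value. The partial circular-linear correlation residualizes *all three*
of x, cos(theta) and sin(theta) on the covariate before applying the same
formula — partialling only the linear variable is the other defensible
reading of a "modified" circular-linear correlation; we chose full
residualization because it is symmetric and reduces exactly to the plain
coefficient when the covariate is orthogonal to everything.

# Decoding

The preprocessing order is: whole-trial baseline correction, z-scoring per
channel and timepoint across trials, PCA on the pooled wake-sleep
observations with the first 30 components retained, then 150-ms
running-average smoothing in component space. Each step appends itself to a
`history` attribute, and a test asserts the order — pipelines of this shape
are notorious for silent step reordering.

The classifier is an LDA with its pooled covariance shrunk toward a scaled
identity (`gamma = 0.01`): 30 features estimated from a few dozen trials
per class need conditioning. Performance is the area under the ROC curve,
computed from ranks. Localizer decoding uses stratified fivefold
cross-validation, repeated five times with re-randomized folds and
averaged; wake-to-sleep temporal generalization trains on every localizer
timepoint and tests on every sleep timepoint with no cross-validation
(independent datasets). Sleep test labels are the category learned in each
epoch's session, so AUC above 0.5 means sleep activity resembling the
just-learned category.

Chance is estimated empirically: the training labels are shuffled 250
times, test labels left intact, and the resulting AUCs averaged into a
per-participant surrogate baseline. On pure noise this baseline must sit at
0.5; the acceptance suite verifies 0.5 +/- 0.01 under the full
preprocessing chain, which guards against the subtle optimism that
whole-set z-scoring and pooled PCA can otherwise introduce.

The searchlight variant back-projects the components to sensor space and
repeats the temporal generalization on small spatial neighborhoods,
collapsing the AUC over configured train/test windows. Neighborhoods are
radius-based with sizes clamped into 5-9 channels by nearest-neighbor
ordering; a single global radius cannot keep all sizes in that band on a
cap-shaped layout (boundary channels thin out while the interior
saturates), so the clamping is what actually guarantees the 5-9 feature
range.

# Group inference and behavior

Decoding maps are compared against surrogate maps with a dependent-samples
cluster permutation test: pointwise paired t values thresholded at
two-tailed p < 0.05, supra-threshold points clustered by contiguity
(adjacent samples in 1-D, 4-connectivity in 2-D), each cluster summarized
by the sum of its t values (maxsum), and the null distribution of the
maximum cluster mass built from random sign flips of the participant
difference maps — the exact permutation scheme for a paired design. The
Monte-Carlo p includes the observed statistic in the null set,
`p = (b + 1) / (m + 1)`, so it can never fall below `1/(m + 1)`; for small
cohorts the full `2^n` enumeration is available and the random scheme is
tested against it. Family-wise error calibration (5% +/- 2% over 500 null
simulations) is part of the acceptance suite.

Recognition memory is scored as `d' = z(hit rate) - z(false-alarm rate)`
with extreme proportions replaced by `1/(2N)` and `1 - 1/(2N)`; cued recall
as recalled images out of recognized words (percent); and the retention
index as the post-sleep recall-of-hits percentage relative to the pre-sleep
percentage, times 100, averaged across sessions. Correlations between
retention and reactivation strength use Spearman's rank correlation (average
ranks for ties, t approximation), optionally partialling a covariate on the
ranks; Steiger's z is provided for comparing two dependent correlations.

# The synthetic generator

`sim_config()` collects every generator constant. The defaults describe a
plausible 120-min-study-style nap scaled to 30 min: stages W, N1, N2, N3
and REM laid out in 30-s scoring epochs with two 5-s movement artifacts;
spatially correlated 1/f background (alpha = 1, 15 uV per channel, 30%
shared variance); SOs at 5/min during clean N2/N3 as single biphasic cycles
(75 uV trough, 40 uV peak, frequency jittered 15% around 0.75 Hz); 70% of
SOs carry a 14-Hz, 20-uV Gaussian-windowed spindle burst of 1.1-1.6 s
plus 2/min solitary spindles; and category-specific spatial patterns
injected 0.2-0.9 s after the downstate in half of the complexes, scaled by
`reactivation_snr` times the noise SD.

Two generator choices deserve emphasis:

* **Phase planting.** A spindle peak "at SO phase theta" is placed by
  inverting the Hilbert-phase timeline of the band-filtered SO template
  itself, not the ideal-sinusoid mapping `tau = (theta - pi/2)/(2 pi f)`.
  The instantaneous phase of an isolated filtered cycle is not linear in
  time; the ideal mapping leaves a phase-dependent bias of up to 0.3 rad
  that would corrupt ground truth. Since the band-filtered Hilbert phase
  *is* the operational definition of SO phase in this analysis, the
  template timeline is the correct planting rule, while the estimator still
  faces noise, spindle leakage and filter transients on the measured data.

* **The precision link.** Cohort simulations draw each participant's
  preferred phase from a von Mises around `coupling_mu = -0.64` rad with
  between-participant concentration `phase_dispersion_kappa = 6`, matching
  an across-participant resultant length of about 0.91 via
  `R = I1(kappa)/I0(kappa)`. Both the participant's reactivation SNR and
  the expected retention ratio are scaled by the same latent gain
  `((1 + cos(phase)) / 2)^5` — 1 at the upstate, 0 at the downstate. The
  fifth power was calibrated at design time so that, at the study's sample
  size of 20 participants, a single simulated cohort carries enough
  between-participant contrast for the planted coupling-reactivation and
  reactivation-retention correlations to be reliably recoverable; a linear
  gain leaves the cohort bunched within a ~25% SNR band (the paper-matched
  phase dispersion is narrow) and the planted correlations drown in
  decoding measurement noise. Event-level concentration defaults to
  `coupling_kappa = 5` for clean demonstrations; empirically realistic
  within-participant concentration is closer to kappa ~ 0.7 (per-participant
  resultant lengths around 0.34), and the parameter is free.

Behavior uses 120 old/120 new recognition items per session (hit rate 0.8,
false-alarm rate 0.15), pre-sleep recall-of-hits probability 0.55, and an
expected post/pre retention ratio of `0.3 + 0.7 * link * gain`, all counts
binomial. `behavior_link_strength = 0` severs the link, which the tests use
as a negative control.

What the generator does **not** emulate: REM cycling and realistic
whole-night architecture, ocular/muscle artifacts, volume-conducted forward
models, non-stationary spindle morphology, or any relationship between the
localizer ERP and sleep physiology beyond the shared spatial templates.
Passing tests on this generator therefore show that the pipeline recovers
what it assumes — correctly shaped events, von Mises coupling, linearly
mixed spatial patterns — not that those assumptions hold in any given
recording.

# Numerical choices and problem sizes

* Percentiles use R's type-7 (linear interpolation) definition.
* Angles are wrapped to (-pi, pi]; degrees appear only in printed output.
* The resampler applies an FFT low-pass with exact unit passband gain
  (raised-cosine roll-off from 80% to 100% of the new Nyquist) before
  interpolating, preserving in-band amplitudes to well under 1%.
* Epoch windows are endpoint-inclusive: `round((t1 - t0) * fs) + 1`
  samples, symmetric around the lock sample; sample indices are 0-based in
  time arithmetic.
* Zero-variance features are set to zero (with a warning) before
  classification rather than propagating NaN.
* Antipodal phase sets have R = 0 and an undefined mean; the mean is
  returned as NA with `mean_reliable = FALSE` rather than an arbitrary
  direction.
* The acceptance suite runs at deliberately desk-sized problem sizes: a
  30-min nap for detector recovery; 10,000 events for event-level phase
  recovery and 20 x 60 events at kappa = 1 for the group Rayleigh test;
  500 null simulations of 20 x 40-point maps with 1000 sign flips each for
  the family-wise-error calibration; and a 20-participant cohort (120
  localizer epochs, 2 x 60 sleep epochs, 32 channels, decoding grids
  decimated to 20-ms steps, 24 surrogate shuffles, 500 permutations) for
  the end-to-end reactivation analysis. These sizes are the package's
  validation design, chosen to estimate each quantity with comfortable
  statistical margin.

# Known limitations

* The detectors are single-channel (Cz by convention); no multi-channel
  consensus detection.
* The EDF writer quantizes to 16 bits over the per-channel range; signals
  mixing very large and very small channels lose precision (BrainVision
  float32 output does not).
* The Rayleigh p approximation is the standard small-sample exponential
  form; for n < 10 it is approximate (the acceptance checks use larger n).
* The partial circular-linear correlation's chi-square p does not reduce
  its degrees of freedom for the partialled covariate; with one covariate
  and the cohort sizes used here the effect is negligible, but it is a
  known approximation.
* Cluster inference assumes exchangeability of the signed participant
  difference maps — guaranteed under the paired null, but the surrogate
  maps must come from the same preprocessing as the observed maps for this
  to hold.
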