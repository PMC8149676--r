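# sleepreplay

Tools for studying **endogenous memory reactivation during sleep**: slow
oscillation (SO) and sleep-spindle detection in NREM scalp EEG, SO-spindle
phase coupling with circular statistics, wake-to-sleep temporal
generalization decoding with shuffled-label surrogate baselines,
cluster-based permutation inference, and signal-detection memory scoring —
plus a synthetic-data generator with planted ground truth that makes every
stage of the pipeline testable without any recordings.

The package is aimed at sleep/memory electrophysiologists who run nap or
night studies with a wake "localizer" task (two stimulus categories) and
want to quantify whether category-specific activity re-emerges during
SO-spindle complexes, and whether that reactivation tracks behavior.

## The analysis in brief

* **Events.** SOs are spans between successive positive-to-negative zero
  crossings of the 0.3-1.25 Hz filtered NREM signal containing a trough
  then a peak, 0.8-2 s long (with an amplitude criterion; see the
  vignette). Spindles are runs where the 200-ms RMS envelope of the
  12-18 Hz filtered signal exceeds its 75th percentile for 0.5-3 s. A
  complex is an SO whose downstate is followed by a spindle within 1.5 s.
* **Coupling.** Per complex, the Hilbert phase of the SO-band signal at the
  moment of maximal spindle-band amplitude (0 = upstate, +/-pi =
  downstate); per participant, the circular mean phase and resultant
  length R, with the Rayleigh test `z = n R^2` against uniformity, and
  circular-linear correlations against linear covariates.
* **Decoding.** Whole-trial baseline, per-timepoint z-scoring, PCA on the
  pooled wake-sleep data (30 components), 150-ms smoothing, then a
  shrinkage-regularized LDA scored by ROC-AUC: fivefold cross-validation
  within the localizer, and training-time x testing-time temporal
  generalization from localizer to downstate-locked sleep epochs, with a
  250-shuffle surrogate baseline per participant.
* **Inference.** Dependent-samples cluster permutation (maxsum statistic,
  sign-flip null, Monte-Carlo p with floor 1/(n_perm+1)); d' with the
  1/(2N) correction; cued-recall retention index; Spearman, partial
  Spearman and (partial) circular-linear correlations.

## Worked example

Simulate one participant's nap, detect events, and quantify coupling:

```r
library(sleepreplay)

cfg <- sim_config(seed = 1)                 # 30-min nap, 64 channels
sim <- simulate_sleep_recording(cfg, participant = 1)
eeg <- rereference(sim$eeg, "linked-mastoids")

sos      <- detect_slow_oscillations(eeg, sim$mask, channel = "Cz")
spindles <- detect_spindles(eeg, sim$mask, channel = "Cz")
paired   <- pair_so_spindle(sos, spindles, window = 1.5)
nrow(sos); nrow(spindles); nrow(paired$complexes)
#> [1] 76
#> [1] 103
#> [1] 42

epochs <- extract_epochs(pick_channels(eeg, "Cz"),
                         paired$complexes$so_downstate, c(-2.5, 2.5),
                         lock = "SO-downstate")
coupling_result(event_coupling_phase(epochs))
#> <coupling_result> n = 42 events; preferred phase = -0.482 rad (-27.63 deg);
#>   R = 0.856; Rayleigh z = 30.75, p = 6.23e-18
```

The printed summary is read as: across this participant's 42 SO-spindle
complexes, spindle power peaked on average 28 degrees before the SO upstate
(phase 0), with a resultant vector length of 0.86 — strongly nonuniform
(Rayleigh p << 0.001), i.e. spindles are phase-locked to the rising flank
of the SO, which is the physiological signature of intact SO-spindle
coupling. The generator planted phases around -0.64 rad (-37 deg), so the
estimate recovers the truth to within sampling error at this event count.

A cohort-level run — localizer decoding, temporal generalization onto sleep,
cluster statistics and behavior — is assembled exactly as in
`tests/testthat/test-acceptance.R`; the methods vignette
(`vignettes/so-spindle-reactivation.Rmd`) documents every model and
parameter.

## Scope

Manual sleep scoring is consumed as an input mask (`hypnogram_mask`,
`expand_hypnogram`), not produced; ICA artifact rejection is assumed done
upstream. File I/O covers EDF and BrainVision recordings and TSV/JSON
tables. See the vignette for design decisions and known limitations.
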