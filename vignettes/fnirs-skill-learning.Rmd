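---
title: "Mapping motor-skill acquisition with fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping motor-skill acquisition with fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirskill)
```

# The problem

When novices train on a bimanual surgical task such as laparoscopic
intracorporeal suturing, their skill is conventionally tracked with completion
times and error penalties. Portable neuroimaging adds a second, physiological
axis: continuous-wave fNIRS measures task-locked changes in oxy- and
deoxyhemoglobin (HbO/HbR) concentration over prefrontal and sensorimotor
cortex while the trainee works. `nirskill` implements the full analysis chain
for a longitudinal training study of this kind - 15 sessions over three weeks
(3 repetitions x 10-min practice blocks in sessions 1-5, 5 x 5 min in 6-10,
7 x 3 min in 11-15; 75 repetitions; 2-min rests between blocks; one retention
session after four weeks) - together with a synthetic-study generator so that
every stage can be validated against known ground truth.

# Signal model and preprocessing

A recording holds intensity at 760 and 850 nm, sampled at 5 Hz, for channels
defined by (source, detector) pairs. Channels under 15 mm separation sample
only scalp and skull ("short-separation" channels, optimally ~8 mm in
adults); channels near 30 mm reach cortex. The chain is, in order:

1. **Optical density.** `OD(t) = -log10(I(t)/I_ref)` per channel and
   wavelength. The reference is the channel's temporal mean (the first sample
   is available via configuration); the choice only shifts OD by a constant,
   which downstream drift terms absorb.
2. **Motion correction** (`correct_motion_sg()`), a hybrid spline +
   Savitzky-Golay scheme. Epochs where a 1-s moving window's amplitude range
   exceeds 0.4 OD or its SD exceeds 5x the series' median moving SD are
   flagged; inside each flagged segment the artifact trajectory is removed
   (smoothing-spline detrending for segments of at least 3 s; plain
   local-baseline replacement below that, where a spline on under 15 points
   is unstable), and the signal after the segment is re-anchored so step
   shifts do not persist. A Savitzky-Golay smoother (10 s frame, cubic) then
   suppresses residual spike-band content. The artifact mask marks flagged
   samples; the smoother, by design, touches every sample.
3. **Bandpass** in the neurovascular coupling band, 0.01-0.1 Hz: a 3rd-order
   Butterworth applied forward-backward. Zero-phase filtering matters because
   HRF timing must not shift; the tests verify a zero-lag cross-correlation
   peak, >= 90% RMS passage at 0.05 Hz and <= 10% at 0.5 Hz.
4. **Modified Beer-Lambert law.** Per channel and sample the 2x2 system
   `dOD(lambda) = d * PPF(lambda) * (eps_HbO dHbO + eps_HbR dHbR)` is solved
   for the chromophores. Distances enter in cm, extinction coefficients in
   cm^-1 mM^-1 (the standard compiled hemoglobin spectra, swappable because
   they set the micromolar scale), and partial pathlength factors of 1.0/1.0
   yield micromolar units.

# HRF estimation

Each long channel's concentration series is fit by ordinary least squares on
a *deconvolution* design: 125 Gaussian bases (SD 0.5 s, means every 0.5 s,
peri-onset range -2 to 60 s; unit peak, so coefficients are in uM),
time-locked to every practice-block onset, plus drift terms, plus the
selected short-separation channel series of the same chromophore as a
nuisance regressor (nearest by default; by maximal correlation or all short
channels as alternatives, and `"none"` for comparisons). The solve is
QR-based; a shared base design plus Frisch-Waugh partialling for the
channel-specific short-channel column makes per-channel fits exact and fast.

**Drift model.** The drift block is a constant, a linear term, and a
low-frequency discrete-cosine set up to 0.015 Hz. The cosine set is the one
place this package deviates from a minimal constant+linear drift, for a
measured reason: the data entering the GLM have been high-pass filtered at
0.01 Hz but the task regressors have not, and with block designs whose
fundamental falls in the filter's transition band that mismatch biases
recovered HRF amplitudes 15-30% downward. Filtering the design instead is
ill-posed (smoothed 0.5 s Gaussians become collinear). Including cosines
through the transition band - the standard way of putting the high-pass
inside the GLM - restores identification from the harmonics the filter
passes cleanly; measured peak recovery on synthetic data is then within ~3%.

One fit covers all repetitions of a session (multi-onset design), keeping
each fit well-conditioned; day-level HRFs are averages over fits
(`average_hrf()`). A caution that falls out of the basis algebra: onset
spacing must exceed the 62 s basis span, otherwise shifted basis copies from
consecutive onsets coincide and the design is nearly singular. The 2-min
rest blocks of the real protocol satisfy this comfortably; shortened test
designs must too.

# Channel-level statistics

The unit of analysis is the *windowed effect*: the mean of a subject's
day-averaged HRF over 0-20 s post-onset minus its mean over the -2-0 s
baseline, for HbO (HbR is computed and carried through but has lower
amplitude and statistical power). Tests are textbook t statistics, computed
explicitly and cross-checked against `stats::t.test` to 1e-10:

- day vs baseline: one-sample t of subjects' effects against zero;
- day 15 vs day 1: paired t on per-subject differences (positive = day 15
  higher);
- good vs weak learners: subjects split at the cohort mean of final-day
  performance scores (ties go above), then Welch's t per channel.

Inference is per-channel at alpha = 0.05, uncorrected, matching the original
analysis; Benjamini-Hochberg adjustment is available behind a flag.
Zero-variance degeneracies are flagged rather than returned as NaN.

# Behavioral arm

The official FLS score normalization is unpublished; the package implements
the documented form `score = max(0, cutoff - time - penalty)` with cutoff
600 s and configurable penalty weights. The learning curve is assessed with
LC-CUSUM: a repetition is a success when its score reaches the criterion
score; successes add `log10((1-p1)/(1-p0))` = -0.0792 and failures
`log10(p1/p0)` = +0.398 (p0 = 0.10 acceptable, p1 = 0.25 unacceptable
failure rates; base-10 logs are forced by those published weights), and a
trainee is declared proficient when the cumulative score reaches -3.7. The
trace is unbounded - no reflecting barrier at zero - which is what lets weak
performers drift positive and near-proficient ones hover between 0 and -0.5,
as the published traces describe.

**Criterion score.** The source analysis cites prior work without printing
its criterion. The arithmetic of the printed weights is unforgiving: reaching
-3.7 within 75 repetitions requires `0.398 f - 0.0792 (75 - f) <= -3.7`,
i.e. at most 4 failures *in total*. A criterion met only at the end of
training therefore makes crossings unobservable for everyone. The default
(200 score units, i.e. time + penalty under 400) makes repetitions past the
steep part of the learning curve clear successes while first-day repetitions
fail, which reproduces the published pattern: a handful of crossings per
21-trainee cohort, some trainees finishing below -3, others between -0.5
and 0. It is a configuration value, not a claim about the original study.

# The synthetic world

`simulate_hemodynamics()` writes down the generative model the preprocessing
assumes: per long channel, HbO = amplitude x (canonical HRF convolved with
the block drive) + gain x superficial + physiological oscillations + linear
drift + white noise; short channels carry everything except the task term;
HbR is -1/3 of the HbO task amplitude plus independent nuisance draws
(scaled by 0.5) that are nonetheless shared between long and short channels,
so short-separation regression is meaningful for both chromophores.

Choices worth knowing:

- The ground-truth HRF is a double-gamma (peak 6 s, undershoot 16 s, ratio
  1/6) while estimation uses Gaussian bases - a deliberate model mismatch so
  recovery does not depend on estimating with the generating basis. The
  convolution kernel is normalized to unit sum, so a sustained block
  plateaus at exactly the channel's amplitude (uM); `task_response_truth()`
  exposes the resulting noiseless response as the oracle for tests.
- Superficial hemodynamics: a smooth random process (random-phase sinusoid
  bank, ~0.004-0.09 Hz, 1/sqrt(f) amplitudes) with SD 0.4 uM - scalp
  signals dominate raw long-channel recordings, which is exactly why
  short-separation regression exists. Physiology: cardiac 1.1 Hz (0.15 uM;
  below the 2.5 Hz Nyquist at 5 Hz sampling), respiration 0.25 Hz (0.08),
  Mayer waves 0.10 Hz (0.10) - the Mayer component sits at the filter edge
  on purpose. White noise SD 0.05 uM; drift 2e-4 uM/s.
- Motion: Gaussian spikes of 0.5 s width (~5 uM, ~0.2/min) and step shifts
  (~3 uM, ~0.05/min), shared event times with channel-specific scaling.
- Long practice blocks raise the question of whether cortical drive is
  sustained for 10 minutes; the generator exposes `adaptation_tau` (default
  `Inf`, fully sustained) rather than fixing one behavior.
- Behavioral learning curves are exponential approaches to subject-specific
  asymptotes, with population parameters calibrated once so a default
  21-trainee cohort (12 good / 9 weak learners) reproduces the published
  day-1 (~483 s, score ~49 after the zero floor) and day-15 (~114 s, score
  ~440) summaries; good learners differ from weak ones in asymptote and
  learning rate. The published across-repetition mean penalty (72.5) is not
  simultaneously reachable with those endpoints under a monotone penalty
  curve and is knowingly not targeted.

`simulate_study()` assembles whole cohorts: per-subject amplitudes follow
channel roles (prefrontal channels active throughout; "sensorimotor"
channels elevated by day 15, +0.4 uM by default with an extra +0.15 uM for
good learners; the rest null), interpolated linearly across sessions, with
between-subject amplitude and day-difference jitter. Recordings are written
as intensity so analyses exercise the full chain.

What a green test does *not* establish: the generator's superficial process
has no heartbeat harmonics or serial dependence beyond its sinusoid bank,
motion artifacts are additive and stereotyped, optode coupling is perfect,
and channel geometry is a line rather than a cap. Passing recovery tests
here validates the estimators under the stated model, not fNIRS hardware.

# Numerical choices and degenerate inputs

- Butterworth design by bilinear transform of the analog prototype; padding
  for the zero-phase pass uses odd reflection over three periods of the
  low edge. No R signal-processing package ships in this environment, so
  these primitives live in the package and are oracle-tested.
- OLS rank failures abort with the design's condition number; short-channel
  regressors collinear with the design are rejected rather than silently
  dropped.
- Zero-variance effect vectors yield flagged exact-degenerate p-values
  (p = 1 at zero mean, p = 0 otherwise), never NaN.
- Non-uniform timestamps (jitter above 1% of the sample interval) are an
  error; silent resampling would hide acquisition faults.
- All-equal final-day scores make the good/weak split meaningless and are an
  error; a split that leaves a group with fewer than two subjects skips the
  group contrast with a message.
- SNIRF, the community HDF5 dialect, is declared in the I/O interface but
  unavailable here (no R HDF5 bindings in the environment); the CSV bundle
  (`data.csv` + `layout.json` + `meta.json` + `stim.json`) is the on-disk
  format and is lossless for data, layout and stimulus timing.

# Desk-scale testing

The Monte-Carlo validation suites (type-I calibration through the full
simulate-preprocess-fit-test chain; paired-contrast power over replicate
studies) run with the protocol's subject counts, repetition structure,
sampling rate and analysis defaults, but with shortened practice/rest blocks
(25/45 s) and reduced montages so 500 null studies and 50 effect studies fit
in minutes on one CPU. Block duration enters the analysis only through the
design matrix, and the 70 s onset spacing respects the basis-span constraint
above, so the scaled runs exercise the same estimator regime as the
paper-scale protocol.

# Limitations

The anatomical labeling of channels (which gyrus a channel overlies) is out
of scope; channels are identified by their (source, detector) pair. The GLM
assumes white residuals within a fit - no prewhitening - so single-fit
t-statistics are not trusted anywhere; all inference is across subjects.
The FLS score and the LC-CUSUM criterion are parameterized stand-ins for
values their originators did not publish.
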