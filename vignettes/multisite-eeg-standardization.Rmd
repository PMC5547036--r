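---
title: "Standardizing multi-site ERP studies: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing multi-site ERP studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mseeg)
```

# The problem

Event-related potential (ERP) studies that pool EEG across acquisition
sites inherit heterogeneity at every level: different amplifiers and
sampling rates, different electrode caps and reference schemes, different
stimulus-presentation hardware with different (and jittered) delays
between the software event marker and the moment the participant actually
sees or hears the stimulus, different operators making different cleaning
decisions, and different statistical conventions. Each of these injects
between-site variance that can swamp the neural effects of interest or,
worse, masquerade as them. `mseeg` implements the arithmetic of
standardization: converting every site recording to a canonical form,
cleaning it through a fixed, fully logged pipeline, testing effects with
multiple-comparison-aware statistics, auditing machine-learning accuracy
claims for subject leakage, and checking files against the study protocol
before they are shared.

Everything is exercisable without any real data: the `synthConfig()` /
`genRecording()` / `applySite()` generator produces multi-site ERP
recordings with known ground truth, and the whole test suite is built on
it.

# The synthetic study conditions

A generated recording is the sum of

* pink background noise — white Gaussian noise spectrally shaped to a
  1/f power profile, scaled to a target standard deviation (default 5 uV,
  a typical resting EEG amplitude scale);
* band-limited oscillations — by default one 10 Hz (alpha) component of
  3 uV with unit channel weights;
* an ERP component — a Gaussian-envelope deflection (default 8 uV peak,
  300 ms latency, 100 ms width, centro-parietal topography) added
  time-locked to every stimulus event; events sit on an exact-sample grid
  (default 30 events, 1.5 s apart);
* artifacts, each optional: blinks (0.3 s positive half-sine deflections
  weighted to frontal electrodes), EMG bursts (20-100 Hz band-limited
  noise, 0.5 s, tapered, on a random channel), mains noise (a pure
  sinusoid on all channels) and a flat (disconnected) channel.

`applySite()` renders the same ground truth as a specific site would have
acquired it: montage subset, site reference, site rate, and — the key
timing model — each event marker is displaced from the true onset by
`Normal(delayMean, delaySd)` plus `trial * driftPerTrial` milliseconds,
rounded to the nearest sample. The default regimes used throughout the
checks (24.6 +/- 0.59 ms and 49.3 +/- 2.93 ms, with drift up to ~2 ms
across a run) are the scale of delays measured for auditory stimulation
on older and newer Windows presentation systems respectively; visual
setups show comparable offsets that additionally depend on monitor model
and stimulus position.

What the generator deliberately does **not** emulate: biophysical source
mixing (no head model — topographies are chosen weights, not dipole
projections), non-stationary background rhythms, heart-rate variability
in ECG, slow electrode drift and impedance changes, or inter-subject
anatomical variability. Passing tests therefore demonstrate that the
*algorithms* are correct under controlled conditions, not that artifact
classification, say, reaches any particular sensitivity on clinical
recordings.

# Harmonization

`harmonizeRecording()` applies, in a fixed order: marker-delay
correction, electrode matching, band-pass filtering, resampling,
re-referencing. The order matters: delays are corrected on the native
clock where one marked sample is one acquired sample; matching precedes
filtering so filters run only on retained channels; filtering precedes
resampling so the anti-alias step is explicit; the reference is applied
last so it holds exactly on the output.

**Delay sign.** We estimate delay as mean(marked - true) in ms
(`estimateDelay()`), so a *positive* delay means the marker is late.
Correction (`correctEventDelays()`) therefore *subtracts* the mean delay
by default. Hardware timing reports sometimes state the same measurement
with the opposite subtraction (true minus marked); the `delaySign` flag
covers that convention. The default is verified by a ground-truth
alignment oracle: correcting synthetic site markers and re-estimating
against true onsets leaves a residual below one sample. Only the mean is
corrected: per-trial jitter and drift are not recoverable from markers
alone (drift is exposed in the simulator precisely so its effect on
downstream latency estimates can be studied).

**Electrode matching.** "Closest equivalent electrode" is made concrete
as nearest neighbor in 3D Euclidean distance on the unit-radius head
frame, with a default acceptance radius of 0.2 (about 11 degrees of
scalp); ties break toward the alphabetically smaller source label so the
map is deterministic. A property test checks equivalence with exhaustive
search on 1,000 random montages. Digitized per-session positions can be
supplied as montage TSVs, but no co-registration of head shapes is
attempted.

**Filters and resampling.** The band-pass is a zero-phase (forward-
backward) 4th-order Butterworth; before downsampling an anti-alias
low-pass at 0.4 x target rate is applied, then the signal is resampled in
the Fourier domain, which keeps output sample k exactly at time k/rate —
resampling two sites by different ratios cannot introduce a relative
shift. Event onsets remap by `round(onset * p/q)` with round-half-to-even
(unbiased under repeated resampling). Harmonizing an already harmonized
recording detects the recorded pass band in the provenance metadata and
skips the second filtering pass, making harmonization idempotent instead
of compounding pass-band attenuation.

# The cleaning pipeline

`runPipeline()` runs the seven steps in fixed order — epoch, gross
artifact rejection, filter, ICA fit, component removal, final review,
interpolation + re-reference — with large-amplitude artifacts removed
*before* the ICA fit so the decomposition is not spent on them. Two
principles shape the implementation:

1. **Declarative removals.** What an operator would click interactively
   is expressed as rejection lists in the configuration, or produced by
   `detectGrossArtifacts()` in `--auto` mode (defaults: 150 uV
   peak-to-peak per cell; whole channel/trial at 50% flagged cells;
   channels at 5 x median robust variance or zero variance). The robust
   (MAD-based) channel variance is deliberate: a single spiking trial
   should flag that cell, not sacrifice the channel.
2. **Replayable provenance.** Every removal carries its step tag in the
   `CleaningLog`; trials are addressed by their original indices, and
   cell removals are masks rather than deletions. `survivingMask(log)`
   reconstructs the surviving-data mask from the log alone, and the
   pipeline guarantees it equals the actual state. Each step's full
   state, parameters and checksum are archived under
   `<id>_<task>_<visit>_step<NN>_<stepname>.rds`; `replayStep()` re-runs
   any step from its archived predecessor and must reproduce the
   archived successor within 1e-6 uV.

**ICA.** The decomposition is symmetric FastICA with a tanh contrast on
PCA-whitened data, seeded explicitly (the seed is part of the log). The
applied transform is strictly linear on the uncentered data, so removing
no components is exactly the identity and removing all components of a
complete decomposition exactly annihilates the signal — properties the
provenance tests rely on. Component labels come from transparent
heuristics (frontal low-frequency topography for blinks; frontal
antisymmetry for lateral eye movements; high-band versus low-band power
*density* for EMG, so a flat spectrum scores zero; single-channel
topography concentration for electrode discontinuity; 0.8-1.5 Hz
autocorrelation for cardiac components), each mapped to [0, 1] with an
argmax-above-0.5 rule and `"other"` as the fallback. The label set is
the five artifact classes plus `"other"`.

**Interpolation.** Removed channels are reinstated with order-4 spherical
splines (50 Legendre terms, 1e-5 ridge on the kernel) computed once as a
linear predictor from surviving channels. Interpolation runs before the
final re-reference, so the average reference includes the interpolated
channels; reinstated channels are marked as reconstructions in the
provenance mask, not as surviving data.

# Cluster statistics and the threshold-averaged extension

Voxel-wise t maps over time x frequency (x sensor) grids are thresholded
at a cluster-forming p, connected components are formed under a declared
adjacency (orthogonal or diagonal grid neighborhoods; sensor dimensions
use distance-threshold neighborhoods from electrode positions, reflecting
volume-conduction smoothness), and cluster size / maximum / mass are
tested against the permutation distribution of the maximum measure —
label reshuffling for unpaired designs, sign flipping for paired ones.
Positive and negative excursions cluster separately; the family-wise null
takes the maximum of |measure| over both signs. p-values use the add-one
estimator with a relative tie tolerance of 1e-8 so that null replicates
numerically equal to the observed measure (the identity permutation, in
exhaustive mode) are always counted. When the number of distinct
permutations is within the requested budget the null is enumerated
exhaustively, making small-sample p-values exact rational numbers.

The threshold-free extension (`uceTest()`) removes the analyst's
threshold choice: cluster-value maps (each voxel carries the measure of
its containing cluster, zero when inactive) are computed on a grid of
thresholds — default {0.05, 0.02, 0.01, 0.005, 0.002, 0.001, 0.0005,
0.0001}, spanning the conventional range — and averaged **per voxel**.
Inference is max-statistic permutation on the averaged map. Two details
are this implementation's documented conventions rather than settled
literature: the per-voxel (not per-cluster-object) averaging across
thresholds, and the choice of max-statistic inference on the averaged
map. A one-element grid reduces exactly to single-threshold cluster-value
maps, which anchors the construction.

# Cross-validation auditing

`makeFolds()` builds record-wise folds (records shuffled into folds
regardless of subject) and subject-wise folds (whole subjects), and
`compareSchemes()` reports the accuracy inflation between them. On
feature tables where the only structure is a per-subject offset
(no class effect), record-wise leave-one-out reaches high accuracy purely
by memorizing subjects while subject-wise stays at chance — the leakage
the fold scheme is supposed to prevent.

The reference classifiers are nearest-centroid (closed form, so fold
predictions are hand-checkable) and a ridge classifier (least-squares on
+/-1 targets, sign decision). Two de-biasing details in the ridge
reference matter for honest subject-wise baselines: the intercept is set
midway between the class score means rather than at the target mean, and,
when subject identities are available, the larger class is subsampled to
an equal number of subjects before fitting. Without the latter,
leave-one-subject-out on balanced data is systematically *below* chance —
the held-out subject's own class always has one fewer training subject,
so its class mean is the noisier one — a bias that would silently
exaggerate the reported inflation. Degenerate folds (single-class
training sets) are skipped, warned about, and counted rather than
included in the mean.

# Quality control

`runQc()` runs a fixed battery per file — readability with checksum
invariance (QC never mutates its input), sampling rate, required
channels, required event codes, impedance metadata below the protocol
threshold (5 kOhm by default; pass-with-warning when the file carries no
impedance metadata, since impedance is an acquisition-time measurement
that EEG files rarely store), flat/noisy/line-dominated channel scan
(line frequency 60 Hz by default, configurable for 50 Hz sites),
regex-based de-identification scan of header fields, and file-name
convention (`<study>_<site>_<subject>_<visit>_<task>`). The report always
has one entry per check, so a fleet of reports is directly tabulable, and
the property the tests enforce is one-to-one: a file violating exactly
one rule fails exactly that check.

# Numerical conventions and check sizes

* Coordinates and event onsets are 0-based; epoch windows are half-open
  `[start, end)`.
* Reference operations are exactly rank-one updates, so between-channel
  differences are invariant to 1e-9 and average referencing is idempotent
  to machine precision.
* EDF round trips quantize to 16-bit integers over the per-channel
  physical range (the EDF standard), so signal equality after I/O is
  asserted to within one quantization step.
* Deterministic seeds are threaded through every stochastic operation
  (generator, site delays, ICA, permutations, folds); identical seeds
  give bit-identical results.
* The statistical calibration checks run at 12 observations per group on
  a 16 x 20 time-frequency grid with 500 permutations and 400 null
  replicates, where the 95% Monte-Carlo band around a true family-wise
  error rate of 0.05 is [0.030, 0.072]; oracle-equivalence checks use
  1,000 random 4 x 4 masks and exhaustive 2+2 permutation cases; the
  cleaning-efficacy and leakage checks use 10 generator seeds each.
  These sizes were chosen so the full suite completes in minutes while
  keeping the Monte-Carlo bands tight enough to detect calibration
  errors of a few percentage points.

# Known limitations

* EDF support covers continuous 16-bit EDF/EDF+ with one annotation
  channel — enough for the package's interchange needs, not a complete
  implementation of the standard (no discontinuous files, no per-signal
  rates, no sub-second record durations beyond the single-record
  fallback).
* Artifact classification heuristics are calibrated on the generator's
  artifact forms; on real data they are a starting point for review, and
  the pipeline accepts explicit override lists for exactly that reason.
* The threshold-averaged cluster test's inference convention (per-voxel
  averaging + max statistic) should be cross-compared against other
  threshold-free formulations before results are pooled across toolkits.
* Only the mean marker delay is corrected; per-trial jitter widens ERP
  averages slightly and is left as measured variance.
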