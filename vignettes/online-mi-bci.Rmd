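---
title: "Detecting pedaling motor imagery in real time: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pedaling motor imagery in real time: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pedalbci` implements an online brain-computer interface (BCI) that
discriminates two cognitive states from multichannel EEG — relaxation versus
imagined pedaling — together with the event-related desynchronization (ERD)
analysis that explains *why* it works, and a synthetic EEG generator that
makes every stage testable without human recordings. This vignette is the
package's own account of the underlying science and of the design choices
that were genuinely open.

## The phenomenon

When a person imagines a complex lower-limb movement, the sensorimotor mu
rhythm (8–12 Hz) and, to a lesser degree, beta rhythms (13–30 Hz) recorded
over the leg representation of the primary motor cortex lose power relative
to quiet rest. This task-locked power loss is event-related
desynchronization. The leg area sits deep in the longitudinal fissure under
the vertex, so the effect is strongest at Cz and its immediate neighbors
(C1, C2, C3, C4, FC1, FC2, CP1, CP2). For an electrode $E$ and frequency
$f$, the package quantifies it as

$$\mathrm{ERD}_E(f) = \frac{P(f) - R(f)}{R(f)} \times 100,$$

where $P(f)$ is the mean power over imagery epochs and $R(f)$ over relax
epochs. Negative values are desynchronization; the statistic is scale-free
and bounded below by $-100$. `erd()` / `erd_matrix()` compute it from *raw*
(absolute) spectra: per-epoch normalization would change the imagery/relax
power ratio and bias the statistic, so the relative-power normalization used
for classification features (below) is deliberately *not* applied here. The
mu-band motor-cortex summary `mu_motor_erd()` averages the 25 cells at
$f \in \{8,\dots,12\}$ Hz and $E \in \{Cz, C1, C2, C3, C4\}$.

## The experimental protocol

A session is a cue-driven sequence: 10 trials, each presenting 10 *Relax*
and 10 *Imagine* cues of 5.8 s in random order, never more than two of the
same task consecutively (so the subject cannot anticipate), separated by 3 s
fixation crosses. `build_trial_schedule()` draws the order by rejection
sampling of balanced permutations — every admissible order is equally
likely. We assume the cross also precedes the first cue of a trial (the
protocol does not say; it is how cueing software usually behaves, and it
only shifts onsets by 3 s).

Analysis uses 1 s epochs advanced by 200 ms; the first 2 s of every cue are
discarded (visual-cue transient). At 500 Hz these are exact sample counts
(500-sample windows, 100-sample shift), so epoch boundaries are computed by
rounding $t \cdot f_s$ with a $10^{-9}$ s end tolerance — the count per cue
is $\lfloor (5.8 - 2.0 - 1.0)/0.2 \rfloor + 1 = 15$, and the tolerance
protects the last window at 4.8 s from floating-point misses. The first 4
trials train the classifier; trials 5–10 are scored online. The
tDCS-related dose arithmetic exposed by `current_density()` is the usual
$I/(\pi r^2)$ for a circular gel electrode.

## The synthetic generator

`generate_session()` emulates a cue-locked acquisition on the 30-channel
10-10 montage at 500 Hz:

* **Rhythm source.** A sinusoid at the subject's mu center frequency
  (default 10 Hz) with random phase, amplitude-modulated by slow (< 1 Hz)
  jitter so the spectral line spreads over roughly ±1 Hz. A filtered-noise
  rhythm would look more organic, but a deterministic-amplitude source gives
  *exact* control of band power, which is what makes ERD ground truth
  possible. The modulation depth is 0.1: deep jitter would re-randomize the
  realized band power per session and defeat that control (at depth 0.2 the
  per-session spread of recovered ERD was about ±3 points; at 0.1 it is
  about ±1.5 on an 18-cue-per-task session, shrinking with session length).
  An optional beta source works identically.
* **Suppression.** During Imagine cues the source amplitude is multiplied by
  $\sqrt{1 - \rho \cdot d}$, where $\rho$ is the subject's
  `erd_power_fraction` and $d$ the day's multiplier, so band *power* drops
  by exactly $\rho d$ and the ERD ground truth is $-100\,\rho d$. Envelope
  transitions use 100 ms raised-cosine ramps to avoid clicks that would leak
  broadband power into both states.
* **Spatial projection.** The source projects to electrodes with a Gaussian
  weight over the 2D-projected montage, centered at Cz with scale roughly
  one electrode spacing — so the nine central electrodes carry most rhythm,
  matching why exactly those nine are selected for classification.
  Coordinates are an idealized 10-10 layout (grid angles of 18–20° per 10%
  arc step, azimuthal equidistant projection); only relative distances are
  ever used.
* **Noise.** Per-channel independent 1/f background plus a common-mode 1/f
  component (the latter exercises the Laplacian's common-mode rejection),
  and an optional common 50 Hz line sinusoid.
* **Cohorts.** `generate_cohort()` draws per-subject parameters from
  realistic ranges (mu center 8–12 Hz, amplitudes 6–14 µV, $\rho$ 0.2–0.45,
  noise 1.5–3 µV) and applies a per-day expression curve: the
  active-stimulation preset expresses full ERD from day 1; the sham preset
  ramps up over the first three days (0.1, 0.55, 0.9, 1, 1), emulating
  subjects who learn the task across days. The sham ramp is illustrative —
  the study's day-by-day learning magnitudes are not published as numbers —
  so cohort-level day effects are qualitative, not calibrated.

What the generator does *not* emulate: volume conduction through a real head
model (no leadfield), ocular/muscle artifacts, electrode drift or
impedance changes, non-stationary rhythm frequency. Tests passing on this
synthetic data therefore validate the pipeline's mechanics and its
parameter recovery, not its robustness to real-world artifacts.

## Preprocessing

Each epoch passes a 4th-order Butterworth high-pass at 0.05 Hz (DC
removal), a 50 Hz IIR notch, and a 4th-order Butterworth low-pass at 45 Hz.
Numerical choices here matter more than they look:

* **Second-order sections.** At a 0.05 Hz cutoff and 500 Hz sampling, the
  single transfer-function form of a Butterworth filter is numerically
  broken — coefficient cancellation leaves the "high-pass" with a spurious
  DC gain of ~0.4%. Filters are therefore designed as cascaded biquads via
  the bilinear transform, with zeros exactly at $z = \pm 1$; the design is
  cross-checked against an independent implementation at well-conditioned
  cutoffs in the test suite.
* **Zero-phase application.** Filtering is forward–backward per epoch with
  even-reflection padding and steady-state initial conditions scaled by the
  padded signal's mean. A causal 0.05 Hz high-pass is ill-posed on a 1 s
  window (its time constant is ~3 s); the zero-phase variant with mean-based
  initialization maps a constant epoch to zero exactly, i.e. its practical
  effect is epoch-mean removal, while passing 10 Hz within 0.01%. The more
  common odd-reflection/first-sample scheme injects a slow offset transient
  here (~8% amplitude error on a mu-band tone) precisely because of that 3 s
  time constant.
* **Notch width.** The notch's quality factor defaults to 10. A very narrow
  notch (Q = 30) has a ring-down of ~0.2 s that cannot settle within a 1 s
  window, smearing transient energy across the epoch (residual ~0.12 RMS on
  a unit 50 Hz tone, under the 20 dB target); Q = 10 contains the transient
  (worst-case residual 0.095 RMS, ≥ 27 dB at the 50 Hz component) while
  attenuating the 6–30 Hz feature grid by less than 0.5%.
* **Streaming mode.** `apply_filter_chain_causal()` runs the same chain
  causally over the continuous recording with filter state carried forward,
  for use as a true online system would; the per-epoch zero-phase chain is
  the default because it is what the offline-reproducible analysis needs.

The surface Laplacian then replaces each channel by itself minus the
1/distance-weighted average of all 29 other channels (weights normalized to
sum to one per target), over the full montage, *before* the nine central
electrodes are selected. A spatially constant frame maps to exactly zero.
The montage-wide 1/distance variant is an assumption — the neighbor set of
the original reference implementation is not described — but any
common-mode-rejecting variant behaves equivalently on the generator's
source model.

## Spectral features and the classifier

For every epoch and electrode, the power at each integer frequency from 6
to 30 Hz is the AR spectral density fitted by Burg's recursion
(`stats::ar.burg`, order 16 by default — roughly $f_s/30$, enough poles to
resolve separate mu and beta peaks on 500-sample windows) and evaluated at
the integer frequency (1 Hz "resolution" read as point evaluation, not band
integration). Burg's method is used because it yields smooth, stable
spectra from 1 s windows where the periodogram is noisy; the periodogram
remains in the package as the independent test oracle
(`periodogram_psd()`). One caveat carries over to the ERD analysis: the
height of an AR spectral peak responds *superlinearly* to the
rhythm-to-noise ratio, so under heavy background noise Burg-based ERD
values overstate the true power suppression (e.g. about −50% measured for
a −35% injected suppression under a 2 µV background), while at low
background they agree with the periodogram to within a point or two. ERD
magnitudes from this estimator should be compared between conditions, not
read as exact power fractions, unless background is low.

Each (epoch, electrode) spectrum is then normalized to relative power
(sum 1 over the 25-bin grid). Normalization is per-epoch — the natural
scale-free reading; whether the original analysis normalized per epoch or
across the training set is not stated, and this choice is recorded as an
assumption. From the training trials, `select_optimal_frequencies()` picks,
per electrode, the frequency with the largest absolute difference between
the task-mean normalized powers (ties break toward the lowest frequency,
for determinism). The per-epoch feature vector is the normalized power of
each of the nine electrodes at its optimal frequency.

An RBF-kernel SVM (`e1071::svm`, i.e. libsvm) separates the two states.
Features are standardized with training-set statistics (an addition: RBF
kernels on raw relative powers in [0, 1] with tiny variance are badly
conditioned); `C = 1` and the median-heuristic kernel width are the
defaults, both exposed. Evaluation is exactly the protocol's: train on
trials 1–4, classify every 200 ms epoch of trials 5–10, no temporal
smoothing, accuracy = 100 · correct / total. The feedback bar of the
original experiment is modeled as a per-cue counter of correct detections.

One property of this feature design is worth stating plainly: relative
power is invariant to rescaling the whole signal, so on *noise-free*
synthetic data — where mu suppression is a pure rescaling of the single
source — the two states are indistinguishable by construction and accuracy
sits at chance. The classifier's information is the rhythm-to-background
contrast; detection requires background, and accuracy grows with the
suppressed fraction $\rho$ as soon as realistic background noise is present
(about 50 / 60 / 77 / 94% at $\rho$ = 0 / 0.15 / 0.3 / 0.5 under the
default 2 µV background in the acceptance runs).

## Problem sizes and reproducibility

The test suite and the acceptance script regenerate everything from seeds.
Unit tests use reduced sessions (2–5 cues per task per trial) because the
properties they check do not depend on session length; the acceptance runs
use the full protocol where the quantity itself is protocol-sized (the 1800
evaluation epochs, the 63 optimal frequencies of a 7-subject group-day, the
full-session ERD matrix) and a 5-cue, 7-trial session for the
accuracy-vs-$\rho$ sweep, chosen so the sweep's ~450-epoch accuracy
estimates have ~2-point standard error — comparable to the tolerance at
which monotonicity is asserted. All randomness flows from explicit seeds;
sessions are bit-reproducible.

## Known limitations

* The group-level day-by-day dynamics (sham learning curve) are
  qualitative; only the within-session quantities (ERD, optimal
  frequencies, accuracy) are parameter-recovery tested.
* The Laplacian variant and the normalization scope are assumptions, as
  noted above.
* EDF+ I/O is not provided; recordings interchange through the package's
  delimited container (gzipped TSV sample matrix + JSON sidecar with
  labels, rate and cue annotations), which `read_session()` restores
  losslessly for the pipeline.
* The statistical machinery of the original study (mixed factorial ANOVA,
  sphericity corrections, Bonferroni pairwise tables) is intentionally out
  of scope: `accuracy_summary()` emits tidy per-subject/per-group tables
  that any stats package can consume.
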