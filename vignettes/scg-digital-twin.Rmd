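---
title: "A digital twin of a triboelectric seismocardiography chain: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital twin of a triboelectric seismocardiography chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgtwin)
```

## What the package models

Seismocardiography (SCG) records the millimetre-scale chest-wall vibrations
produced by the heart's mechanical activity. A wearable acquisition chain for
SCG consists of a force transducer pressed against the sternum, an analog
conditioning circuit, and an ADC; downstream software localizes heartbeats,
averages them into templates, reads off fiducial events (MC, IM, AO, IC, AC,
MO), screens signal quality, and feeds window-level features to classifiers
of systolic and diastolic blood-pressure range.

`scgtwin` implements that whole chain in software. Because no public
recordings exist for this class of device, the package is anchored by a
synthetic generator whose outputs carry exact ground truth; every processing
stage is validated against that ground truth, and the sensor and circuit
models are validated against their engineering calibration numbers
(sensitivities, step-response times, filter corner frequencies, ADC
resolution).

## The synthetic SCG generator

**Beat morphology.** No closed-form equation for an SCG complex exists, so a
beat is modelled as a superposition of six Gabor wavelets (Gaussian-windowed
sinusoids), one per fiducial event: event $e$ contributes
$A_e \exp\{-(t-L_e)^2/2w_e^2\}\cos 2\pi f_e (t-L_e)$. This choice has three
properties that matter here: the signal is band-limited inside the 1–25 Hz
SCG band; the envelope of each component peaks exactly at the event latency
$L_e$ with height $|A_e|$, so annotations are exact by construction; and
event amplitudes/latencies can be scaled independently to plant effects.
Defaults place MC–MO over 0.04–0.40 s with AO the dominant positive
deflection (amplitude 0.12 N) — the morphology SCG atlases describe. A
consequence of the oscillatory carrier is that every deflection is flanked
by sidelobes roughly 15–20 % of its own height; the fiducial detector must
(and does) account for this.

**Rhythm and modulation.** Beats are placed at intervals
$RR = 60/\mathrm{HR} + \varepsilon$, with $\varepsilon$ Gaussian (SD
`rr_jitter_sd`, default 0.02 s) truncated at $\pm 3$ SD and RR floored at
0.3 s. Respiration multiplies beat amplitude by
$1 + d\,\sin 2\pi f_r t$ (default $f_r = 0.25$ Hz, depth $d = 0.2$; 0 for
breath-holding). Default heart rates follow the two observed cycle lengths:
60 bpm for breath-holding (≈1 s cycle) and 75 bpm otherwise (≈0.8 s cycle).

**Activity artifacts.** Office work adds noise synthesised directly in the
frequency domain with support restricted to 0.5–2 Hz (so band containment
is exact, not approximate); walking adds a mean-removed train of Gaussian
force bumps (width 80 ms) at the step rate, default 2 Hz. Both are recorded
in the annotations.

**Planted blood-pressure mapping.** Real labels come from a cuff device and
their relation to SCG morphology is latent. The generator therefore plants a
documented, learnable relation: the AO amplitude scales by
$1 + 0.35\,(c_{SBP}-1)$ and mean heart rate shifts by $8\,(c_{DBP}-1)$ bpm,
each with Gaussian noise (SD 0.05 fractional, 1 bpm). SBP/DBP values are
drawn from truncated normals inside the three class bins
(SBP: <120, 120–135, >135 mmHg; DBP: <80, 80–85, >85 mmHg; edges belong to
the middle class). Classification results on this dataset measure pipeline
fidelity to a known effect; they are *not* estimates of real-world accuracy.

**What the generator does not emulate:** inter-subject morphology
differences, posture-dependent coupling, heart-rate variability beyond white
RR jitter, ectopic beats, sensor detachment, or any physiological SBP/DBP
dependence on SCG timing intervals (PEP/LVET). Tests passing on synthetic
data show the chain recovers what it is designed to recover — not that the
planted mapping resembles human physiology.

## The sensor forward model

The transducer model is phenomenological, calibrated to measured numbers
rather than derived from electrostatics:

* **Static response** — piecewise: slope 3.76 V/N on 0–0.2 N, slope
  0.10 V/N above 0.6 N, and a quadratic segment between (the slope blends
  linearly across the knee), modelling gradual saturation of contact area
  and transferred charge. Continuous, monotone, zero at zero force.
* **Dynamics** — an asymmetric first-order lag whose time constant switches
  between $\tau_r = 0.02/\ln 9$ s (rising) and $\tau_f = 0.06/\ln 9$ s
  (falling), so a simulated step reproduces the measured 10–90 % rise time
  of 0.02 s and 90–10 % recovery of 0.06 s exactly (for a first-order
  system that span is $\tau\ln 9$).

These two published facts about the physical sensor — flat response over
0.5–25 Hz *and* 20/60 ms step times — cannot both hold for any first-order
LTI system (a 9.1 ms time constant corresponds to a 17.5 Hz pole). The real
device's step times were measured under large excursions where its response
is nonlinear. We keep the step times, which are the quantities this model is
asked to reproduce, and treat the flat band as a property of the physical
sensor that the surrogate only approximates; the *analog chain* is verified
to be flat within 1 dB at 10 Hz, and in-band calibration recovery is
verified through the static path.

In `acquire()` a static strap preload (default 0.1 N) is added so vibration
troughs stay on the sensitive 0–0.2 N segment instead of losing contact; a
2 s settling period is simulated and discarded so the high-pass stage has
absorbed the preload's DC step before the recording begins.

## The analog chain and ADC

Causal discrete-time cascade in circuit order: optional additive 50 Hz
mains interference → single-pole low-pass at $1/2\pi R_f C_f \approx 796$ Hz
(the 10 MΩ/20 pF transimpedance stage; the sensor is treated as a voltage
source followed by this pole, avoiding an unknowable charge-source model) →
third-order Butterworth low-pass at 33.9 Hz → gain ($G = 2.4$ by default,
chosen so a 0.2 N beat peak lands near 60 % of full scale; the physical
amplifier's gain is unpublished) → RBJ biquad notch at 50 Hz ($Q = 10$ by
default — unpublished; narrow enough to spare the 1–20 Hz band) →
first-order high-pass at 0.8 Hz → mid-scale offset. Filters are causal
because the real front end is causal; only the *offline* beat pipeline uses
zero-phase filtering.

The ADC quantizes to $2^{12}$ levels after clipping. Full scale defaults to
3.0 V because $3.0/4096 = 0.732$ mV matches the converter's stated
resolution exactly (the 3.3 V logic rail is the documented alternative,
which would give 0.806 mV). Rounding to the nearest code bounds the
reconstruction error by LSB/2 on the unclipped range.

Filter stages are verified by actual sine sweeps (steady-state amplitude
fitted on a sine/cosine basis after discarding the transient half of each
probe), not by reading back design coefficients, so the measured 33.9 Hz
cutoff, 50 Hz notch minimum and ≈0.8 Hz corner test the implementation
end to end.

## Beat localization, templates, fiducials

The offline pipeline mirrors the three-step localization scheme:

1. **Narrow-band enhancement**: zero-phase Butterworth band-pass, default
   5–25 Hz — inside the SCG energy band but above respiration and postural
   drift. Order 2 per pass.
2. **Sliding RMS envelope**: centred, reflection-padded, default window
   100 ms — long enough to merge intra-beat oscillations into one bump per
   beat, short enough to separate beats at 100 bpm.
3. **Peak detection**: local maxima above an adaptive threshold (0.3 × the
   median candidate height) with a hard refractory interval, default
   `min_rr` 0.4 s (150 bpm ceiling). Candidates are accepted
   largest-first, so of two near peaks the larger survives.

Segments (default −0.1 to +0.5 s around the envelope peak) are aligned to a
provisional mean by cross-correlation within ±50 samples (one refinement
pass, edge replication when shifting) and averaged; per-sample SDs are kept.
Template MSE against the generating motif shrinks like $1/\sqrt n$, which
is tested.

Fiducial annotation is a rule set of this package (no published rule
exists): AO = largest positive systolic peak; IM = deepest trough before
AO; MC = last positive peak before IM; IC = first trough after AO; AC =
largest positive diastolic peak after IC; MO = first trough after AC.
Search windows default to 0–0.25 s (systole) and 0.25–0.5 s (diastole)
relative to the segment anchor. Candidates must exceed 15 % of the
template's maximum absolute deflection; this floor is what rejects the
carrier sidelobes noted above (~15–20 % of their parent deflection, i.e.
≲2 % of the template maximum for non-AO events) while keeping the smallest
genuine event (MO, 25 % of maximum). Unfindable events are flagged, never
zeroed, and the returned set is forced to respect the MC < IM < AO < IC <
AC < MO ordering. The rules are validated against generator truth (every
event within 20 ms); on real data they would be a convention requiring
ECG-referenced validation.

## Quality screening and features

Each cuff measurement at $t_0$ pairs with the preceding 45 s of signal.
Windows are z-scored (beat detection is scale-invariant, so whether
normalization precedes or follows detection — both orderings are supported
via `normalize_first` — changes nothing except the scale the detector
sees; features are always computed on the normalized scale so
wearing-pressure differences cancel).

The SQI is a reconstruction (the original formula is unpublished): the
unweighted geometric mean of (i) mean beat–template correlation, (ii)
$\exp\{-CV(RR)/c\}$ and (iii) $\exp\{-CV(\text{p2p})/c\}$ with $c = 0.5$,
zero when fewer than 3 beats are found. The retention threshold is kept at
0.7. The geometric mean makes the index veto-like (any collapsed sub-score
drags the SQI down), and $c = 0.5$ places a clean resting window
(CV ≈ 0.03–0.15) in the 0.85–0.97 range while pure noise falls well below
0.7.

Features per retained window (fixed dimension 11): heart rate; mean and SD
of per-beat RMS intensity, peak-to-peak amplitude and maximum upstroke
slope (first difference of the band-passed segment, per second); and the
template amplitude linearly interpolated at 0.1, 0.2, 0.3, 0.4 s after the
anchor. Per-beat quantities enter as mean + SD because the printed feature
list names per-beat quantities without saying how they enter a fixed-length
vector.

## The classifier

Softmax multinomial logistic regression, written out rather than wrapped,
because the training loop itself is part of the modelled pipeline:
L2-regularized multinomial cross-entropy (intercepts unpenalized),
full-batch gradient descent from zero initialization, internal
standardization with training-set moments only (no leakage). Defaults
$\lambda = 10^{-3}$, learning rate 0.1, ≤5000 iterations, tolerance
$10^{-8}$; the loss trace is non-increasing at the default rate and the
numerical gradient at the reported optimum vanishes (both tested). Fitted
probabilities agree with an independent optimizer (`nnet::multinom`) to
within $10^{-3}$ mean absolute difference on overlapping-class data — a
cross-check in the test suite, not a runtime dependency. Splits are
stratified 70/30 (the printed split is "random, 30 % test"; stratification
keeps all classes in both partitions at small n). Evaluation: 3×3 confusion
matrix, accuracy, per-class one-vs-rest ROC with trapezoid AUC.

## Numerical and scale choices

* Simulation rates: sessions are synthesized and digitized at 1000 Hz (the
  ADC rate); step-response and filter-sweep verifications run at 4 kHz so
  "within one sample" is a 0.25 ms statement.
* Standard test problem sizes: 30–60 s sessions for rhythm checks; 300
  sessions of 46 s (one 45 s window each) for the planted-mapping
  recovery check, which completes in about a minute; 45-session runs for
  the smaller classifier tests.
* Degenerate inputs error loudly (constant windows, <2 segments, <2 beats,
  zero-variance correlation inputs) rather than returning NaN.
* Determinism: every stochastic stage takes a seed; per-session sub-seeds
  are derived from one master seed; RNG state is saved and restored so
  library calls never perturb a caller's stream.

## Known limitations

* The planted BP mapping is linear-in-class with two effect channels; real
  SCG–BP relations are nonlinear, multi-channel and subject-specific. High
  accuracy here bounds pipeline loss, not clinical performance.
* The asymmetric first-order sensor surrogate under-represents in-band
  amplitude fidelity of the physical transducer (see above); fiducial
  *timing* through the full chain also inherits a small constant envelope
  latency that cancels in RR statistics but would matter for absolute
  PEP-style timings, which this package does not compute.
* The fiducial rule set and the SQI formula are reconstructions; their
  parameters (search windows, 15 % floor, $c = 0.5$) are validated only
  against the generator.
* Walking artifacts are strictly periodic; real gait has cadence drift and
  broadband impacts.
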