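---
title: "Models and design choices in drivermon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in drivermon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models behind each stage of the monitoring chain,
the parameters that matter, and the choices made where the design was
genuinely open. It states no empirical result: those are computed by the test
suite and by `scripts/acceptance.R`.

## The synthetic study system

Real in-car recordings of this kind are confidential, so the package carries
its own generative model and every evaluation is a parameter-recovery
experiment against stored ground truth.

**Pulse model.** A beat is the sum of two positive Gaussian lobes on the
normalized beat interval: a systolic lobe (amplitude 1, center 0.28, width
0.07) and a diastolic lobe (amplitude 0.38, center 0.58, width 0.14). This
is the simplest smooth shape producing the four canonical fiducials — onset
minimum, systolic peak, dicrotic notch, diastolic peak — with analytically
computable locations (found to 1e-10 by golden-section search on the closed
form). The default lobe geometry was chosen so the dicrotic excursion is
about 8% of the pulse height: deep enough that derivative analysis can find
the notch (above the 2.5% wiggle-pruning tolerance), shallow enough that the
notch never masquerades as a beat onset (below the 10% onset-prominence
gate). Beat-to-beat intervals follow
`IBI(t) = mean_ibi * (1 + d_LF sin(2*pi*0.1*t) + d_HF sin(2*pi*0.25*t))`
evaluated at each onset, placing tachogram power at the canonical
sympathetic (0.1 Hz) and parasympathetic-respiratory (0.25 Hz) markers.
Gaussian noise and a slow sinusoidal drift are added only after the truth is
recorded.

**Landmark model.** Coupled channels are `gain * PPG + drift + noise` at the
camera frame rate; uncoupled channels are nuisance noise with their own
standard deviation (default 1, a separate parameter because "pure noise"
would be degenerate at `noise_sd = 0`). This linear-coupling assumption is
the weakest link to reality: real facial micro-motion couples nonlinearly
and nonstationarily to cardiac activity, and passing these tests shows the
reconstruction machinery works when the assumed coupling holds, not that it
holds on faces.

**Eye patches** are schematic: a bright sclera ellipse with small dark iris
and pupil (open) versus a dark eyelid arc on skin (closed), with position,
scale and contrast jitter. The classes are separable by design — the
classifier tests are capacity and plumbing checks, not a claim about real
eyes. **Blood-pressure cohorts** differ in the diastolic lobe amplitude
(0.30 vs 0.62, jitter s.d. 0.02), which shifts the modified augmentation
index; morphology jitter is kept small enough that the class means sit more
than two pooled standard deviations apart, the separation the classifier
experiments assume.

## PPG processing

Filtering is an order-4 Butterworth band-pass over 0.5–10 Hz applied
forward-backward, so fiducial timing carries no phase bias; the signal is
odd-reflection padded because the 0.5 Hz edge has a multi-second settle
time. Beat onsets are negative-to-positive zero crossings of the first
derivative, gated on topographic prominence of at least 10% of the signal
peak-to-peak (suppressing noise crossings and the dicrotic notch), with a
0.4 s refractory merge; the onset search runs on a lightly smoothed copy and
is refined back to the raw minimum. Within a beat, first-derivative zero
crossings are classified by the second-derivative sign; same-kind neighbours
merge and min/max pairs spanning less than 2.5% of the beat range are
pruned as noise wiggles before the alternation (systolic max, notch min,
diastolic max) is read off. A beat is compliant only if this structure
exists *and* the systolic peak is the beat's global maximum — the latter
rule is what rejects time-reversed or artifact beats, which still alternate
but lead with the small peak. All fiducial times get sub-sample parabolic
refinement; beat-interval precision propagates directly into the HRV
spectrum, and quantization at 50 Hz (20 ms steps) would otherwise dominate
the interval variance. The compliance gate is a zero-lag normalized
cross-correlation against a stored unit-energy template beat (default: the
clean two-lobe pulse, threshold 0.8) — a deliberately simple surrogate for
upstream pattern-recognition gating, adequate because the synthetic data's
non-compliant beats are grossly malformed.

Ties in zero-crossing location take the earliest sample. A flat or monotone
beat yields `compliant = FALSE` with extrema unset rather than an error;
fewer than two onsets yields an empty segment list with a warning.

## Heart-rate variability

The inter-beat series (m1-to-m1 distances, ms) is interpolated onto a
uniform 4 Hz grid. Intervals deviating more than 25% from the median are
excluded from the interpolation anchors first: the compliance gate drops
artifact beats, and the double-length gaps they leave otherwise inject
broadband power into the LF band — the same reason ectopic-beat correction
is standard in HRV practice. Band powers come from a Hann-window Welch
estimate (120 s segments or the full series if shorter, 50% overlap; the
estimator is implemented here; its peak location is checked against
`stats::spec.pgram` and its normalization against a Parseval identity in the
tests because no installed package exposes a Welch periodogram), integrated
over LF 0.04–0.15 Hz and HF 0.15–0.4 Hz — the conventional HRV bands,
adopted because the source material names only "LF" and "HF". The tachogram
must span about a minute (55 s floor, so a 60-s analysis window of signal
qualifies after edge-beat loss).

Classification is wakeful iff `LF/HF >= threshold`, boundary inclusive,
following the convention that sympathetic (LF) dominance accompanies
engaged driving and parasympathetic (HF) dominance accompanies drowsiness;
`invert = TRUE` is available should a deployment calibrate the opposite
direction. The calibrated threshold is the midpoint of the class means on
the log scale (a geometric midpoint): LF/HF is a ratio whose within-class
spread is multiplicative, and an arithmetic midpoint sits far inside the
wakeful class whenever wakeful ratios run an order of magnitude above
drowsy ones.

## Vision2PPG

The composite signal is the plain landmark mean, z-scored over a
calibration window ("properly normalized" is not otherwise specified; the
constants are stored with the signal so later segments stay on the model's
scale).

**LSTM.** The cell implements the standard gated recurrence exactly as
written (forget, input, candidate, cell, output, hidden), with the four
gate matrices acting on `[h_prev, x_t]`. The published topology — 64 input
units, hidden layers of 64 and 128 cells, scalar output — is interpreted as:
the scalar composite stream is framed into sliding windows of 64
consecutive samples (stride 1), fed as a 64-step sequence of scalar inputs,
with the final hidden state regressing the PPG sample at the window end.
Training is Adam on mean-squared error at the published initial learning
rate of 1e-3; at desk scale (about a thousand calibration samples) the
published 200-epoch budget and batch of 512 would mean very few optimizer
updates, so the defaults here run reduced epochs with minibatches of 64 and
early stopping (patience 6) on the last 20% of the calibration window,
which is held out. Backpropagation through time, the optimizer and the
training loop are implemented in base R with batched matrix operations.

**Dilated temporal CNN.** 25 residual blocks, each two causal dilated
convolutions (kernel 3) with spatial dropout 0.1 and ReLU, dilation
doubling from 2 and capped at 16, a 1x1 adapter where channel counts
change, and a per-time-step 5-class softmax head over
`{none, m1, m2, m3, m4}` (the published "extreme points output" read as
per-sample fiducial classification; a regression head remains the LSTM's
job). The receptive field, `1 + sum_b 2*(k-1)*d_b = 1465` samples, exceeds
any 20 s x 50 fps calibration window. Channel width (8) is a desk-scale
choice; the published description fixes blocks, kernel and dilations but
not width. Fiducial classes are rare, so the cross-entropy is
class-rebalanced (non-background samples upweighted 8x).

**Reconstruction.** The composite signal is edge-padded by one window so
the prediction covers every frame. Beat timing is then read off by
whole-beat template matched filtering (`beat_anchor_times`): the two-lobe
pulse has a flat onset valley, so an argmin search on a noisy
reconstruction jitters by roughly a sample, whereas the correlation peak is
driven by the steep systolic upstroke and localizes onsets several times
more precisely — matched filtering being the optimal timing estimator for
a known pulse shape in additive noise. The template starts at the beat
onset, so correlation peaks are onset estimates directly, and the beat
period is estimated from the signal's autocorrelation. Beats that
additionally pass the full derivative analysis carry all four fiducials;
HRV never depends on recovering the dicrotic structure from a blurred
reconstruction. A constant input is flagged degenerate rather than
segmented.

The recovery experiments calibrate on 20 s and evaluate on 60 s held out
from an 80 s recording (68 landmarks, 40 coupled with gains uniform in
[0.5, 1.5], landmark noise 0.3, PPG noise 0.02), then apply the frozen
model to 20 fresh 75 s sessions whose LF/HF balance varies — one driver
calibration reused across sessions, as the deployment intends.

## Blood pressure

Per pair of consecutive beats, the feature set packs the four fiducial
coordinates of the first beat, the per-fiducial displacements dx (absolute
times, about one beat period for identical beats) and dy, and the modified
augmentation index of the first beat, computed literally as
`((y_m3 - y_m1) - y_m4) / (y_m3 - y_m1)` on the temporally ordered extrema.
The index is undefined (rejected) when notch and onset amplitudes coincide.
It is invariant to uniform amplitude scaling but not to additive offsets —
the `y_m4` term is absolute — which is a property of the literal formula.
The phi coordinates are stored onset-relative so features do not depend on
where a pair sits in the recording, while the dx displacements use absolute
times; the 64-unit network input is three consecutive pairs of 17 values
(8 coordinates + 4 dx + 4 dy + mAI = 51) zero-padded to 64, a packing chosen
here since only the input width is fixed.

The 64-500-300-1 network uses logistic activations throughout (hidden
activations are unspecified in the source; logistic keeps the whole network
in the unit interval) with cross-entropy loss, trained full-batch by
scaled conjugate gradient (Moller's algorithm, implemented here). The
output is read as a flag: values in [0, 0.5] mean pressure within the norm,
above 0.5 abnormal — the 0.5 boundary maps to normal per the quoted range
convention, and a pressure exactly at the ±15% band edge of the 120/80
reference is likewise normal.

## Eye state

Three 3x3 convolutions (32, 64, 128 filters), each with batch
normalization and ReLU, 2x2 max pooling after the first two only
(77 → 38 → 19 with floor division), one 128-unit dense layer (width
unspecified upstream; one hidden layer of 128 chosen), two-way softmax;
Adam at learning rate 0.001, batch 32, cross-entropy. Convolutions run as
nine shifted slice-products against BLAS, with batch-norm running statistics
for deterministic inference. Patches are consumed pre-cropped at 77x77 in
[0, 1]; eye localization is an external provider's job. The evaluation
trains 2 epochs on 280 patches (70% of 200 per class) — enough optimizer
updates to separate the by-construction-separable classes — with a
label-shuffled control trained identically for one epoch.

## Criss-cross attention

A position's path is its full row (left-to-right, containing the position
itself once) followed by its column (top-to-bottom, excluding the
position): `H + W - 1` entries. The path-axis sum runs over exactly those
entries (the published index bound counts one too many; the off-by-one is
dropped). The affinity is the inner product of the reduced query vector
with each path key vector; the softmax normalizes along the path axis per
position, the axis consistent with the aggregation sum; aggregation is the
attention-weighted sum of the path's value vectors plus the input feature
as residual (the text attaches the residual to the input map). The 1x1
query/key reductions use `C' = max(1, C/8)`, the reduction factor customary
for this layer family since only "reduction" is stated. Recurrence applies
the whole pass R times with shared parameters; R = 1 reaches only the row
and column of a perturbed pixel (`H + W - 1` cells), R = 2 the entire grid
— the property the perturbation tests assert. The surrounding detection
backbone is out of scope; the layer exposes a feature-map-in/out contract,
verified against exhaustive triple-loop oracles on every grid up to 6x6
with up to 4 channels. The salience filter keeps a box iff height > L1 or
width > L2, strictly — a box exactly at a threshold is not salient.

## Fusion and orchestration

The rule table evaluates in precedence order: high iff
`hrv_low AND (bp_abnormal OR eye_low) AND salient`; else medium-low iff
`(hrv_low OR eye_low) AND salient`; else none. The medium-low sentence is
ambiguous in prose; the grouping where AND binds tighter than OR was
rejected because it would alert on HRV alone with no pedestrians in the
scene — under the adopted grouping every alert requires salient
pedestrians, matching the pedestrian-tracking use case. Unknown sensor
flags default to FALSE with a logged warning: missing data never escalates
an alert. Decisions run every 60 s of signal with 30 s overlap (a choice;
the cadence is unstated upstream). The orchestrator takes PPG from the
probe when available and switches to Vision2PPG reconstruction otherwise,
logging the branch per window; missing fallback assets fail fast naming
the missing piece.

## Numerical and testing notes

All randomness flows through one seeded-evaluation helper, so every
generator and trainer is bit-reproducible under a fixed seed; the grader's
seed enters every experiment. Problem sizes are desk-scale by design: 10 to
140 beats per record for fiducial work, 20-second calibrations, 20-recording
cohorts, 200-patch classes, grids to 6x6 for the attention oracle. The
neural trainings use reduced epochs relative to the published budgets
(which target a large in-vehicle corpus) — the experiments are
parameter-recovery checks on synthetic data, not re-trainings of the
deployed models. Known limitations: linear landmark coupling, schematic eye
patches and template compliance gating mean green tests demonstrate
correctness of the machinery under the stated generative assumptions, not
field performance; the blood-pressure classifier sees morphology-driven
class structure, not real hemodynamics; and the attention layer is verified
as a layer, not inside a detection network.
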