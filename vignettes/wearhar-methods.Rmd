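---
title: "Methods: simulation, preprocessing, recognition and adaptive prescription in wearHAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, preprocessing, recognition and adaptive prescription in wearHAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearHAR)
```

wearHAR is a desk-scale toolkit for multimodal wearable-sensor digital
health studies: it simulates labelled 12-channel sensor sessions and a
virtual exercise physiology, cleans and aligns the signals, classifies
2-s activity windows with a hybrid Transformer--GCN model, personalises
the classifier by federated averaging, generates exercise prescriptions
with a PPO policy under a hard cardiovascular safety rule, and scores
simulated 12-week trials. This vignette documents the models, their
assumptions, the tunable parameters and the numerical choices, in the
order data flows through the package.

## The synthetic sensing layer

No public dataset accompanies the study design this package supports,
so every downstream stage is exercised on simulated data whose
generating process is fully known. A `SensorStream` (a
`SummarizedExperiment` with channels as rows) carries 12 channels: the
three accelerometer axes at each of the wrist, chest and ankle
placements, plus heart rate, galvanic skin response (GSR) and skin
temperature.

**Accelerometer model.** Each action label owns a dominant frequency
and an amplitude (running 2.8 Hz / 8 m/s^2 at full intensity, jumping
2.2 / 10, walking 1.8 / 3.5, squat 0.6 / 4, bending 0.45 / 3,
stretching 0.25 / 1.5, rest 0 / 0); channels are sinusoid + Gaussian
noise (sd 0.3 m/s^2) with placement-specific gain and random per-axis
phase, and gravity on the z axes. The model is deliberately minimal so
that tests have closed-form oracles: a periodogram argmax recovers the
configured frequency, and windows are class-separable by construction.
It does *not* emulate biomechanically realistic motion, orientation
changes, sensor saturation, or heteroscedastic noise -- so a classifier
passing here is shown to learn frequency/amplitude structure, not to
work on real accelerometry.

**Physiology.** Heart rate relaxes first-order (time constant 30 s,
configurable) toward `resting + 0.92 * intensity * (HRmax - resting)`,
bounded by the theoretical maximum `220 - age`. Fatigue accumulates
superlinearly in intensity (`0.085/60 * i^1.6 * (1 + 0.8 f)` per work
second) and decays exponentially during rest with a 900-s time
constant -- slow enough that fatigue carries across a session, which is
what makes adaptive pacing worthwhile. Chronic adaptation follows a
logistic approach to fixed ceilings (VO2max 62 mL/kg/min, 65
repetitions), giving diminishing returns. These dynamics are the
package's own design: any monotone saturating model satisfying the
bound invariants would do, and all rates are arguments.

**Sampling-rate policy.** `sampleRatePolicy()` is a nondecreasing step
function over {50, 100, 150, 200} Hz with breakpoints at intensity
0.25, 0.5 and 0.75, so low-intensity activity is sampled at 50 Hz and
high-intensity activity at 200 Hz. Sessions simulated with the policy
have piecewise-constant rates and are later unified by resampling.

**Corruption.** `injectInterference()` modifies only its window
(wide-band EMI bursts and sparse motion-artifact spikes on
accelerometer channels; linear drifts on skin temperature or GSR);
`dropSegments()` masks samples either independently (`mean_gap = 1`)
or in geometric runs of a requested mean length, retaining the
pre-drop values as ground truth for imputation scoring.

## The preprocessing pipeline

1. **Resampling.** Linear interpolation onto a uniform grid. The
   reference rate is configurable with default 100 Hz, the value tied
   to the 2-s windowing; 50 Hz is equally valid and exposed as
   `reference_hz` (the two appear interchangeably in descriptions of
   this pipeline family, so the package treats the rate as a knob, not
   a constant). Grid points bracketed by a missing source sample stay
   masked.
2. **Wavelet denoising.** A periodised orthogonal Daubechies-9 DWT is
   implemented in the package (no wavelet package ships with the
   target R installation); the 18 scaling-filter constants are frozen
   in source and checked in tests via the quadrature-mirror identities
   and a perfect-reconstruction round trip (< 1e-8). Detail
   coefficients pass through the semi-soft threshold with cutoffs
   lambda_low < lambda_high; the approximation is untouched. The
   shrinkage rule is implemented exactly as specified, including its
   discontinuity of size lambda_low at |d| = lambda_high; a
   `continuous = TRUE` variant replacing the top branch by the
   identity is available but off by default. Because no cutoff values
   are prescribed, the default rule is the per-signal universal
   threshold: sigma-hat = MAD/0.6745 of the finest detail scale,
   lambda_high = sigma-hat * sqrt(2 log N), lambda_low =
   lambda_high / 2 -- standard, reproducible, and respecting the
   ordering constraint.
3. **Gap imputation.** The printed recurrence h_t = act(W_h h_{t-1} +
   W_x x_t + b), xhat = W_o h_t + b_o is implemented as a single
   tanh recurrence with a linear readout, trained by full
   backpropagation through time (Adam) on one-step-ahead MSE over the
   observed regions (window tau defaults to 1 s of samples; hidden
   size 16). Gaps are filled by rolling the predictor forward; for
   interior gaps the same model is also run on the time-reversed
   series, and the forward roll, the backward roll and the linear
   bridge between the gap edges are combined by a stacked
   least-squares combiner whose weights are calibrated, per
   distance-to-nearer-edge bin, on synthetic gaps cut from the fully
   observed stretches of the same series. The two-sided construction
   is the package's choice: a purely causal predictor cannot beat
   two-sided interpolation on short interior gaps of a time-reversible
   process, while the rolled predictions' mean reversion wins mid-gap
   on the contiguous multi-sample drop-outs that motivate imputation
   in the first place; the calibrated combination, which contains the
   linear bridge in its span, adapts the balance to the series at
   hand. Gaps with no history fall back to linear interpolation, with
   a message.
4. **DTW alignment.** The cumulative-cost recursion with
   D(1,1) = C(1,1), first row/column accumulating along their only
   feasible direction, and backtracking that prefers the diagonal on
   ties. The local cost defaults to squared Euclidean distance on
   z-scored series; a Sakoe-Chiba band (radius 0.25 max(M, N)) bounds
   the search in pipeline use and is disabled in oracle tests, which
   compare against exhaustive monotone-path enumeration for lengths up
   to 6. `alignChannel()` warps a lagging physiological channel onto
   the acceleration timeline and reports the median path offset as the
   lag estimate.
5. **Windowing and standardisation.** 2-s windows with 50% overlap,
   majority label per window (ties to the earlier label), trailing
   partial windows dropped. Z-score statistics (per-channel mean and
   population standard deviation, pooled over time and windows) are
   fit on the training split only and applied to all splits;
   zero-variance features are kept with scale 1.

## The Transformer--GCN classifier

Each T x 12 window is cut into `subFrames` (default 8) sub-frames; per
sub-frame and placement node, fixed summary statistics (mean, standard
deviation, RMS of the first difference, per channel) form the node
features. The physiological channels ride on the chest node, which is
where that hardware sits. Node features are embedded by per-node
linear maps, mixed by graph-convolution layers
H' = ReLU(D^{-1/2} A D^{-1/2} H W) over the self-looped placement
graph (three nodes, fully connected by default -- the package observes
placements, not joints, so the body graph is a declared stand-in, and
the node set is configurable), concatenated into one token per
sub-frame, projected to the model width and tagged with sinusoidal
positional encoding. A post-norm Transformer encoder (multi-head
self-attention, two-layer feed-forward, residuals, layer
normalisation) processes the sequence; mean pooling and a linear
softmax head give class probabilities.

Both passes are written out explicitly in R and the backward pass is
verified against numerical gradients in the test suite (agreement to
~1e-7 relative). Training is full-batch Adam on the cross-entropy with
fixed-seed initialisation; when a validation split is given the
best-validation-accuracy parameters are kept. The test-scale default
is width 64 with 4 heads and one encoder layer; the full-scale
configuration (width 512, 8 heads) is reachable through `harConfig()`
but is not what the test suite runs. The evaluation protocol is
subject-level: `splitDataset()` partitions *subjects* 7:2:1 with a
dominant-class stratified assignment, and `crossValidate()` runs
subject-level k-fold (default 5) selection by macro F1. The
depth-0 reference is a nearest-centroid classifier on per-window
channel means and standard deviations.

The default study-condition dataset (`syntheticHarDataset()`) is 10
subjects x two 10-s bouts of each of five actions at per-bout
intensities uniform on [0.45, 1], 100 Hz, about 99 windows per
subject. Bout intensity is varied so that amplitude statistics alone
do not solve the task; the learned model must combine amplitude and
frequency cues, which is what lets it beat the centroid baseline.

## Federated personalisation

`fedavgAggregate()` is the sample-count-weighted mean of client
parameter vectors -- a convex combination, tested coordinate-wise.
`localFinetune()` runs local training passes (default 10, matching the
stated local-round count; the federation round count is a separate
argument) from the global parameters and returns only the flattened
parameter increment plus the local sample count; the update object's
transport schema is asserted by test to contain nothing else. The
spec-level narrative conflates local epochs with federation rounds;
the package exposes both counts. No secure aggregation or differential
privacy is implemented: the privacy property is purely the mechanical
one of never serialising raw windows.

## PPO exercise prescription

The intervention environment steps the virtual physiology in 180-s
blocks of a session (15 blocks ~ 45 min). Within a block, work bouts
of 60 s alternate with the prescription's rest interval, so the rest
interval directly sets the work fraction. The policy is a
softmax-linear actor over a discrete intensity grid {0.1, ..., 1.0}
(continuous vs discrete being unstated upstream, discrete keeps the
actor exactly analysable) on features (1, HR reserve fraction,
fatigue, HRV/100); the critic is linear in the same features.

**Reward.** The per-step reward is the negative goal loss
L = w1 f_muscle + w2 f_fatloss + w3 f_fatigue (defaults: negative
expected strength-adaptation increment; negative expected energy
expenditure; predicted end-of-step fatigue -- all pluggable through
`goalSpec()`), minus an injury-risk penalty, plus a terminal bonus of
5 x the session VO2max gain. Injury events are sampled with
probability logistic in fatigue and executed intensity
(plogis(-7 + 6 f + 3 i)); the *reward* uses the expected penalty
(penalty x probability) rather than the sampled event, which keeps the
learning signal low-variance, while the events themselves are counted
for the safety and ablation statistics. The reward function is the
package's own construction and is stated here precisely because no
upstream definition exists.

**Training.** Clipped-surrogate updates (epsilon 0.2) with
generalised advantage estimation (lambda 0.95, discount 0.99),
advantage normalisation per episode, an entropy bonus (coefficient
0.03) and learning rate 0.08, 4 gradient epochs per episode. The
training log records per-episode reward, mean executed intensity,
override and injury counts; the summary reports the convergence
episode (first episode whose trailing-window mean reward is within
10% of the final window's mean) and an oscillation count (sign changes
of the smoothed mean-intensity trend). Only *orderings* against the
rule-based baselines are tested -- the published absolute reward
numbers for this family of comparisons depend on an unspecified
environment and are not reproducible.

**Safety.** `safetyOverride()` implements the hard rule: if heart rate
exceeds 90% of (220 - age), or severe movement deformation is
flagged, the proposal is replaced by a mandatory recovery prescription
(intensity capped at 0.2, rest at least 90 s), and the override
persists until heart rate falls below 85% of maximum (hysteresis, so
the system does not chatter at the threshold). Every rollout applies
the override between the policy and the environment, so no executed
step can violate the rule; the suite verifies zero violations over
10,000 steps of continuous maximal effort by a 55-year-old subject
(chosen so the threshold is actually reached -- overrides trigger
thousands of times in that test).

**Rest-interval ablation.** The >= 90 s rest floor is compared against
unconstrained rollouts on matched seeds. The comparison trains the
policy under an aggressive goal profile (weights 0.60/0.35/0.05,
injury penalty 2) mirroring the non-optimised arm of the ablation
design -- whose reward lacks the rest-adequacy emphasis -- because a
safety-weighted policy simply never gets hurt, leaving nothing for the
constraint to improve. Directionally, the floor must lower
end-of-horizon fatigue and injury counts; both are asserted.

## Trial metrics

Growth rates ((post - pre)/pre x 100), injury rates and signed percent
changes are reported half-up to one decimal, matching how such values
are conventionally printed (base R's round-half-even would differ at
the boundary). `groupCompare()` gates within-group paired t-tests on
Shapiro-Wilk normality of the differences (Wilcoxon signed-rank
fallback; an exact sign test when the differences are degenerate;
groups of fewer than three default to the t-test since Shapiro-Wilk is
undefined), compares week-12 values *and* change scores between groups
(both labelled, since summaries of this design are ambiguous about
which is meant), uses the pooled-SD Cohen's d, and compares injury
rates by chi-square with a Fisher fallback when expected cell counts
drop below 5. `simulateTrial()` runs a two-arm 12-week virtual trial
(adaptive policy vs fixed baseline) to produce record tables for
`trialReport()`; it demonstrates the machinery and makes no claim of
reproducing any human cohort.

## Problem sizes and determinism

The suite runs at desk scale by choice: the classifier criterion uses
10 subjects (~990 windows), width 64 and 100 epochs (~1.5 min); the
policy comparison uses 12 training seeds x 80 episodes (~1 min); the
ablation 3 seeds x 60 episodes; the safety check 10,000 steps; DTW
oracle tests 200 instances with lengths <= 6. Every seeded operation
restores the caller's RNG state and is bit-stable; one top-level seed
is fanned out per stage through a deterministic string hash
(`runPipeline()` records it in `run.json` with the resolved
configuration).

## Known limitations

* The generator's separable sinusoid classes make recognition easier
  than real accelerometry; accuracy numbers here say nothing about
  field performance.
* The physiology is a two-state (heart rate, fatigue) caricature with
  no interindividual variability beyond the subject fields; the
  injury model is a convenience logistic.
* The full-batch R implementation of the classifier is practical to a
  few thousand windows; it is a reference implementation, not an
  engine.
* Effect sizes reported by `groupCompare()` on simulated trials
  reflect the simulator's assumptions, not any empirical cohort; the
  published effect-size values for the corresponding human trial are
  not derivable from its printed summaries and are deliberately not
  acceptance-checked.
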