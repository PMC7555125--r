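---
title: "Methods: thermally cycled e-nose breath analysis with a perceptron classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermally cycled e-nose breath analysis with a perceptron classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and the analysis problem

An electronic nose for breath screening exposes an array of 14 metal-oxide
(MOS) gas sensors to a subject's exhaled air and classifies the collective
response pattern. The sensors run in a thermal-cycling mode — 3.5 s of
heating followed by 5.5 s of cooling, a 9 s period — so a single chemical
exposure produces a temperature-dependent response waveform rather than one
steady-state value. Each acquisition lasts 90 s at 30 Hz: 2700 samples per
channel. Alongside the 14 sensors, two synchronization channels carry a
square wave locked to the heater phase (a constant high level while
heating, zero while cooling), and the breath sample is injected into the
chamber at the heat-to-cool transition at the 5000 ms mark. A record is
therefore a 16 x 2700 matrix of ADC counts — 43,200 values — plus the
subject's age, sex and smoking status.

`enosepipe` implements the full analysis chain over such records:

1. **segmentation** of thermal periods from the sync channels,
2. **feature extraction** — elementwise ratios of two cooling segments per
   sensor, downsampled to 16 values, plus three encoded covariates
   (227 inputs),
3. **classification** with a from-scratch 227-454-1 sigmoid perceptron
   trained by full-batch backpropagation with early stopping,
4. **evaluation** by repeated random 5-fold cross-validation
   (20 repartitions, 100 experiments) reporting accuracy, sensitivity and
   specificity.

Because no public breath dataset with this acquisition layout exists, the
package ships a first-class synthetic cohort generator whose defaults
emulate the study conditions: 36 cancer and 23 control subjects with the
published demographic composition.

## The synthetic generator

### Waveform model

Each sensor's baseline is a smooth, exactly periodic template: a
saturating rise during the 105-sample heating phase and an exponential
decay toward a per-sensor floor during the 165-sample cooling phase,
parameterized per sensor by a floor, an amplitude and a decay constant
(`enose_sensor_params()`). The record opens on the tail of a cooling phase
(45 samples), so the first heat-to-cool transition — and the sample
injection — falls exactly at sample 150 (5000 ms x 30 Hz). Only the shape
class of the template matters downstream: the feature stage uses
within-record ratios, which cancel the template entirely.

### Injection response

From the injection onward the breath sample multiplies each sensor's
signal by a response factor

    r_s = exp(beta_s * effect_size * label + gamma_s + eta_s)

where `gamma_s` is the sensor's class-independent response to breath,
`beta_s` its disease-linked component (substantial on half of the 14
sensors, near zero on the rest, so the class signal is distributed but not
universal), `effect_size` the tunable separation between classes, and
`eta_s ~ N(0, subject_sd^2)` a per-record, per-sensor log-response jitter.

Two choices here are deliberately the package's own:

* **Ramp placement.** The factor ramps linearly from the *end of the
  cooling phase in which the injection occurs* (sample 315) to full effect
  one thermal period later (sample 585), modelling gas transport and
  mixing delay. This leaves period 1's cooling segment as a clean
  pre-response baseline, so the noise-free period-4 / period-1 ratio
  equals `r_s` exactly — the closed form the test suite checks.
* **Between-subject variability** (`subject_sd`, default 0.15). Real
  breath responses vary between subjects far more than sensor noise
  (lifestyle, diet, physiology). Without this term, any nonzero effect
  size is trivially separable and the accuracy-versus-effect curve
  degenerates into a step. With it, the default grid (0, 0.25, 0.5, 1.0)
  spans chance to near-perfect separation. Closed-form checks set it to
  zero.

Additive Gaussian sensor noise (`noise_sd`, default 8 counts on signals of
hundreds to thousands of counts) and a slow multiplicative drift
(`drift_per_cycle`, default 0.5 % per 9 s cycle) complete the model.
Values are clipped to the 12-bit ADC range [0, 4095]; the bit depth is not
published for the original instrument and 12 bits is the conventional
choice for the MEGA2560-class acquisition board described.

### Cohort composition

Default demographics reproduce the study: the cancer group has 6 women and
30 men with 2 subjects aged 20-40 and 34 aged 40-75; the control group has
16 women and 7 men with 14 aged 20-40 and 9 aged 40-50. Ages are drawn
uniformly within their bands (only the bands are published) and smoking is
Bernoulli(0.4) independent of class (recorded in the study, prevalence
unpublished).

This composition makes age and sex genuinely informative about the label —
as they were in the study cohort. That is faithful, but it means a
"no-signal" experiment cannot use it: with `effect_size = 0` the
covariates alone predict class well above the majority rate. The generator
therefore has a `demographics = "balanced"` mode (age uniform 20-75, sex
fair coin, label-independent) used by the leakage/null guard and the
signal-recovery study, so those experiments measure only what the sensor
channels carry.

### What the generator does not emulate

No physicochemical sensor kinetics (Langmuir adsorption, humidity and
temperature cross-sensitivity), no chamber purge dynamics between samples,
no sensor aging beyond geometric drift, no correlated noise across
sensors. The per-sensor response magnitudes are synthetic placeholders —
the real ones are unpublished. Passing tests therefore demonstrate that
the *pipeline* recovers a class signal of known size from records with
this structure; they say nothing about the clinical performance of any
real instrument.

## Segmentation

Thermal periods are located exclusively from the sync channels (the
package requires them; there is no period-free fallback). A heat-to-cool
transition is the first index of a maximal run of zeros after debouncing:
runs shorter than 5 samples (167 ms) are absorbed as glitches, which makes
the detector total on single-sample corruption while leaving clean
meanders untouched. The two sync channels must agree on every transition
index after debouncing; any disagreement is a hard error naming the sample
— the channels have no other purpose than acquisition integrity, so a
majority vote would hide exactly the faults they exist to expose.

Indexing is 0-based with half-open `[start, end)` intervals throughout.
Each complete cycle contributes the 165 samples from its heat-to-cool
transition as the cooling segment; cycles whose cooling phase would run
past the end of the record are discarded, as is a partial cooling tail at
the start. On the default timing grid the cooling segments start at
samples 150, 420, 690, ... (stride 270 = 9 s x 30 Hz) and nine complete
cycles fit in 2700 samples — the tenth would end at sample 2745. "Period
1" downstream always means the first complete cycle; since the published
description does not pin whether period numbering starts at the valve
event or at recording start, both ratio period indices are exposed as
parameters.

## Features

For each sensor the feature stage divides the cooling segment of period 4
elementwise by that of period 1 (165 ratios), then keeps every 10th value
— 0-based indices 0, 10, ..., 150 — reducing 165 to 16 per sensor. The
downsampling phase (start at 0, drop the last 5 samples) is the simplest
convention that yields the published count of 16; the offset is
configurable. A zero anywhere in the denominator segment (an ADC floor
hit) makes the record unusable and raises a degenerate-signal error naming
the sensor and sample rather than propagating infinities.

Ratios of raw ADC counts are used rather than converted resistances; under
any per-sensor linear conversion the two are identical, which is also why
the features are exactly invariant to per-sensor gain (a tested property).

Age enters as `age / 100` — keeping it the same order of magnitude as the
ratio features, which sit around 1-2 — and sex and smoking as 0/1
indicators (male = 1, smoker = 1). No further normalization (no
z-scoring) is applied: all 227 inputs are already O(1), sized for sigmoid
units. The total input dimension is 14 x 16 + 3 = 227.

## The perceptron

The network is 227 inputs, one hidden layer of 454 units (twice the input
dimension, fixed), one output unit, logistic sigmoid on both layers.
Training is plain full-batch gradient descent with backpropagation —
deliberately optimizer-free, which makes bit-exact determinism trivial
given a seed. Several training details are unpublished for the original
system and are repository choices, each exposed in `train_config()`:

* **Loss**: logistic cross-entropy by default (the natural pairing with a
  sigmoid output; its output-layer delta is simply `p - y`), with MSE
  available for fidelity experiments.
* **Learning rate**: 0.05.
* **Initialization**: uniform Glorot bound per layer, seeded; biases zero.
* **Early stopping**: the published protocol stops when training error
  still falls but test-set error starts to rise, observed between 500 and
  8000 epochs. Operationally: every `eval_every` (10) epochs the held-out
  accuracy is recorded; training stops at 8000 epochs or once no
  improvement has been seen for `patience` (200) epochs after a 500-epoch
  minimum; the returned model is the snapshot at the best held-out
  accuracy, earliest epoch on ties.
* **Decision threshold** 0.5, with `>=` mapping to the cancer class.

Analytic gradients are verified in the test suite against central
differences (relative error below 1e-6) and the vectorized forward pass
against an independent two-loop evaluator (1e-12).

## Evaluation protocol

Cross-validation mirrors the published design: the cohort is randomly
divided into 5 groups (on 59 records: four of 12 and one of 11, larger
folds first), training runs on four groups, and the fifth serves *both*
as the early-stopping set and as the reported test set. This single-split
usage is a known optimistic-bias design; it is reproduced deliberately for
fidelity, and a `validation = "three-way"` mode (inner carve-out for
stopping, untouched test fold) is available as a non-default extension.
The partitioning is repeated 20 times (unstratified, as published; a
stratified option exists), giving 100 experiments. Reported metrics are
unweighted means of per-experiment accuracy, sensitivity and specificity
("average values for 100 experiments" reads as macro averaging; pooled
confusion counts are available as an option). Experiments with an empty
positive or negative class report that metric as missing, never as zero.
A master seed spawns one child seed per experiment, so any experiment can
be re-run in isolation.

## Problem sizes and numerical choices

The package defaults keep the published protocol (up to 8000 epochs). The
test suite and the analysis scripts run a reduced profile — typically
1000-2000 epoch cap, 500-epoch minimum, patience 200, evaluation every 20
epochs — which preserves the protocol's 500-epoch floor while keeping a
full 100-experiment evaluation at desk scale. The signal-recovery study
uses effect sizes {0, 0.25, 0.5, 1.0} with five generator seeds each and
one 5-fold repartition per seed (295 held-out predictions per effect
size). The null guard checks that zero-effect accuracy under balanced
demographics lies within the 95 % binomial band of the majority-class
rate (36/59); with best-snapshot early stopping on the held-out fold the
null accuracy sits slightly above the majority rate, which is the
optimistic bias of the reproduced protocol, and inside the band.

Cohort containers are ZIP archives of per-record CSVs with values printed
at 17 significant digits, so write-then-read round-trips are bit-exact;
records are validated on read with *all* violations reported, not only the
first.

## Known limitations

* Table-3-level clinical metrics of the original study are not
  reproducible: the 59-subject dataset was never deposited, so all
  quantitative claims here are about synthetic cohorts of known effect
  size.
* The generator's response coefficients are placeholders; absolute
  accuracies on synthetic data should not be read as clinical estimates.
* The reproduced evaluation design reuses the held-out fold for early
  stopping, inflating reported metrics; use the three-way mode when an
  unbiased estimate matters more than fidelity.
* The segmentation requires intact sync channels and a fixed 9 s period;
  it does not adapt to drifting cycle timing.
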