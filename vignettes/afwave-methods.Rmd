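---
title: "Time-frequency ECG classification with afwave: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency ECG classification with afwave: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`afwave` classifies short single-lead ECG recordings into four rhythm
classes — normal sinus (N), atrial fibrillation (A), other rhythms (O) and
noise (~) — by converting each recording into a time-frequency image and
training a convolutional classifier on those images. This vignette is the
package's account of the science: the model at each stage, the tunable
parameters and why their defaults are what they are, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Why time-frequency images

Atrial fibrillation shows up in a single-lead ECG as three joint phenomena:
irregularly irregular RR intervals, absent P waves, and a continuous
fibrillatory baseline oscillation conventionally located around 4–10 Hz.
None of these is a single "component" one can threshold; all of them are
distributed over time and frequency. Analysing a 30 s window as a continuum
— rather than beat by beat — lets a classifier see the joint pattern. The
package therefore renders each 30 s cut as a scalogram image and treats
rhythm classification as image classification.

## Preprocessing

Records are loaded from the PhysioNet/CinC 2017 layout (a MATLAB v5
container holding one int16 sample vector named `val`, with a WFDB-style
header). ADC units are converted to millivolts using the header gain; when
the header omits a gain the package assumes 1000 units/mV, the CinC 2017
convention. The amplitude unit is itself a convention: the source format
does not state units, and the mV reading is an assumption flagged here.

Segmentation is purely duration-based: a record at least 30 s long
contributes its **first** 30 s (`round(30 * fs)` samples, half-open window
starting at sample 0); shorter records are excluded. The cut position is a
design choice — the start of the record is the simplest deterministic rule —
and a `offset_s` argument exposes other positions. No beat detection or
R-peak alignment is performed anywhere; that is a deliberate non-goal of the
continuum approach.

Kept cuts are resampled from the 300 Hz acquisition rate to a 128 Hz
analysis rate. Resampling is Fourier-domain (truncate or extend the DFT,
`scipy.signal.resample` style) rather than polyphase FIR: the polyphase
resampler available to the package has an uncompensated group delay of
about two samples at the 300→128 ratio and visible passband ripple, which
breaks the package's guarantee that a band-limited (< 40 Hz) signal
round-trips with relative RMS error below 1e-2. Fourier-domain conversion
is exact for band-limited content at the cost of assuming near-periodicity
at the edges, an acceptable trade for 30 s windows whose content is far
from the band edge. Both the STFT and the CWT branch operate on the 128 Hz
segment by default so the two image families share a time axis; passing
`fs_analysis = 300` keeps the native rate.

## The transforms

**STFT.** The spectrogram branch uses a symmetric 256-point Hamming window
(`w[n] = 0.54 − 0.46 cos(2πn/(L−1))`) with 128-point overlap and a
one-sided spectrum; frame count is `floor((N − 256)/128) + 1` with no
zero-padding. A 30 s, 128 Hz segment gives 129 bins × 29 frames.

**Generalized Morse CWT.** The main branch. The analytic Morse wavelet is
defined in the frequency domain:

$$\Psi(\omega) = U(\omega)\, c\, \omega^{\beta} e^{-\omega^{\gamma}},$$

with $U$ the unit step. The family is parameterised by the shape exponent
$\gamma$ and the time-bandwidth product $P^2 = \beta\gamma$; the package
follows the common toolbox convention in which "Morse (3, 60)" means
$\gamma = 3,\ P^2 = 60$, hence $\beta = 20$. The peak angular frequency is
$\omega_p = (\beta/\gamma)^{1/\gamma}$, about 1.8821 for (3, 60). The
response is normalised so its peak value is exactly 2 at every scale — the
one-sided analytic convention under which a unit real sinusoid at a
center frequency has unit scalogram magnitude.

The filter bank is geometric: scales grow by $2^{1/v}$ with $v = 10$ voices
per octave by default (a conventional density for this filter-bank style;
the ridge-recovery tests quantify what one voice of error means). The
smallest scale places the wavelet peak at the Nyquist frequency; the
largest is bounded so two time-domain standard deviations of the wavelet
(σ ≈ $\sqrt{P^2}/\omega_p$ samples at unit scale) fit inside the signal.
The frequency-axis limits are thus a convention of the implementation, not
a property of the data.

Coefficients are computed per scale as an inverse FFT of the signal
spectrum times the scaled wavelet response. Two normalisations are
available: `L1` (default; unit sinusoid → unit magnitude, the rendering
convention) and `L2`, the literal $1/\sqrt{a}$ integral-transform form. The
signal is extended by reflection to twice its length before the FFT to
suppress circular wrap-around; the cone of influence — the per-time
boundary frequency below which a coefficient is within one e-folding of an
edge — is computed from the wavelet's time spread and *reported* rather
than masked, leaving the caller to decide what to trust. The test suite
verifies the FFT path against direct numerical integration of the
transform (a trapezoid-rule correlation against a numerically synthesised
time-domain wavelet, sharing only the documented boundary extension) to
within 1e-3 relative error outside the cone of influence.

## Rendering

A scalogram (elementwise modulus of the coefficients) becomes an RGB image
in four steps: normalise to peak 1, log-compress as `log(1 + m/1e-8)`,
min-max scale, bilinearly resize to the target panel (224×224 by default;
the pipeline preset uses 64×64 for the desk-scale CNN), and map through a
yellow-high perceptual colormap so regions of high energy concentration
appear yellow. Normalising *before* log compression makes rendering exactly
invariant to positive rescaling of the magnitudes, which would not hold for
`log(1 + m/ε)` applied to raw magnitudes; dynamic-range compression is
preserved. The CWT's geometric frequency grid makes the vertical axis
log-frequency by construction; the STFT's is linear; in both cases the
highest frequency is the top row and no re-gridding is applied. Images
contain only the data panel — no axes, ticks or colorbars, which would be
chart furniture in a classifier input. All-zero matrices render uniformly
at the colormap's low end.

## Classifier

The dataset is split 64:16:20 into training, validation and test sets by
seeded largest-remainder apportionment, stratified by class so every class
appears in every subset (per-class shares are reconciled to the global
subset sizes). The training recipe is rmsprop (squared-gradient decay 0.9),
minibatch 64, at most 105 epochs, validation once per epoch, and early
stopping when validation accuracy has not improved for 10 consecutive
checks — "10 iterations" is read as validation checks, not optimiser steps,
since step-level patience would halt almost immediately. The returned
weights are those of the best validation check. A gradient-clipping
threshold is exposed but defaults to no clipping. The `train_config()`
default learning rate is 1e-4, the transfer-learning fine-tuning value; the
pipeline preset for the bundled CNN uses 1e-3, the conventional rate when
training a small network from random initialisation.

Two backbones are supported behind one interface. The bundled **small
reference CNN** — two 3×3 convolution blocks of 16 and 32 filters, each
with relu and 2×2 max pooling, then a fully-connected softmax head on
zero-centred inputs — is implemented in pure vectorised R (im2col
convolution) so the full pipeline runs on one CPU with no external
deep-learning runtime. Its width was chosen so the four synthetic classes
are reliably separable at desk scale; the narrower variant first tried
collapsed Other into AF on some seeds while its training loss was still
falling. Alternatively, a **pretrained backbone** can be supplied as a
frozen feature-extractor function; the final three stages (fully-connected
layer, softmax, class decision) are then replaced with a fresh head of the
requested width and only the head is trained. Heavy pretrained backbones
(e.g. a 224×224×3 ResNet101) are deliberately out of scope as artifacts;
the interface is the point.

Ties in the class decision go to the lowest class index. Class imbalance is
not re-weighted by default (a class-weight hook is a possible extension);
whether the original protocol stratified its split is unknown, and exact
per-subset counts under an unknown seed are not reproducible in any case.

## Evaluation

Evaluation reduces the K×K confusion matrix (rows = true) one-vs-rest per
class: Tp the diagonal entry, Fn the row remainder, Fp the column
remainder, Tn the rest. Six metrics are computed per class —

$$\mathrm{Acc} = \frac{Tp+Tn}{Tp+Tn+Fp+Fn},\quad
  \mathrm{Se} = \frac{Tp}{Tp+Fn},\quad
  \mathrm{Sp} = \frac{Tn}{Tn+Fp},$$
$$\mathrm{Pre} = \frac{Tp}{Tp+Fp},\quad
  \mathrm{F1} = \frac{2\,\mathrm{Se}\,\mathrm{Pre}}{\mathrm{Se}+\mathrm{Pre}},\quad
  \mathrm{MCC} = \frac{Tp\,Tn - Fp\,Fn}
  {\sqrt{(Tp+Fp)(Tp+Fn)(Tn+Fp)(Tn+Fn)}}$$

— plus unweighted macro averages. Any metric with a zero denominator is
reported as 0 with an explicit degeneracy flag rather than NaN, keeping
batch evaluation stable. Note that published tables in this area sometimes
list per-class "accuracy" numerically equal to sensitivity — i.e. they
report recall under the accuracy heading; this report emits both `acc`
(one-vs-rest accuracy as printed above) and `se`, so either reading is
checkable. ROC and precision-recall curves sweep every distinct score
threshold with ties grouped; areas are trapezoidal; `recall_at_precision(p)`
returns the maximal recall among thresholds with precision ≥ p (the
PR-curve operating point convention for imbalanced classes). The ROC area
is cross-checked against an independent implementation in the tests.

## The synthetic generator

Real CinC 2017 recordings cannot ship with the package, so every stage is
exercised by a synthetic generator whose presets encode the four classes'
distinguishing physiology:

| preset | RR CV | P wave | fibrillatory band | ectopics | noise |
|---|---|---|---|---|---|
| N | 0.02 | yes | — | — | 0.02 mV |
| A | 0.25 | no | 0.15 mV, 4–10 Hz | — | 0.02 mV |
| O | 0.05 | yes | — | 15% premature, wide/tall | 0.02 mV |
| ~ | 0.10 | faint | — | — | 0.4 mV + 0.8 mV wander |

Beats are five Gaussian bumps (P, Q, R, S, T) at fixed offsets with
amplitudes (0.15, −0.10, 1.0, −0.25, 0.35) mV; RR intervals are
gamma-distributed (shape set by the CV, keeping intervals positive) with
mean 60/HR at 70 bpm; ectopic beats arrive prematurely (preceding RR
shortened to 60%) with a wide, tall, P-free morphology, the premature
ventricular pattern. The fibrillatory amplitude of 0.15 mV — "coarse"
fibrillatory waves, clinically — is calibrated so that AF and Normal
scalograms differ by at least a factor of 2 in time-averaged 4–10 Hz band
energy at matched seeds; that separation is the contract that makes the
end-to-end classifier test meaningful, and it is asserted in the suite. At
0.10 mV the measured ratio falls to 1.5–1.9 and the contract fails, so
0.15 mV is the generator's fixed condition, not a tuning knob.

Durations are drawn uniformly in 9–60 s so the duration filter genuinely
excludes records (roughly 40% at these bounds). Signals are quantised to
the 1e-3 mV grid of the int16 container so written datasets round-trip
bitwise.

What the generator does *not* emulate: realistic PQRST morphology variants,
T-wave memory, respiration-modulated baseline, electrode artifacts,
atrial flutter's sawtooth, or any pathology beyond the four presets.
Passing the end-to-end test therefore shows the pipeline's plumbing,
transforms, training loop and evaluation are correct and that the
classifier can exploit genuine time-frequency class structure — it does
not certify clinical performance on real ECG, which requires the public
accession and a pretrained backbone at full image resolution.

## Problem sizes and determinism

The package's own experiments run at desk scale: the end-to-end synthetic
study uses 200 records (50 per class, of which about 115–120 survive the
duration filter), 64×64 images, and the small CNN, completing in a few
minutes on one CPU; the CWT-vs-integration check uses 256-sample signals;
ridge recovery uses 8 s sinusoids. A single master seed fans out
deterministically (via a Lehmer step) to the synthesis, split,
initialisation and shuffling sub-seeds, so a pipeline rerun with the same
configuration reproduces its split assignments, rendered images and
confusion matrix exactly; training itself is deterministic given the seed
because all arithmetic is sequential CPU floating point.

## Known limitations

- The MAT reader supports the single-variable little-endian v5 layout the
  CinC 2017 distribution uses, not arbitrary MAT files.
- Fourier-domain resampling assumes the segment is long relative to its
  edge effects; it is not suitable for sub-second snippets.
- The small CNN is a reference implementation in interpreted R: adequate
  for hundreds of small images, not for the full 8,528-record study.
- Per-class "accuracy" ambiguity in published tables (see Evaluation) means
  external comparisons should state which definition they quote.
- The cone of influence is reported, not enforced; downstream consumers of
  raw coefficients near record edges must apply their own masking.
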