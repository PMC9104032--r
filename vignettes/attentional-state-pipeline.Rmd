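---
title: "Decoding attentional state from CW-fNIRS: models, parameters, and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding attentional state from CW-fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirstate)
```

This vignette is the package's own account of the science it implements:
the signal model and its assumptions, the parameters that matter, the
numerical choices, the design decisions that were genuinely open, and what
passing the synthetic benchmark does and does not establish about real
recordings.

## The problem

Continuous-wave fNIRS measures light attenuation at two wavelengths
(here 760 and 850 nm) through cortex. During a working-memory task
(2-back), task-positive prefrontal regions (bilateral DLPFC, MFG) show an
oxygenation response — HbO rises, HbR falls — that a classifier can use to
distinguish engagement from relaxation, the basis of a two-state
brain–computer interface. The scientific questions the evaluation layer
answers are: *is a given per-subject accuracy better than a random
classifier could achieve on that many trials*, and *is the group effect
significant under a distribution-free test*.

## Signal model and conversion

The modified Beer–Lambert law relates optical-density change at
wavelength $\lambda$ to chromophore concentration changes along the photon
path:

$$\Delta OD_\lambda(t) = \left(\varepsilon_{HbO,\lambda}\,\Delta HbO(t) +
\varepsilon_{HbR,\lambda}\,\Delta HbR(t)\right)\, d \cdot DPF_\lambda$$

with $d$ the source–detector separation and $DPF$ the differential
pathlength factor. Two wavelengths give a 2×2 linear system per channel
and sample, inverted exactly by `od_to_hemoglobin()`. Assumptions
inherited from CW-fNIRS practice: homogeneous medium (no partial-volume
correction), constant scattering (attenuation changes attributed entirely
to chromophores), and a path-length correction captured by a single DPF.

Numerical conventions, audited by unit tests: extinction coefficients in
cm⁻¹·M⁻¹ (base-10), distances converted mm → cm, concentrations mol/L
internally and µM at every public surface. The bundled extinction table is
the widely used Prahl/Gratzer–Kollias compilation; because every
correctness property of the conversion is a forward/inverse round trip,
results do not depend on which published tabulation is loaded.

The optical-density baseline is the arithmetic mean intensity over the
first 5 s of the record (the estimator is unstated in the source
pipeline's description; the mean is the standard choice, and the window is
configurable). One subtlety is documented by a dedicated test: the mean of
the *intensity* does not commute with the logarithm, so with noisy data
the recovered concentrations equal truth-minus-baseline only to second
order in the noise amplitude; the exact (<1e−9) round-trip guarantee holds
for the noiseless case.

## Preprocessing parameters

| parameter | default | unit | status |
|---|---|---|---|
| OD baseline window | first 5 | s | stated by the protocol |
| epoch offset after marker | 2 | s | stated |
| epoch duration | 8 | s | stated |
| Butterworth order / cutoff | 6 / 0.6 | – / Hz | stated |
| basis σ / spacing | 1 / 1 | s | stated |
| CV folds | 5 | – | stated |
| SVM cost C | 1 | – | unstated; exposed |
| sampling rate (simulator) | 10 | Hz | unstated; typical CW-fNIRS |
| DPF | 6.0 | – | unstated; conventional value |

**Filter placement.** The nominal processing order places temporal
filtering after epoching, but an 8-s window is short for a clean 6th-order
0.6 Hz filter (edge transients eat a large fraction of the window). The
default therefore filters the continuous concentration series and epochs
afterwards; `pipeline_config(filter_stage = "epoch")` selects the literal
order, and both paths are tested. Filtering is zero-phase
(forward–backward), which squares the magnitude response — the
transfer-function test checks the measured gain against
$|H(f)|^2 = (1+(f/0.6)^{12})^{-1}$ accordingly. The implementation pads
each trace by odd reflection about its endpoints (up to 250 samples)
before the forward–backward pass so that startup transients decay inside
the pad; without this, zero-state filtering visibly distorts any trace
whose edges sit away from zero.

**Epoch windows** are half-open $[t_m + 2, t_m + 10)$ s with sample
indices by round-half-even; markers whose window would cross either record
boundary are dropped and counted, never truncated.

## Feature extraction

Each epoch trace is modelled as a linear combination of unit-peak
Gaussians $\exp(-(t-c_k)^2/2\sigma^2)$, $\sigma = 1$ s, centers 1 s apart.
The fitted heights (OLS via QR) are the features. Open choices resolved
here:

- **Center placement.** The count and offset of the bells over the 8-s
  window are unstated; centers at 0.5, 1.5, …, 7.5 s (8 functions) cover
  the window symmetrically with no center outside the data. Both are
  configurable in `build_basis()`.
- **σ = 1 interpreted as 1 second**, consistent with the 1-s spacing
  context.
- **Unit-peak (not unit-area) bells**, so "height of the bell" is the
  regression coefficient itself, in µM.
- **Chromophores.** HbO and HbR are processed separately through the
  conversion but, since a single accuracy per subject is the target, the
  default feature matrix concatenates both (10 channels × 2 chromophores ×
  8 bells = 160 features); `chromophore = "hbo"`/`"hbr"` exposes the
  separate analyses. Short-separation channels measure scalp, not cortex,
  and contribute no features.

## Classification

Per-feature z-scoring uses training-set statistics only — fitted inside
each cross-validation fold and applied unchanged to the fold's test data.
A leakage audit test corrupts test-fold values and asserts the fitted
normalizer and decision rule are bit-identical. The classifier is a
linear-kernel soft-margin SVM (`e1071`, C = 1 by default). Folds are
stratified (with ~21 epochs, unstratified folds can easily be
single-class) and seed-reproducible; the headline accuracy is the mean
over fold accuracies, with the pooled per-epoch accuracy reported
alongside. A decision score of exactly zero deterministically maps to
"relax". One implementation note: libsvm orients its decision values by
order of class appearance in the training data, so the recovered linear
rule is canonicalized to score > 0 ⇔ "nback"; without this, folds whose
first training epoch happens to be "nback" would silently invert.

## Evaluation layer

**Chance bound.** For $n$ trials and $k$ classes the adjusted-Wald
interval around $p_0 = 1/k$ is
$\tilde p \pm z\sqrt{\tilde p(1-\tilde p)/(n+z^2)}$ with
$\tilde p = (np_0 + z^2/2)/(n+z^2)$. For 20 two-class trials at
$\alpha = 0.05$ the upper limit is 70.07%, displayed as 70% (raw value
retained). The bound is strictly decreasing in $n$ and widens as $\alpha$
shrinks; both properties are tested.

**Wilcoxon signed-rank.** Differences from the reference value; zeros
removed before ranking (required to reproduce the published $T$ values);
midranks for ties. The exact two-sided p enumerates all $2^n$ sign
assignments (computed by convolution over doubled ranks, verified against
literal brute force for $n \le 12$); the normal approximation uses the
tie-corrected variance and a 0.5 continuity correction. For the
online-session-vs-70% comparison only the continuity-corrected normal
approximation reproduces the published p = 0.107 (the exact p is 0.102),
so `reproduce_results()` computes and labels both rather than silently
choosing. Tests are two-sided throughout; for the online-vs-50% comparison
the two-sided exact p is 0.078, so the published significance claim for
that comparison corresponds to the one-sided reading — the reproduction
reports the computed values and leaves the interpretation explicit. The
rank-biserial effect size is $r_{rb} = (T^+ - T^-)/(T^+ + T^-)$.

**Below-chance flags** use strict inequality against the upper bound. The
published table flags one calibration value of 82% although 82 > 70, which
would require per-subject trial counts that are not printed; the package
applies a single group bound by default and accepts per-subject counts
where known.

## The synthetic-data generator

The generator's defaults are the study conditions: 10 two-back blocks
(40 s: ten stimuli of a few seconds each) interleaved with 11 relax blocks
(20 s), starting and ending with relax, at 10 Hz — 21 epochs per session,
matching the ~20-trial regime of the chance computation. Per 2-back block
a trial list of 3 targets and 7 non-targets (no lures) is randomized.
Activation is the canonical double-gamma hemodynamic response (peak 6 s,
undershoot 16 s, ratio 1/6), normalized to unit peak and convolved with
the task boxcar, so the amplitude parameter (1 µM default) is the peak HbO
excursion; HbR is a −1/3-scaled copy. Physiological noise per channel and
chromophore: cardiac ~1 Hz (0.2 µM), respiration ~0.25 Hz (0.1 µM), Mayer
waves ~0.1 Hz (0.1 µM), white noise (SD 0.3 µM), optional linear drift
(default 0). Short-separation channels receive noise only.

Each oscillator carries a random-walk phase drift (SD 0.1 rad/sample,
decorrelating over roughly a minute). This is not cosmetic: physiological
rhythms are not phase-stable clocks, and with strictly periodic blocks
(60-s cycle — an integer number of periods of all three default
frequencies) phase-locked sinusoids would be perfectly synchronized with
the class labels, making the "noise" informative. The drift restores the
intended independence between noise and labels.

**What passing the synthetic benchmark shows** — that the implementation
chain is correct end to end: the MBLL inversion is the exact algebraic
inverse of the forward model, the filter realizes its analytic response,
OLS recovers planted heights at the theoretical sampling distribution, the
classifier finds real class structure and finds none when there is none.
**What it does not show** — performance on real recordings. The generator
has no motion artifacts, no optode-coupling drift, no scalp-layer
partial-volume contamination of long channels, identical activation on
every long channel, and Gaussian stationary noise. Real per-subject
accuracies will be lower and more variable than the simulated 95–100%.

## A statistical limitation worth knowing

The adjusted-Wald interval describes the accuracy of a *random classifier*
over $n$ independent trials — a binomial quantity. The fold-mean
cross-validated accuracy of a *trained* classifier on null data is not
that quantity: across simulated null sessions (zero activation) its
distribution is over-dispersed relative to binomial (and with
low-frequency physiological noise, epoch-to-epoch correlation widens it
further), so roughly 1 null session in 7 falls outside the 21-trial
interval even though no information is present. The interval is the
field's standard yardstick for flagging individual results, and the
package implements it as such; but it should not be read as an exact null
acceptance region for cross-validated accuracies. Permutation testing of
the full CV pipeline would be the sharper (and far costlier) null.

## Problem sizes used in the bundled workflow

The analysis scripts simulate 12 subjects × 2 sessions of 620 s at 10 Hz
(21 epochs, 160 features per session); the test suite exercises shorter
3-block sessions for the per-module checks and the full default session
for the end-to-end properties (20 seeds each for the high-SNR and null
conditions). These sizes make the whole workflow run in well under a
minute on a laptop while keeping every statistical check meaningful.
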