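---
title: "Virtual short channels: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual short channels: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vshortr)
```

## The problem

Continuous-wave fNIRS measures changes in detected light intensity between
source-detector pairs on the scalp. Long-separation channels (~30 mm) carry
a mixture of cortical hemodynamics and superficial (scalp/skull) physiology:
cardiac pulsation near 1 Hz, respiration near 0.2-0.3 Hz, Mayer waves near
0.1 Hz and slower systemic fluctuations. Short-separation channels (~8 mm)
sample almost exclusively the superficial layer, and regressing them out of
the long channels — short-channel regression (SCR) — is the standard way to
unmask cortical responses. Many montages, however, have no short channels.

`vshortr` trains a transformer encoder to map windows of long-channel
optical density (OD) at two wavelengths onto the OD of the short channel
paired with each long channel. The predictions are *virtual short channels*:
drop-in SCR regressors when physical ones are absent.

## Model

Each recording is segmented into non-overlapping windows of 128 samples at
7 Hz (~18 s), giving tensors `[windows x 128 x 28]` for the default montage
(14 long channels x 2 wavelengths). Per time step the 28 features are
projected affinely into a 128-dimensional embedding; two identical encoder
blocks follow, each with 4-head self-attention and a 128 -> 256 -> 128
GELU feed-forward, both wrapped in dropout (0.1), a residual addition and
layer normalisation (post-norm); an affine decoder maps back to the 28
short-channel features. About 272k parameters. No positional encoding is
added by default (see "open choices").

Training minimises the hybrid loss

$$ L = \mathrm{MSE}(\hat y, y) + \alpha\,(1 - r(\hat y, y)),\qquad \alpha = 0.3, $$

where the MSE averages over every time point and feature, and the Pearson
term is computed over time separately per (window, feature) and averaged —
the MSE anchors amplitudes while the correlation term preserves temporal
shape. Optimisation uses AdamW (initial learning rate 8e-4, weight decay
1e-4, batch 128, default 180 epochs) with a per-epoch cosine-annealed
learning rate, and the checkpoint with the best validation loss is kept.
Windows are min-max normalised to [-1, 1] with statistics fitted on the
training split only. Inputs and targets are normalised with their own
per-feature statistics: long channels carry roughly three times the
superficial amplitude of the short channels, and normalising targets with
the input statistics would squash them to a third of the range and starve
the MSE term against the correlation term (measured on the default cohort:
validation loss 0.014 vs 0.005, and the downstream SCR residual variance
several-fold worse). The target statistics travel with the model and are
used to map predictions back to OD.

At inference, test-time augmentation averages predictions over five
perturbed copies of each window (Gaussian noise sigma 0.01, temporal jitter
up to 10 samples with edge replication and inverse shifting, amplitude
scaling of 5%, and a baseline offset drawn with sigma 0.01, matched to the
noise sigma since no separate magnitude is established for it).

## What the simulator emulates — and what it does not

Real paired long/short recordings of the kind this method is developed on
are rarely redistributable, so the
package ships a generative stand-in whose defaults define the conditions
used throughout the tests: 6-minute resting recordings at 7 Hz on a
14-long + 8-short montage (760/850 nm), with

* three shared oscillators (cardiac 1 Hz, respiratory 0.25 Hz, Mayer
  0.1 Hz) whose instantaneous frequency wanders inside a bounded random
  walk shared across sites, so long-short coherence is high but below 1;
* a shared broadband pink "systemic" background. Scalp physiology is not a
  line spectrum — blood-pressure and vasomotor variability fill the whole
  low-frequency band — and without this component a whole-band median
  coherence would be dominated by noise-only cells and quality control
  would behave nothing like on real signals;
* spatial heterogeneity: per-site amplitudes and slowly wandering phase
  offsets drawn with correlation `exp(-d / 60 mm)` across optode sites and
  magnitude scaled by `1 - phase_coupling` (default coupling 0.95). A long
  channel and its bundled short channel are near-neighbours and therefore
  receive highly similar superficial series; distant sites decorrelate;
* a cortical component for task runs, injected only into a localised
  subset of long channels (by default the left temporo-parietal quadrant,
  mirroring motor-cortex-focused analyses; a motor response is not a
  global wave, and a global injection would be indistinguishable from
  shared systemic physiology): a 20 s-on/20 s-off boxcar convolved
  with a canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6
  — the community default, as the response shape is not otherwise
  specified), injected through the Beer-Lambert forward model with an
  O2Hb:HHb amplitude ratio of 1 : -1/3 so concentration conversion
  recovers the canonical O2Hb-up / HHb-down pattern;
* spontaneous resting-state cortical hemodynamics: pink-spectrum
  fluctuations in every long channel, correlated within cortical
  neighbourhoods (`exp(-d / 40 mm)`) but absent from the short channels
  and never globally shared.  This is the contrast the whole method rests
  on — a predictor trained on recordings whose long channels contained
  nothing but superficial signal would happily map any long-channel
  content into its short-channel predictions.  Their amplitude (3e-4 mM
  O2Hb, the same order as the task response) follows the standard
  observation that spontaneous low-frequency oscillations are comparable
  to task-evoked responses;
* per-measurement slow drift and white sensor noise; an intensity
  representation `I = exp(-OD)` with baseline 1, which is unidentifiable
  from OD and therefore arbitrary.

Amplitude defaults (cardiac 6e-3, respiratory 5e-3, Mayer 8e-3, background
1e-2, drift 5e-4, noise 5e-4 OD; long channels receive the superficial
signal x3, modelling the longer scalp path) were chosen once so that the
generator's own identities hold crisply — in particular, regressing a long
channel on its paired short channel at full coupling must recover the
non-superficial floor to within 1% of the long-channel variance, which
bounds how much independent drift/noise the short channels may carry. They
are chosen for testability of the pipeline, not as a calibrated match to
any instrument's signal-to-noise ratio.

What passing tests on this simulator do **not** show: robustness to motion
artifacts, optode decoupling, skin-blood-flow transients, anatomical
variability of path length, or any nonlinearity of real scalp optics. The
simulator is a correctness harness, not a claim about hardware.

## Quality control

Long-short pairs are screened by the median magnitude-squared wavelet
coherence (analytic Morlet, centre frequency 6, 12 voices per octave;
cross- and auto-spectra smoothed in time with a scale-proportional Gaussian
of standard deviation 2.8 scale lengths and across two octaves of scales —
spans chosen so that genuinely coupled pairs and independent or noise-only
pairs separate cleanly around the 0.39 retention threshold; cone-of-influence
cells excluded; median
over 0.01-1.5 Hz, the Mayer-to-cardiac range, further restricted to
periods that fit ten times into the record). A long channel is dropped at
both wavelengths when its median coherence with the paired short channel
falls below the threshold (default 0.39) at either wavelength — the model
consumes paired-wavelength features, so rejection keeps the feature map
rectangular. With these smoothing spans the estimator is exactly 1 for
identical signals and its white-noise floor sits near 0.06, far below the
threshold, while well-coupled synthetic pairs sit near 0.98.

## Numerical choices

* **Precision.** Training runs in single precision — the standard
  arithmetic for this model class and about twice as fast on one CPU —
  with AdamW accumulators in double. A double-precision path exists and is
  what the finite-difference gradient checks exercise (agreement to 1e-4
  relative).
* **Resampling.** Native rates such as 8.719 Hz reduce to enormous coprime
  ratios against 7 Hz, so rational polyphase filtering is impractical;
  resampling is a zero-phase Chebyshev-II low-pass (stopband >= 40 dB
  below the new Nyquist, applied forward-backward) followed by cubic
  splines on the uniform target grid. Output length is
  `floor((n-1) * target / native) + 1`.
* **Correlation guard.** The loss adds epsilon = 1e-8 to the correlation
  denominator and treats zero-variance series as r = 0 with zero gradient,
  so flat (e.g. masked or augmented) windows never produce NaN.
* **Degenerate features.** Constant features normalise to 0 and carry a
  `degenerate` flag; undefined metrics (constant reference) are excluded
  from medians and counted, never imputed.
* **Stage order.** SCR operates on OD, then the 3rd-order zero-phase
  Butterworth band-pass (0.01-0.2 Hz), then Beer-Lambert conversion
  (DPF 6, vendored Gratzer/Kollias extinction table, overridable). Each
  series carries a stage tag and the functions refuse a reordered
  pipeline.
* **Block averages.** Epochs span -5 to 30 s around onsets
  (`round(35 * fs) + 1` samples); per-trial baselines are the mean over
  [-5, 0); partial epochs at the edges are dropped, not padded.
* **Divergence guard.** Gradients are clipped at global norm 1 by default
  (disabled in strict mode), and a non-finite loss aborts training with
  the last good checkpoint.

## Open choices made here

* **Positional encoding** is not part of the reference protocol's
  description.
  The default here is none: the long-to-short mapping is time-stationary
  within a window, and on the default cohort adding fixed sinusoids nearly
  tripled the converged validation loss (a position code is information the
  decoder must learn to cancel). `"sinusoidal"` and `"learned"` remain
  available for ablation.
* **Residual order**: post-norm ("add & norm" after each sublayer), the
  reading most consistent with a residual addition followed by
  normalisation; no pre-norm variant is provided.
* **Pearson granularity** in the loss: per (window, feature) over the 128
  time steps, then averaged — matching the per-channel temporal-shape
  motivation of the correlation term.
* **Coherence per wavelength** with joint rejection of both wavelengths,
  rather than a combined-signal coherence.
* **Target layout**: the target matrix duplicates short channels so that
  the output space matches the 28 input features (each long channel's
  column holds its paired short channel); this is why the decoder is
  28-dimensional even though only 16 physical short measurements exist.
* **SCR form**: ordinary least squares with intercept, fitted over the
  full recording per channel and wavelength.
* **Fine-tuning scope** for montage adaptation: encoder core frozen by
  default (`frozen_core = TRUE`), only the enlarged projections update.
* **Sweep protocol**: the threshold sweep retrains at a reduced epoch
  budget (configurable) and masks rejected channels to zero rather than
  dropping columns, keeping one architecture across thresholds.

## Problem sizes used by the tests and the acceptance script

Bookkeeping checks use the full 69-subject cohort geometry (1311 windows).
Parameter recovery trains the default transformer on a 30-subject cohort
for 40 epochs, three seeds; task preservation uses a 4-subject, 10-minute
tapping cohort; the threshold sweep uses 6 subjects with two deliberately
decoupled channels each and 4-epoch retrains. These sizes are the package's
study conditions for automated verification; the full 180-epoch protocol is
the shipped default of `train_config()`.

## Known limitations

The montage is fixed at training time; transfer to other layouts goes
through `adapt_to_montage()` and needs paired data for fine-tuning. The
simulator contains no motion artifacts, so the wavelet motion-correction
question does not arise here (the reference pipeline also omitted it).
Prediction uncertainty is not estimated. Because predictions are made
from long channels that contain the cortical signal, a fraction of a
regionally-correlated task response can be absorbed into the virtual
regressors and then subtracted by SCR; under the synthetic conditions the
grand-average response survives with its sign, latency and deoxygenated
counterpart intact but with part of its amplitude removed (the acceptance
script reports the measured relative error). Training-time augmentation
and the spontaneous-activity contrast in the training data reduce, but do
not eliminate, this absorption. Window-level random splitting
mirrors the original protocol but lets windows of one subject appear in
both train and test sets; `split_windows(by_subject = TRUE)` is the
stricter alternative and is recommended for honest generalisation claims.
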