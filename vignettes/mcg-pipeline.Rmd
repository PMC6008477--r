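---
title: "Mechanocardiography feature extraction and classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanocardiography feature extraction and classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcgpipe)
```

## The signal model

A smartphone lying on the sternum records six inertial axes at a
nominal 200 Hz: three linear accelerations (seismocardiography, SCG)
and three angular rates (gyrocardiography, GCG). The pipeline assumes
the additive decomposition

$$ s(t) = s_h(t) + s_b(t) + n(t), $$

where $s_h$ is the cardiac vibration of interest, $s_b$ the breathing
component and $n$ broadband noise. Conditioning follows that model: a
brick-wall FFT band-pass over 1–40 Hz suppresses $n$ and baseline
wander, and the residual breathing estimate — a moving average under a
unit-sum all-ones window of 50 samples (0.25 s) — is subtracted,
$\hat{s}_h(t) = s(t) - \mathrm{Mean}_{50}(s(t))$.

Each conditioned recording is cut into non-overlapping 10 s episodes
(2000 samples), and each episode into eight 2.5 s sub-segments (500
samples) overlapping by 1.5 s. All features are computed per axis and
per episode; the classifier input is the concatenation over the six
axes.

## Heart-rate estimation

For each sub-segment $u$, the first 1.5 s prefix $u_{1.5}$ is
correlated with the sub-segment,
$R(i) = \sum_j u(j)\, u_{1.5}(j+i)$, keeping only shifted indices
inside the prefix support. Under that index constraint the sum reduces
to the linear autocorrelation of the prefix, which is what the
implementation computes (via FFT convolution; the test suite checks it
against the naive double sum). The inter-beat interval is the lag of
the global maximum of $R$ over lags strictly greater than
$i_0 = F_s/3$ samples, divided by $F_s$. The floor caps detectable
rates below 180 beats/min; the prefix length caps the detectable
interval at just under 1.5 s, i.e. rates above roughly 40 beats/min. A
sub-segment whose admissible correlation never becomes positive (e.g.
a silent axis) yields a missing value rather than a spurious period.
The episode heart rate is $60/\mathrm{median}(RR_{1:8})$.

Two deliberate readings are worth stating. "First side peak" is
implemented as the *global* argmax over admissible lags — the literal
reading of the defining formula — not as the first local maximum. And no
per-sub-segment windowing or normalisation is applied before
correlation; the estimator is scale invariant regardless.

## Rhythm features (18 per axis)

* **HRV indexes.** With $\Delta$ the first-difference operator on the
  valid RR series: $HRV_1 = \mathrm{median}|\Delta RR|$ (the median
  absolute difference), $HRV_2 = \mathrm{median}|\Delta^2 RR|$, and
  $HRV_3 = \mathrm{median}|\Delta|\Delta RR||$. $HRV_1$ is sometimes
  written without the difference operator that the name "median
  absolute difference" implies; the difference-based definition is
  what this package computes.
* **Approximate entropy.** The standard Pincus estimator
  $\Phi_m(r) - \Phi_{m+1}(r)$ with Chebyshev distance and self-matches
  included, $m = 2$ and $r = 0.2\,\mathrm{sd}(x)$ — the literature
  defaults, since several variants of the estimator circulate. It runs on the episode downsampled by 4 (500
  points) to bound the quadratic cost; both parameters and the
  downsampling factor sit in `pipeline_config()`.
* **Spectral entropy.** Single unwindowed periodogram of the episode,
  restricted to 1–11 Hz; bins below $\tfrac16\max P(f)$ are treated as
  noise floor and dropped; the surviving bins are renormalised to a
  probability distribution whose Shannon entropy (natural log) is the
  feature. The unit-sum normalisation makes it amplitude invariant.
* **Turning-point ratios.** $TPR(x) = RD(FIL_m(x))/(N-2)$, where $RD$
  counts strict interior extrema. The 11 filter schemes are a design choice of this
  package: scheme
  1 is the identity and schemes 2–11 are brick-wall bands tiling the
  conditioned spectrum ([1–5], [5–10], …, [35–40], [1–20],
  [20–40] Hz), declared in the configuration so an alternative bank is
  a drop-in. An i.i.d. series has $E[TPR] = 2/3$, which the test suite
  verifies by Monte Carlo. `RRITPR` is the same statistic on the
  (identity-filtered) RR series itself.

## Morphology features (247 per axis)

* **Energy features.** Eleven sub-band energies: band-pass, square,
  mean over the 2000 samples. The filter bank reuses the ten TPR
  bands plus the full 1–40 Hz band; schemes 6–11 are additionally
  rectified and smoothed with a 101-sample triangular kernel before
  averaging, realising the "long triangular smoothing" the method
  requires for some features. The sub-band energy interpretation fixes
  the operator order as filter-then-square. Energies scale with the
  square of signal amplitude — the only place absolute sensor units
  matter, which is why the three-class feature set (which must bridge
  differing hardware gains) excludes them.
* **Uniform 1-D LBP histograms.** Each time index is coded by
  comparing the centre sample against eight neighbours at offsets
  $(-4,-3,-2,-1,+1,+2,+3,+4)\times d$ for spacing $d$, with bit $r$
  set when the neighbour is $\ge$ the centre (so a constant
  neighbourhood codes 255 and a strict local maximum 0). The bits are
  kept in temporal order as the defining equation writes them:
  uniformity — at most two circular bit transitions — is not invariant
  under reordering half the neighbourhood, so the equation's ordering
  is authoritative. Exactly 58 of the 256 codes are uniform; each gets
  its own bin and all others share bin 59. Four histograms per axis:
  spacings 3 and 21 samples, each on the raw signal and on its
  cumulative trapezoidal integral (velocity/displacement indicators).
  Counts are raw (not normalised); classifier-side standardisation
  handles scale. Spacings are sample counts, so their physical extent
  shifts if the sampling rate deviates from 200 Hz.

Per axis: 18 rhythm + 11 energy + 4×59 LBP = 265 features; over six
axes, 1590. The three-class mode drops the energy block (254 per axis,
1524 total). Rhythm features of an axis with no detectable periodicity
are imputed as 0 with a warning — a validity flag is deliberately not
appended, which would silently change the documented 265-feature
layout.

## Classification and evaluation

Evaluation is leave-one-subject-out: every segment of one subject is
held out against models trained on all remaining subjects, which is
what prevents subject leakage at this cohort size. Features are
z-scored with training-fold statistics only. Two classifiers are
provided:

* **Kernel SVM** — RBF kernel, one-vs-one for more than two classes,
  trained by solving the soft-margin dual quadratic program
  (`quadprog`). Defaults $C = 10$, $\gamma = 1/p$. An inner 3-fold
  grid search over $C$ and $\gamma$ is implemented
  (`svm$tune = TRUE`) but off by default: on the synthetic benchmark
  it changes no prediction while multiplying cross-validation runtime
  by the size of the grid.
* **Random forest** — CART/Gini trees in compiled code, 500 trees,
  $mtry = \lfloor\sqrt{p}\rfloor$, grown to purity (minimum node size
  1). Both are deterministic under a fixed seed.

A recording's final label is the modal class of its segment
predictions; ties fall to the larger summed prediction score, then to
the lowest class index — both deterministic. Metrics: accuracy as
trace over total of the confusion matrix; sensitivity/specificity for
two classes with the disease class positive; per-class one-vs-rest F1
and their arithmetic mean. Undefined ratios (empty denominators) are
reported as `NA`, never as 0.

## The synthetic-signal generator

Clinical recordings of this kind are restricted, so the package ships
a simulator that realises exactly the decomposition the features
assume. Per axis, each beat contributes a template of two systolic
Gabor wavelets (carriers near 17 and 12 Hz, widths 45 and 50 ms) and a
smaller diastolic wavelet 0.38 s after onset; six fixed per-axis
gain/frequency/phase variants stand in for sensor orientation, with
the dorso-ventral accelerometer axis strongest. Breathing is a 0.25 Hz
sinusoid (amplitude 0.5 signal units) plus a 10 % amplitude modulation
of the cardiac train; noise is Gaussian (sd 0.1). RR intervals are
log-normal with the configured mean and coefficient of variation,
independent across beats.

Condition phenotypes follow the qualitative clinical picture:
NORMAL has RR CV 0.02 and nominal morphology; AFIB has RR CV 0.25 plus
per-beat log-normal amplitude/width jitter (scale 0.2) — irregular in
rhythm *and* morphology; CAD (pre-PCI) keeps regular rhythm with the
systolic complex scaled to 0.55 amplitude and widened 1.5× (widening
also divides the carrier frequency, i.e. poor contractility and a
broadened, slowed systolic complex); STEMI keeps amplitude 0.75 with
width 2.2×, pushing systolic energy into lower bands. No quantitative
morphology reference exists for the two ischemic classes, so those two
parameter sets are artifact choices — useful for exercising the
pipeline, not claims about pathophysiology. Cohort generation draws
per-subject heart rates uniformly from condition ranges (NORMAL
55–75, AFIB 70–110, CAD 55–80, STEMI 60–95 bpm) and amplitude gains
from 0.7–1.3.

What a green synthetic test establishes, therefore, is that the
*machinery* is correct and that the features separate the statistical
structure they were designed for (rhythm irregularity, morphology
change, energy redistribution). It does not establish clinical
performance: real recordings add motion artifacts, inter-subject
template diversity far beyond six fixed variants, arrhythmias other
than AFib, and demographics confounds — none of which are simulated.
Clinical-grade accuracy claims would require restricted patient data
and are explicitly out of scope.

## Numerical choices and degenerate inputs

* The brick-wall filter is applied to whole recordings, not per
  segment, to keep its ringing away from episode interiors; it is
  idempotent to 1e-9.
* The breathing moving average uses a symmetrised even-length window
  (half weight on the outermost samples) so the estimate is zero-phase
  — a linear ramp maps to zero away from the borders — and is
  border-renormalised by the in-range weight so a constant maps to
  zero everywhere while output length is preserved.
* Episode segmentation drops trailing partial windows; sub-segment
  windows start every 1.0 s, so the final 0.5 s of an episode belongs
  to no sub-segment.
* Silent axes: autocorrelation never positive → missing RR → HR/HRV/
  RRITPR imputed 0 at assembly; an empty analysis band in the
  spectral-entropy step returns 0 with a warning rather than NaN.
* All-zero LBP input is well defined (code 255 everywhere); a signal
  too short for one full neighbourhood yields an all-zero histogram
  with a warning.
* Seeds: every stochastic component (simulator, cohort draws,
  bootstrap, feature subsampling) is driven by explicit integer seeds
  through a save/restore RNG wrapper, so library calls never perturb a
  caller's RNG stream.

## Known limitations

* The RR estimator reports the period of the *dominant* admissible
  autocorrelation peak; at very low rates (near 40 bpm) the admissible
  window can truncate the true period, and for sub-segments containing
  fewer than two beats the estimate is undefined by construction.
* The 11 TPR filter schemes and the energy filter bank are this
  package's own tiling of the conditioned spectrum; results depend on
  that choice, which is why both banks are configuration fields.
* LBP spacings are sample counts; at sampling rates other than 200 Hz
  their temporal extent changes.
* The kernel-SVM dual solver is dense and O(n³)-ish; it is intended
  for cohort-scale problems (hundreds of segments), not for thousands.
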