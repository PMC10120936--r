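---
title: "Quantifying vocal fold recovery: acoustic squeal analysis and fiber directionality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vocal fold recovery: acoustic squeal analysis and fiber directionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squealfiber)
```

## The problem

After laryngeal surgery — here, implantation of an engineered outer vocal
fold replacement in a voicing pig model — functional recovery must be
assessed objectively. Standard human voice measures (jitter, cepstral peak
prominence) assume harmonic, neurally regulated phonation and are unusable
for pig calls, which are nonlinear and chaotic. This package implements two
complementary quantitative readouts:

1. **Acoustic**: spontaneous high-pitched vocalizations ("squeals", the
   call type presumed to originate at the vocal folds) are segmented from
   long cage recordings, summarized by six voice parameters, screened for
   pre/post-surgery discriminability, and tested longitudinally.
2. **Structural**: collagen (second-harmonic generation) and elastin
   (autofluorescence) channels of lamina propria mosaics are reduced to an
   orientation histogram per channel, from which fiber alignment,
   dispersion, and fit quality are extracted, together with the
   collagen–elastin alignment difference.

Raw recordings and slides are not redistributable, so seeded synthetic
generators (`generate_cohort()`, `generate_fiber_phantom()`) emulate the
analysis-relevant structure of both data streams with known ground truth.

## Acoustic pipeline

### Segmentation

Recordings are 16-bit PCM, 44.1 kHz, collapsed to mono (channel mean by
default). `segment_events()` marks maximal runs where a moving-average
volume trace exceeds a threshold of 500 on the raw amplitude scale. The
"volume" statistic is the mean absolute amplitude over a centered window
(RMS available behind `method = "rms"`); the window length is not dictated
by the source procedure, and defaults to 100 ms — short enough not to smear
the sharp squeal onset, long enough to bridge single glottal cycles. Runs
separated by less than 200 ms are merged so amplitude dips inside one call
do not split it. Candidates of at least 0.5 s (inclusive) validate as
squeals. Event refinement to onset/offset inflection is a human labeling
task; label tables are an input (`load_labels()`), and segmentation
provides candidates.

### The six voice parameters

All parameters are computed per event under one `feature_config()`:

| Parameter | Definition | Expected post-surgery change |
|---|---|---|
| Q50 | frequency splitting the whole-event energy spectrum into equal-energy halves (linear interpolation in the crossing bin) | down (loss of high frequencies) |
| Flux1 | mean over neighboring frames of the mean absolute difference of unit-total-energy spectra | up (instability) |
| Flux2 | RMS Euclidean distance between consecutive unit-norm magnitude spectra | up |
| Spread | energy-weighted SD of Mel band centers about the spectral centroid | (not significant in practice) |
| P60 | first Mel band center at which cumulative energy reaches 60 % | down |
| LPC8 | 8th of 16 autocorrelation-method (Levinson–Durbin) linear-prediction coefficients, predictor sign convention | up, toward zero from negative |

Framing for the flux measures is 1024 samples (~23 ms) with 50 % hop and a
Hann window — standard bioacoustic resolution; the whole-event spectrum
(zero-padded to a power of two) feeds Q50 and the Mel features, matching
the definitions "of the event". The Mel filterbank uses 64 triangular
bands from 50 Hz to Nyquist with the HTK Mel formula; band centers are
carried in Hz. Per-frame normalization before flux differencing is the
default so flux reflects spectral *shape* change rather than loudness
drift; it is exposed in the configuration because the original flux
algorithms live in external code not reproduced in the source material.
Spread is the weighted standard deviation; a weighted
mean-absolute-deviation variant sits behind `spread_type = "mad"`.

Q50, P60 and Spread are invariant to global amplitude scaling, as are the
flux measures under per-frame normalization — properties the test suite
checks directly.

### Feature screening and redundancy

`gaussian_overlap()` fits a Gaussian to each group by sample moments and
computes the overlapping coefficient ∫ min(f_pre, f_post): the
equal-variance case uses the closed form 2Φ(−|Δμ|/2σ), otherwise adaptive
quadrature over the union of μ ± 8σ envelopes (error < 1e−8). Features are
ranked ascending by overlap (`rank_features()`); selection is by count or
overlap ceiling — the original 107 → 36 screening threshold is not
published, so no constant is hardcoded. Redundancy among retained features
is the bias-corrected (U-centered) distance correlation of Székely–Rizzo,
implemented from the definition; negatives are reported, not clipped.

### Longitudinal testing

Recording dates contribute very unequal squeal counts, so
`balanced_sample()` draws an equal number per date (default: the minimum
per-date count, the largest balanced sample) inside each phase window:
PRE = [−33, −1], POST_EARLY = [0, 14], POST_MID = [50, 100],
POST_LATE = [150, ∞) days from surgery. `compare_phases()` then runs a
one-sided Wilcoxon rank-sum test — exact by enumeration when the pooled
sample is ≤ 16 and tie-free, otherwise the normal approximation with tie
and continuity corrections — in the feature's expected *worsening*
direction for PRE vs POST_EARLY, and in the inverted *improvement*
direction when later windows are compared against POST_EARLY. Bonferroni
correction uses family size 2 (the Q50/Flux1 pair) or 36 (the screened
feature family), chosen over FDR deliberately: p-values cannot be computed
for every screened feature because a test direction cannot always be
assigned, and Bonferroni only needs the family size.

**A calibration caveat.** The rank-sum test's null hypothesis is
exchangeability. When squeals cluster within recording dates (a per-date
random intercept), both phases can have identical marginal distributions
while the test still over-rejects — we measure ~10 % at a corrected 5 %
with a date intercept of 0.3 SD. Balanced sampling equalizes date
*representation* but cannot remove date *correlation*. The type-I-error
property is therefore verified on exchangeable null cohorts
(`generate_feature_cohort(effect_size = 0, date_sd = 0)`), and results on
strongly date-clustered data should be read as descriptive.

## Fiber directionality pipeline

Each channel passes through: median filter (2-px radius, exact truncated
windows), intensity normalization (99.5th percentile to full scale — the
reference statistic of the original normalization is unpublished, so a
robust percentile is the declared choice), an optional 4 % saturated-pixel
stretch for dim control mosaics, Otsu thresholding on a 256-level
histogram *ignoring zero pixels* (the empty mosaic background), removal of
8-connected components under 50 µm² (inclusive at the boundary; pixel size
metadata is mandatory), and mean filtering (3-px radius) of the
particle-cleaned grayscale image. Filter "widths" are read in the ImageJ
radius convention, (2r+1)² windows, and are configurable because the
original wording is ambiguous.

### Orientation voting

Per-pixel structure orientation is the local intensity gradient direction
rotated by 90° and folded into [0°, 180°). Two numerical choices matter
here and were made after phantom calibration:

- **Gradient estimator.** The default is a derivative-of-Gaussian filter
  pair (σ = 1.5 px) rather than the classic Sobel 3×3 stencil (still
  available via `gradient = "sobel"`). On structures a few pixels wide the
  3×3 stencil quantizes orientations toward multiples of 45°, producing
  spurious histogram spikes; the Gaussian derivative estimates angle
  continuously.
- **Vote gating.** A pixel votes only if its gradient magnitude is at
  least 20 % of the image maximum *and* its structure-tensor coherence is
  at least 0.9. Fiber ends, crossings and mask corners mix orientations in
  a neighbourhood; without the coherence gate these pixels add a
  peak-shaped contamination that inflates fitted dispersion by 10–20 %
  relative on phantoms.

Masked, defined orientations are tallied into 2° bins over [0°, 180°)
(the histogram granularity of the original figures).

### The two-pass normal fit

`fit_normal()` fits counts with a wrapped Gaussian (periodic images at
±180 k, k ≤ 2) plus a constant baseline — real histograms have an
isotropic floor — by Levenberg–Marquardt with multi-start width
initialization. The first pass locates the peak (alignment); the
histogram is then rotated so the peak sits at 0° and re-fitted, which
keeps wrap-around mass attached to the peak and avoids artifacts far from
it. Dispersion is the second-pass σ in degrees; GoF is the second fit's
coefficient of determination clamped to [0, 1]. The wrapped model (rather
than a nearest-wrap Gaussian) is what makes broad distributions
(σ ≈ 40°) recoverable at all. `alignment_difference()` is the circular
distance between channel alignments on the 180°-periodic domain, in
[0°, 90°].

## The synthetic generators

### Squeals

`generate_squeal()` builds a harmonic stack with a slowly drifting
fundamental (default 1–2.2 kHz), per-harmonic amplitudes following a
spectral tilt in dB/octave, per-frame (10 ms) multiplicative log-normal
jitter per harmonic, a 5 ms onset ramp, exponential-then-linear decay, and
a white noise floor, peak-normalized on the 16-bit scale. The defaults
encode the study conditions qualitatively: pre-surgery voice at
−3 dB/octave tilt, 0.05 jitter, −30 dB noise; early post-surgery voice at
−12 dB/octave (the dramatic high-frequency loss), 0.8 jitter and −15 dB
noise. These effect sizes are free parameters of the emulation — the
source reports no quantitative spectral model — chosen once so that the
expected direction pattern (Q50↓, Flux1↑, Flux2↑, P60↓, LPC8↑ toward zero)
is produced with clear margins, not to match any published magnitudes.
LPC8's shift is induced through envelope flattening rather than explicit
formant control, an acknowledged approximation. Chaotic phonation is
approximated by the jitter and noise knobs only; passing tests show the
*pipeline* behaves correctly on signals with these statistics, not that
the generator is a realistic pig.

`generate_cohort()` arranges squeals into per-day recordings (0.3 s
silence gaps) across pigs and session days, with per-date random tilt and
jitter offsets emulating the strong between-session variability of
spontaneous phonation, and a recovery model (none/linear/logistic)
interpolating generation parameters from the post-surgery voice back
toward the pre-surgery voice over 150 days. `generate_feature_cohort()`
is the fast feature-level surrogate used for calibration studies that
need hundreds of replicates.

### Fiber phantoms

`generate_fiber_phantom()` renders anti-aliased line segments (Gaussian
cross-profile, default 2 µm wide, ~30 µm long — note single-fiber area
stays above the 50 µm² particle threshold) at 0.5 µm/px in a 560-px
field, 400 fibers per channel, plus folded-normal background noise and
optional sub-threshold specks for exercising the particle filter. Fiber
angles follow a wrapped normal on the axial domain by default: the
dispersion estimator *is* the σ of a fitted wrapped normal, so the
programmed SD is exactly the estimand and recovery error measures the
pipeline alone. A 180°-periodic von Mises option is provided, with the
concentration solved exactly from the target circular SD (Bessel-function
inversion, valid at any width — the common small-angle approximation
κ = 1/(2σ_rad)² is ~25 % off at σ = 40°). The elastin channel's mean
orientation is offset from collagen's by a programmable angle, the ground
truth for the alignment-difference readout.

Density matters: at high fiber coverage, near-parallel fibers merge and
crossings multiply, broadening the vote distribution beyond the programmed
angular SD. The defaults (~30 % coverage) balance that bias against the
angular sampling noise of a finite fiber count.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: cohorts of 2 pigs × 6
days × 12 squeals (0.7 s each) for end-to-end checks; 300 exchangeable
null replicates for calibration (the rejection-rate bound uses the
matching binomial standard error); a 20-phantom grid crossing angular SD
{5°, 10°, 20°, 40°} with channel offsets {0°, 4°, 8°}; and an AR(2)
series of length 10⁵ for LPC recovery. These sizes were chosen so the
whole suite runs in minutes while every statistical bound retains its
meaning at the stated replicate count.

Degenerate inputs are errors, not silent results: zero-energy spectra
(quantiles undefined), constant signals (singular autocorrelation),
constant vectors (distance correlation undefined), zero-variance groups
(overlap undefined), flat images (no orientations), near-empty histograms
(no fit). Ties in the Wilcoxon test switch to midranks plus the corrected
normal approximation. The boundary cases are inclusive by declared
convention: 0.5 s validates as a squeal, a 50 µm² component is retained.

## Known limitations

- Squeal labels are treated as ground truth; rater variability and the
  onset/offset refinement of real labeling are out of scope.
- The flux measures are declared interpretations of two unpublished
  implementations; the configuration exposes the normalization and
  distance choices.
- Rank tests on date-clustered data over-reject (see the calibration
  caveat); a hierarchical model is out of scope by design, since the
  source analysis treats each subject as its own control.
- Phantom realism is limited to straight fibers with a common width
  distribution; curvature, variable thickness and depth effects of real
  mosaics are not emulated, so phantom recovery quantifies estimator
  behavior, not biological accuracy.
- Dispersion carries a residual positive bias of a few percent from fiber
  interactions at realistic densities; it is well below the 10 % recovery
  tolerance at the default settings but grows with coverage.
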