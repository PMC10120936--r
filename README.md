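# squealfiber

Quantitative assessment of vocal fold recovery after laryngeal surgery in
a voicing animal model, from two complementary data streams:

- **Bioacoustics.** Spontaneous high-pitched pig vocalizations (*squeals*,
  the call type presumed to originate at the vocal folds) are segmented
  from long cage recordings by a moving-average volume rule, summarized by
  six voice parameters, screened by the overlap of pre/post-surgery
  Gaussian fits, checked for redundancy with bias-corrected distance
  correlation, and tested longitudinally with date-balanced one-sided
  Wilcoxon rank-sum tests under Bonferroni control.
- **Fiber microscopy.** Collagen (second-harmonic generation) and elastin
  (autofluorescence) mosaics of the vocal fold lamina propria are reduced
  to per-pixel orientation histograms (median filter → normalization →
  Otsu mask ignoring black → 50 µm² particle removal → mean filter → local
  gradient orientation), from which a two-pass wrapped-normal fit extracts
  fiber **alignment** (peak position), **dispersion** (fitted σ, degrees)
  and **GoF** (R² in [0, 1]), plus the collagen–elastin **alignment
  difference** on the 180°-periodic domain.

Because standard human voice measures (jitter, cepstral peak prominence)
assume harmonic phonation, they fail on pig calls; the six parameters used
here are:

| | |
|---|---|
| Q50 | frequency dividing the event's energy spectrum into equal-energy halves |
| Flux1 | mean absolute difference between neighboring normalized frame spectra |
| Flux2 | RMS distance between consecutive unit-norm magnitude spectra |
| Spread | energy-weighted SD of Mel components about the spectral centroid |
| P60 | Mel frequency at which 60 % of cumulative energy is reached |
| LPC8 | 8th of 16 linear-prediction coefficients (vocal-tract sensitive) |

Raw recordings and slides are not redistributable, so seeded generators
(`generate_cohort()`, `generate_fiber_phantom()`) produce labeled squeal
cohorts and two-channel fiber phantoms with known ground truth; every
pipeline stage is tested against them and against independent brute-force
oracles.

## Worked example

```r
library(squealfiber)

# a one-pig synthetic cohort: 2 pre-surgery and 2 early post-surgery days
coh <- generate_cohort(cohort_spec(pig_ids = "pig_a",
                                   recording_days = c(-14, -7, 1, 8),
                                   squeals_per_day = 8), seed = 101)
ft <- cohort_feature_table(coh)
aggregate(cbind(q50, flux2, p60, lpc8) ~ phase, ft, mean)
#>        phase      q50 flux2      p60   lpc8
#> 1 POST_EARLY 1686.944 0.565 1716.073 -0.044
#> 2        PRE 5332.892 0.436 7011.981 -0.172

compare_phases_family(ft, c("q50", "flux1"), "PRE", "POST_EARLY",
                      family_size = 2, seed = 1)
#>   feature n_a n_b direction  p_one_sided  p_corrected significant
#> 1     q50  16  16 a_greater 7.724551e-07 1.544910e-06        TRUE
#> 2   flux1  16  16    a_less 3.337047e-06 6.674095e-06        TRUE
```

The post-surgery voice loses high-frequency energy (Q50 falls from ~5.3 kHz
to ~1.7 kHz, P60 likewise) and becomes less stable (Flux2 rises); LPC8
moves toward zero. Both evaluation-A parameters change significantly after
Bonferroni correction for the family of two tests, in the expected
directions (`a_greater`: pre stochastically greater).

```r
# a two-channel fiber phantom: angular SD 20 deg, elastin offset 5 deg
ph <- generate_fiber_phantom(fiber_phantom_spec(angular_sd_deg = 20,
                                                channel_offset_deg = 5),
                             seed = 1)
analyze_sample(ph$collagen, ph$elastin, ph$pixel_size_um)$summary
#>   sample_id alignment_difference_deg gof_collagen gof_elastin
#> 1    sample                     2.55        0.939       0.959
#>   dispersion_collagen dispersion_elastin
#> 1                17.4               18.8
```

The programmed 5° collagen–elastin offset is recovered within tolerance
(2.55°), dispersions track the programmed 20° width, and the fit quality
is high — the Table-style output (alignment difference, per-channel GoF
and dispersion) that the imaging arm produces for real mosaics.

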