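---
title: "Benchmarking full-reference IQA metrics on CT images: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking full-reference IQA metrics on CT images: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ctfriqa` reproduces, end to end and on purely synthetic data, the study
design used to ask whether full-reference image quality assessment
(FR-IQA) metrics developed for natural images are applicable to CT: six
reference slices (two each of head, chest, abdomen) are degraded with a
5 x 5 grid of Gaussian noise and Gaussian blur intensities applied singly
and in combination (35 conditions per reference, 210 distorted images),
nine FR-IQA metrics score every (reference, distorted) pair, a
six-member observer panel rates every pair on the DSCQS 0-100 scale, and
the metric scores are benchmarked against the subjective scores with
nonlinearity-corrected PLCC, SROCC, RMSE and pairwise residual F-tests.
Because clinical images and human raters are replaced by a phantom
generator and a stochastic observer model, every stage is deterministic
given a seed and testable in CI.

## Display conversion and cropping

CT images are stored as unsigned 16-bit values with `stored = HU +
hu_offset` (default offset 32768, the convention of unsigned-PNG CT
exports; 0 for data already stored as raw counts — the offset is not
recoverable from the file, so it is explicit configuration).
`window_to_display()` maps Hounsfield units linearly onto 8 displayed
bits: with window width `W` and level `L` (defaults 80/40 head,
1500/−650 chest, 350/40 abdomen), `v = 255 (HU − (L − W/2)) / W`,
clipped and rounded half-up. Half-up rounding is chosen over banker's
rounding because it is what display pipelines implement and it makes the
midpoint deterministic (`HU = L` gives 128). All distortion and metric
computation operates on these 8-bit display images, mirroring a workflow
in which degradations were applied to windowed images in an image
editor.

The reference study cropped away diagnostically empty background by
hand; reproducibility requires a rule, so `crop_background()` thresholds
the display image (default 10 of 255), applies a 3x3 morphological
closing, keeps the largest 8-connected component, and takes its bounding
box plus a margin (default 2 px). The resulting half-open box is
recorded so the identical box can be applied to the distorted partner;
an image with no foreground is returned whole with a warning flag
rather than failing.

## Distortion model

Noise is i.i.d. zero-mean Gaussian with standard deviation sigma_noise
in 8-bit gray levels (grid 6, 9, 14, 21, 30), added in floating point
then clipped to [0, 255] and rounded; blur is convolution with a
normalized Gaussian of standard deviation sigma_blur pixels (grid 0.6,
0.9, 1.4, 2.1, 3.0), truncated at radius `ceiling(4 sigma)` with
reflect borders. The sigma grids are interpreted in display gray levels
and pixels of the windowed image (not HU), matching distortion applied
after display conversion. When both distortions combine, blur is
applied first: system blur precedes detector noise in an acquisition
chain. The alternative order is exposed as configuration
(`distortion_order`) since an image-editor workflow does not pin it
down. Per-pair noise seeds derive deterministically from `(base_seed,
source_id, sigma_noise, sigma_blur)`, so a study regenerates
bit-identically and changing the base seed changes only the noise
realizations, never the blur.

## The nine metrics

All nine metrics are implemented in this package from their published
formulations, with parameters set to the originally recommended values
and every constant surfaced as an argument. Unbounded dB metrics (PSNR,
NQM, VSNR) are capped at 100 dB with an explicit flag when the
distortion is zero or imperceptible, because the downstream logistic
regression needs finite values.

* **PSNR** — `10 log10(255^2 / MSE)`.
* **SSIM** — 11x11 Gaussian window (sigma 1.5), `K1 = 0.01`,
  `K2 = 0.03`, `L = 255`, mean pooling over the valid region.
* **MS-SSIM** — five dyadic scales (2x2 mean-filter downsampling),
  canonical exponents (0.0448, 0.2856, 0.3001, 0.2363, 0.1333);
  contrast/structure at every scale, luminance at the coarsest. Images
  too small for five scales reduce the scale count automatically
  (minimum size `11 * 2^(levels-1)`) and renormalize the exponents.
* **IW-SSIM** — the MS-SSIM maps pooled with information-content
  weights. At each scale, 3x3 local statistics of the two images feed a
  bivariate Gaussian model observed through additive noise of variance
  0.4; the weight of a neighborhood is the mutual information between
  the two noisy observations, `0.5 log2[(sx + C)(sy + C) / ((sx + C)(sy
  + C) − sxy^2)]`. The weights vanish on flat background and
  concentrate on shared structure. (The original formulation computes
  closely related weights on a Laplacian pyramid; computing them
  directly on the dyadic pyramid levels keeps the pooling exactly
  aligned with the MS-SSIM maps, and uniform weights reproduce MS-SSIM
  identically, a degeneracy the tests assert.)
* **FSIM** — phase congruency from a log-Gabor bank (4 scales, 4
  orientations, minimum wavelength 6, multiplier 2, sigmaOnf 0.55)
  combined with Scharr gradient magnitude via the standard similarity
  law (`T1 = 0.85`, `T2 = 160`), pooled with the pointwise maximum
  phase congruency. The phase-congruency noise-energy threshold
  defaults to zero (no adaptive noise estimation), a simplification
  that keeps the map deterministic; it affects absolute PC values, not
  the similarity's ordering behavior on this study's distortions.
* **IFC / VIF** — a Gaussian scale-mixture channel model `D = g C + V`
  estimated from 3x3 local moments of multi-scale subband pairs
  (4-level separable Haar decomposition by default; a pixel-domain
  Gaussian pyramid variant is available for VIF). IFC sums the
  source/distorted mutual information over bands; VIF normalizes the
  distorted-channel information by the reference information under
  additive model noise of variance 2, so identical images give exactly
  1. The original IFC/VIF use a steerable pyramid; a separable wavelet
  is used here because the study's distortions are isotropic and the
  information measures depend on local second moments, not orientation
  selectivity.
* **NQM** — both images are model-restored by weighting their spectra
  with the Mannos–Sakrison contrast sensitivity function at the
  configured viewing geometry (default: the image subtends 4 degrees),
  and the score is the SNR in dB between the restored signals. This
  captures NQM's core idea — judge the degradation after a
  human-visual-system restoration model — without the original's
  masking stages.
* **VSNR** — the error signal in display luminance (`(b + k v)^gamma`
  display model) is split into octave bands by a separable Haar DWT;
  per-band RMS contrasts are compared against detection thresholds from
  the CSF scaled to a peak sensitivity of 150. Wholly sub-threshold
  distortion is imperceptible (capped); otherwise the score combines
  the visible perceived contrast `d_pc` with a global-precedence
  disruption term `d_gp` (distance of the visible band-contrast vector
  from a coarse-favoring allocation of the same total contrast), as
  `VSNR = 20 log10(C(I) / (alpha d_pc + (1 − alpha) d_gp / sqrt(2)))`
  with `alpha = 0.04`. Viewing parameters (48 pixels/degree) are
  configuration, since viewing distance in the emulated study was
  explicitly arbitrary.

## Synthetic phantoms and the observer model

`make_phantom()` draws a deterministic site-specific slice: a body
ellipse with a visible skin/muscle rim and, per site, a skull ring with
brain parenchyma and ventricles; two low-attenuation lung fields with
vessel-like puncta, heart and spine; or liver, kidneys, aorta, bowel
gas, fat and spine. Values are plausible HU with smooth Gaussian
texture; pixels outside the body are stored as 0 (out-of-scan-field
padding) so any clinical window displays them as black, which is what
makes the automatic crop exact (its box equals the body-mask bounding
box, asserted in tests). What the phantoms deliberately do *not* model:
reconstruction-kernel noise correlation, streaks and beam hardening,
partial-volume edges, or anatomical variability. Conclusions from
passing tests are therefore about the pipeline's correctness and the
metrics' ordinal response to noise/blur on CT-like structure, not about
clinical image statistics.

The observer model gives each distortion condition a latent quality

> `Q = floor + (100 − floor) exp(−(sigma_noise/tau_noise + sigma_blur/tau_blur))`

with defaults `floor = 30`, `tau_noise = 12` gray levels, `tau_blur =
1.2` px — a decay to a plateau that reproduces the qualitative shape of
the reference study's single-distortion curves: scores fall
monotonically and the *rate* of decrease (decrement per unit sigma)
declines toward the plateau. Note that because the intensity grids are
unevenly spaced, the raw grade-to-grade decrements need not shrink
monotonically even though the rate does; the package's replication
check is therefore phrased on the per-unit-sigma rate. Noise and blur
act additively in the exponent — the simplest form consistent with
single-factor curves; an interaction is deliberately not modeled.

Each observer `o` draws a session bias `b_o ~ N(0, bias_sd = 5)` added
to both marks of a pair, and each mark gets independent noise `N(0,
mark_sd)`; marks are clipped to the bounded 0-100 scale and
presentation order is randomized per observer. The default `mark_sd =
5.7` is the value `calibrate_mark_noise()` finds when targeting the
reference study's observed inter-rater agreement, ICC(2,1) = 0.68, on
the default 210-condition grid (bisection on `mark_sd`, which is
monotone in agreement). Because the DSCQS score is a within-observer
difference, the session bias cancels from difference scores; agreement
is therefore controlled by `mark_sd` against the spread of `Q`, and
ICC on raw marks (where bias does not cancel) is available as a config
switch.

## DSCQS scoring and agreement

Per pair and observer the quality difference is `mark_ref −
mark_dist`; the DSCQS score is the panel mean difference and the
subjective score is `X = 100 − DSCQS`, not clipped. ICC(2,1) — two-way
random effects, absolute agreement, single measure — is computed from
the ANOVA mean squares with the F-based McGraw–Wong 95% interval. The
ratings matrix defaults to per-observer subjective scores (`100 −
difference`) rather than raw marks, because agreement in a DSCQS study
concerns the perceived quality *difference*; the raw-mark variant is a
switch.

## Evaluation harness

Before PLCC and RMSE, each metric's raw scores `Y` are passed through
the five-parameter logistic

> `Y_L = b1 (1/2 − 1/(1 + exp(b2 (Y − b3)))) + b4 Y + b5`

fitted by least squares against `X`. Initialization: `b3 = median(Y)`,
`b1 = range(X) sign(cor(X, Y))`, `b2 = 2/sd(Y)`, `b4 = 0`, `b5 =
mean(X)`; a pure linear start and 16 jittered restarts are fallbacks,
and the returned solution is never worse than ordinary linear
regression (the linear model is nested at `b1 = 0`), so the corrected
PLCC cannot drop below the raw |PLCC| — a property the tests assert
numerically. SROCC is computed on raw scores as Pearson correlation of
mid-ranks (tie-corrected; capped metrics produce ties, where the
classical `1 − 6 Σd²/n(n²−1)` form would be biased — the two agree to
1e-12 on tie-free data). The residual F-test compares mean-centered
residual variances on `(n−1, n−1)` degrees of freedom, one-tailed at
5%, and the pairwise matrices concatenate one symbol (`1`/`-`/`0`) per
subgroup: overall, `[noise, blur]`, `[head, chest, abdomen]`. Each
subgroup is refitted separately (whether the reference study refitted
per subgroup is unstated; refitting is the defensible default because
the nonlinearity differs per distortion type, and a global-fit switch
would be trivial to add). No multiple-comparison correction is applied,
matching the emulated analysis; subgroups under 8 points are skipped
with a warning rather than fitted.

## Problem sizes, numerics, reproducibility

The package's default study scale is 256 x 256 phantoms, which is what
`scripts/acceptance.R` and the acceptance tests run for the end-to-end
correlation check; the clinical matrix is 512, `make_phantom()`
defaults to 512 when called directly, and the study size is plain
configuration. One full 210-pair study with all nine metrics takes on
the order of a few minutes at 256 and roughly quadruples at 512. Numerical choices worth
knowing: all filtering is separable correlation with reflect padding
(valid-region statistics for SSIM-family windows); 8-bit conversions
round half away from zero; the 5PL optimizer runs Levenberg–Marquardt
with `ftol = ptol = 1e-12` and up to 5000 evaluations; capped metric
values carry a `capped` attribute and never reach the tables as
NaN/Inf. Every source of randomness flows from one base seed through a
deterministic child-seed hash (`base`, stage label, tokens), so stages
are independently reproducible and observer-model changes cannot
perturb image generation.

## Known limitations

The phantom generator's contrast statistics differ across sites more
strongly than typical clinical slices (the abdomen phantom is
low-contrast), which depresses pooled rank correlations for metrics
whose absolute scale depends on reference contrast (VSNR in
particular). The NQM and VSNR implementations capture the restoration
and visibility cores of their originals but omit masking and the
original psychophysically fitted threshold model, respectively; their
scores correlate with panel scores somewhat more weakly than the
published implementations do on clinical data. The observer model's
panel noise imposes a ceiling on any metric's achievable SROCC (about
0.9 on the default grid at ICC 0.68): ordering claims at this agreement
level should be read against that ceiling, not against 1.
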