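---
title: "Task-specific image quality assessment for accelerated brain MRI"
author: "csIQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-specific image quality assessment for accelerated brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csIQA)
```

## The question the package addresses

Full-reference image quality metrics (IQMs) such as RMSE, SSIM, FSIM, NQM
and VIF are routinely used as surrogates for radiologist opinion when MRI
acquisition or reconstruction methods are compared. Whether such a surrogate
is trustworthy depends on the diagnostic task: a level of undersampling
artifact that masks diffuse, low-contrast chronic white-matter lesions may
leave a focal, high-contrast acute stroke lesion perfectly legible —
especially when the reader also has an undegraded diffusion-weighted series
available. csIQA provides the full computational chain needed to study this
question: retrospective Cartesian undersampling, compressed-sensing (CS)
reconstruction, a five-metric IQM battery, inter-rater agreement and
confidence statistics, and subjective–objective regression — together with a
synthetic phantom and simulated-observer study generator, because clinical
rating studies of this kind cannot usually share their images.

## The simulation model

### Phantom

`generatePhantom()` builds a deliberately minimal brain-like slice stack: a
superellipse head with a smooth multiplicative bias field and fine tissue
texture, dark lateral ventricles, a bright scalp rim, and two lesion
systems:

* **chronic** periventricular hyperintensities whose footprint grows
  strictly with an ordinal burden grade 0–3 (0 absent; 1 punctate caps;
  2 caps plus a thin halo; 3 confluent extension into deep white matter),
  at low added contrast (+0.09 over a white-matter level of 0.5);
* an optional **acute** lesion: one compact Gaussian blob in lateral white
  matter at more than twice the chronic contrast (+0.20).

This is not MR physics — no relaxation, coils, or distortion — it is the
minimal geometry that reproduces the focal/high-contrast versus
diffuse/low-contrast distinction between the two diagnostic targets.
`simulateKspace()` takes the unnormalized centered 2D DFT per slice (the DC
sample equals the summed intensity) and adds independent complex Gaussian
noise; the default study uses an image-domain noise s.d. of 0.01 (2% of
white matter).

### Undersampling and reconstruction

`variableDensityPdf()` implements the classic variable-density Cartesian
scheme: the central eighth of phase-encode lines is always fully sampled and
the density decays as \((1-|r|)^p\) with \(p = 7\) by default, with an
additive offset solved by root bisection so the expected line count equals
\(n_{PE}/R\) exactly. `drawMask()` draws Bernoulli masks (up to 100
attempts), keeps those whose realized \(R\) is within 5% of nominal, and
returns the one with the smallest peak point-spread-function sidelobe —
masks are deterministic given the seed, and the half-sample grid-center
convention is fixed so they are reproducible bit-exactly.

`csReconstruct()` solves

\[
\hat{x} = \arg\min_x \tfrac12 \lVert M F x - y \rVert_2^2
          + \lambda \lVert \Psi x \rVert_1 ,
\qquad \lambda = 0.01,
\]

with \(F\) the unitary centered 2D DFT and \(\Psi\) a unitary periodic
Daubechies-4 wavelet (4 levels), by monotone FISTA with unit step — both
operators are unitary, so the gradient Lipschitz constant is exactly 1 and
no step search is needed, which also makes the non-increasing objective
trace an exact invariant rather than an approximate one. Iterations run in
the complex domain; magnitude is taken only from the final iterate. The
solver's own defaults stop at a relative objective change of \(10^{-6}\) or
200 iterations; the study generator uses 60 iterations at \(10^{-4}\),
where reconstruction quality for these phantoms has plateaued. The model is
single-coil; parallel imaging and vendor k-space interpolation are out of
scope, and the package undersamples whatever grid it is given.

### The metric battery

All metrics are computed per slice on pairs normalized by the reference
maximum (`normalizePair()`), so the reference spans 0–1 and RMSE of a test
image within the reference range is bounded by 1. Constants defined on
8-bit scales are applied after an internal 0–255 rescale and are all
surfaced as arguments:

* **SSIM** — 11×11 Gaussian window, σ = 1.5, K1 = 0.01, K2 = 0.03, L = 1
  (the original publication defaults).
* **FSIM** — luminance-only: phase congruency from a 4-scale × 4-orientation
  log-Gabor bank (minimum wavelength 6, multiplier 2, σ_onf = 0.55, median-
  based noise compensation) combined with Scharr gradient similarity,
  weighted by the pointwise maximum phase congruency (T1 = 0.85, T2 = 160).
* **NQM** — octave-band decomposition weighted by the Mannos–Sakrison
  contrast sensitivity function, with threshold-elevation contrast masking
  of the band errors, reported as a weighted SNR in dB. The viewing model
  maps the image width to a fixed 4° visual angle (declared in the
  arguments, since no standard exists for it). Identical inputs return the
  `+Inf` sentinel; it only arises at R = 1, which is never regressed.
* **VIF** — multiscale pixel-domain Gaussian-scale-mixture variant by
  default (deterministic and dependency-light), with a wavelet-subband
  variant behind `domain = "wavelet"`; the two are required (and tested) to
  agree in rank order (SROCC > 0.95) on a graded noise sweep.

Slice scores are reduced to per-series scores by the mean
(`aggregateSeries()`, median available); the slice-to-series reduction is a
declared package default, not a community standard.

### The simulated observer

`simulateConfidence()` scores a reconstructed series the way the analysis
needs a rater to: through the **conspicuity** of the task's lesion set —
mean intensity over the truth mask minus the mean over a surrounding
lesion-free band of normal-appearing tissue, divided by the scaled median
absolute deviation of the band. The MAD denominator is robust to sparse CS
artifact outliers yet rises with the noise-like aliasing that masks diffuse
lesions, which is exactly the mechanism by which acceleration erodes
chronic-lesion reading. Lesion-free subjects use a fixed reference
conspicuity (default 6) standing for a clean negative read. The latent
confidence is

\[
\ell = \text{slope}\cdot c + \text{bias}
     + \text{acuteFloor}\cdot[\text{task}=\text{acute}] + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),
\]

cut by four shared ascending thresholds into a 1–5 Likert score. The
`acuteFloor` is the abstract stand-in for the never-degraded
diffusion-weighted channel: the package deliberately does not synthesize
DWI images (a non-goal), only the confidence floor they provide.

The default panel (`defaultObserverModels()`) is three raters sharing slope
1, noise s.d. 0.33 and thresholds (0, 0.75, 1.5, 2.25), differing only by
latent biases (0, −0.25, +0.25) — rater differences enter through bias only,
which keeps the model identifiable for parameter-recovery checks. These
values were calibrated once against the qualitative behavior the study
design requires — chronic confidence high at full sampling and degrading
with acceleration, acute confidence pinned at the top of the scale with
occasional 4s, and strong inter-rater agreement (pairwise AC2 well above
the 0.80 pooling gate) — and are not revisited per analysis. In the default
study the chronic confidence drop becomes significant already at R = 2,
slightly earlier than a clinical panel would typically show; the high-R
behavior (clear degradation beyond R = 3–4) is the calibrated target.

### Study design

`generateStudy()` reproduces the full design arithmetic: 18 subjects × 7
acceleration factors × 3 raters × 2 tasks gives 126 series and 378 rating
records per task (54 per R value). The subject mix mirrors a realistic
stroke-imaging population: 2 healthy controls, 12 confirmed acute-positive
patients, and 4 clinically suspected cases of which 2 are positive and 2
negative, with chronic grades drawn to make grades 0–1 the majority. The
default problem size is 128×128 slices, 3 slices per subject — a desk-scale
stand-in for full clinical matrices chosen so a complete study (756
confidence scores, 108 CS reconstructions, 1620 metric evaluations) runs in
about a minute.

## Statistics

* **Agreement** (`gwetAC2()`, `gwetAC2Panel()`): Gwet's AC2 with quadratic
  weights \(w_{kl} = 1 - (k-l)^2/(q-1)^2\), chance term
  \(T_w/(q(q-1))\sum_k \pi_k(1-\pi_k)\), linearized variance and symmetric
  95% CI. Pairwise coefficients (plus a panel coefficient) are reported,
  and pooling confidence scores across raters is gated on all pairwise
  AC2 > 0.80. Kappa statistics are deliberately absent (their paradoxes
  under skewed margins are the reason AC2 is used).
* **Confidence versus R** (`confidenceVsR()`): pooled boxplot statistics per
  R plus paired Wilcoxon signed-rank tests of each R > 1 against R = 1,
  Bonferroni-corrected over the six comparisons. The signed-rank
  implementation drops zero differences, uses average ranks, and computes
  the exact tie-aware null by convolution up to n = 12, switching to a
  normal approximation with tie and continuity corrections above; the
  two-sided default can be changed. All-zero-difference comparisons are
  undefined and flagged rather than forced.
* **Gaussianity** (`sampleKurtosis()`): non-excess kurtosis \(m_4/m_2^2\),
  with 2–4 read as consistent with normality.
* **Regression** (`fitConstrainedLogistic()`): the 4-parameter logistic
  \(y = \beta_1 + (\beta_2-\beta_1)/(1+e^{-(x-\beta_3)/\beta_4})\) fit by
  bounded least squares with \(\beta_1,\beta_2 \in [0,100]\) (the
  constraint implied by the confidence scale) and the sign of \(\beta_4\)
  fixed by the rank correlation of the data; five deterministic starts are
  polished by L-BFGS-B and the best kept, so the fit is deterministic. The
  exact parameterization of a "constrained logistic" is an open design
  choice; this one is the minimal monotone form consistent with the scale,
  and the model function is isolated so alternatives can be swapped in.
  Points are per (series, rater) with R = 1 excluded — 324 points per task
  at full design — and pooling across raters is only justified when the
  AC2 gate passes, which the pipeline checks and logs first.
* **Metric ranking** (`iqmPerformanceMatrix()`): one-sided Wilcoxon tests on
  paired absolute residuals for every ordered metric pair, Bonferroni
  m = 20; a significant cell means the row metric tracks confidence better
  than the column metric.

## Numerical choices and degenerate inputs

* k-space convention: DC-centered grids, unnormalized forward DFT (DC =
  summed intensity); the solver rescales to the orthonormal operator
  internally, so objective values are scale-consistent.
* Even grid sizes are assumed throughout (the wavelet requires dyadic
  divisibility); the mask grid center uses the half-sample convention
  \((n+1)/2\).
* Zero-variance responses produce flat fits with warnings, undefined SROCC
  is NA (never silently 0), all-zero Wilcoxon differences raise errors at
  the test level and are caught and flagged by `confidenceVsR()`.
* The NQM `+Inf` sentinel is excluded by `aggregateSeries()`.
* Reconstruction non-convergence is never silent: the result carries
  `converged = FALSE` and a warning; `generateStudy()` counts and reports
  cap-limited reconstructions in one message.

## What the synthetic study does and does not show

The generator emulates the *structure* of a clinical confidence study — its
design arithmetic, the contrast mechanisms of the two lesion systems, the
degradation physics of variable-density CS, and a threshold observer whose
agreement and task dissociation resemble a real panel's. It does not emulate
scanner physics, reader psychology beyond a one-dimensional latent model,
or the specific numeric values a real panel produces: passing the test
suite shows the pipeline's statistics behave correctly and that the
qualitative chronic/acute dissociation is reproduced under the stated
conditions, not that any particular clinical SSR, SROCC or p-value would be
matched. Real rating tables can be analyzed by supplying a ratings
data.frame (schema `subject,R,rater,task,answer,confidence`) and metric
records directly to the statistics layer.

## A worked run

```{r, eval = FALSE}
study <- generateStudy(seed = 1)        # ~1 minute
bundle <- runPipeline(study = study)
studyReport(bundle)
```

On seed 1 this prints pairwise chronic-task AC2 of 0.92–0.94 (acute ~0.999),
a chronic confidence median falling from 5 at R = 1 to 1–2 at R ≥ 5 with
Bonferroni-adjusted p < 10⁻⁵ for every R ≥ 2, an acute median fixed at 5
with all adjusted p = 1, and chronic-task SROCC magnitudes around 0.3–0.4
for all five metrics (positive for the similarity metrics, negative for
RMSE) against acute-task magnitudes below 0.11.

## Known limitations

* Acquisition realism is out of scope by design (single coil, no vendor
  resampling, no DWI synthesis).
* The slice-to-series aggregation (mean) and the NQM viewing model are
  declared defaults, not field standards; both are arguments.
* Grade-0 subjects contribute R-independent confidence by construction
  (fixed reference conspicuity), which dilutes subjective–objective
  correlations relative to a panel that also loses confidence in negatives
  at high acceleration.
* DICOM series reading is not provided; convert to NIfTI first.
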