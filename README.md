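# csIQA

Task-specific image quality assessment for compressed-sensing MRI.

## The problem

Objective full-reference image quality metrics (IQMs) — RMSE, SSIM, FSIM,
NQM, VIF — are widely used as stand-ins for radiologist opinion when MRI
acceleration and reconstruction strategies are compared. But "image quality"
is not one thing: undersampling artifact that erases diffuse, low-contrast
chronic white-matter lesions can leave a focal, high-contrast acute stroke
lesion perfectly readable, especially when an undegraded diffusion-weighted
series is also on the screen. Whether an IQM tracks a reader's confidence
therefore depends on the diagnostic task, and a metric validated on one task
cannot be assumed to transfer to another.

csIQA is an R package for studying exactly this. It implements the whole
chain — retrospective variable-density Cartesian undersampling of k-space,
l1-wavelet compressed-sensing reconstruction, the five-metric IQM battery,
inter-rater agreement and confidence statistics, and subjective–objective
regression — plus a synthetic phantom and simulated-observer study generator,
so the complete analysis is reproducible without access to patient images.
Real rating tables (CSV) and volumes (NIfTI) can be fed into the same
statistics layer.

## The core methods

* **Sampling**: phase-encode line masks with probability 1 over the central
  eighth of k-space and polynomial density decay `(1-|r|)^p`, `p = 7`; an
  additive offset is solved so the expected line count equals `n_PE / R`,
  Monte-Carlo draws are screened to hit nominal `R` within 5%, and the mask
  with the smallest point-spread-function sidelobe is kept.
* **Reconstruction**: `argmin_x 1/2 ||M F x - y||^2 + lambda ||W x||_1`
  (`lambda = 0.01`), with unitary centered DFT `F` and unitary periodic
  Daubechies-4 wavelet `W`, solved by monotone FISTA with unit step (the
  objective trace is exactly non-increasing). The inner loop is compiled
  (Rcpp/Armadillo) with a pure-R reference path kept and tested against it.
* **Metrics**: SSIM (11x11 Gaussian window, K1=0.01, K2=0.03), luminance
  FSIM (log-Gabor phase congruency x Scharr gradient similarity), NQM
  (CSF-weighted, contrast-masked band SNR in dB), VIF (multiscale
  Gaussian-scale-mixture information ratio; pixel-domain default,
  wavelet-domain variant behind a flag), and reference-normalized RMSE.
* **Statistics**: Gwet's quadratic-weighted AC2 with linearized variance
  (pairwise and panel; pooling gated at AC2 > 0.80), non-excess kurtosis,
  an exact tie-aware Wilcoxon signed-rank test with Bonferroni correction,
  and a constrained 4-parameter logistic regression of 0–100 confidence on
  IQM scores with SROCC, SSR, residual kurtosis, and a one-sided
  residual-based metric-ranking matrix.

## A worked example

```r
library(csIQA)
study  <- generateStudy(seed = 1)   # 18 subjects x R=1..7 x 3 raters, ~1 min
bundle <- runPipeline(study = study)
studyReport(bundle)
```

Abridged output of that exact run:

```
== Inter-rater agreement (Gwet AC2, quadratic weights) ==
 chronic task: panel 0.928 | pairwise: rater1-rater2 0.933 rater1-rater3 0.935 rater2-rater3 0.916
 acute task: panel 0.999 | pairwise: rater1-rater2 0.999 rater1-rater3 0.999 rater2-rater3 1.000

== Pooled confidence versus R ==
 chronic task (pooled kurtosis 1.3):
  R=1 median 5.0 [5.0, 5.0]
  R=2 median 3.0 [2.0, 5.0] adj p = 1.994e-07 *
  R=4 median 1.0 [1.0, 4.0] adj p = 8.507e-08 *
  R=7 median 1.0 [1.0, 3.0] adj p = 3.207e-08 *
 acute task (pooled kurtosis 124.0):
  R=1 median 5.0 [5.0, 5.0]
  R=7 median 5.0 [5.0, 5.0]

== Metric fits (chronic task) ==
    task metric    ssr residualKurtosis  srocc
 chronic   FSIM 480824             2.18  0.317
 chronic    NQM 477312             2.20  0.323
 chronic   RMSE 488057             2.19 -0.333
 chronic   SSIM 487244             2.19  0.344
 chronic    VIF 486311             2.19  0.361
```

Reading it: the three simulated raters agree far above the 0.80 pooling
gate; chronic-task confidence collapses with acceleration (Bonferroni-
adjusted p < 1e-6 at every R >= 2) while acute-task confidence stays pinned
at 5 at every R (comparisons without a printed p had no nonzero paired
differences at all); and every metric correlates with chronic-task
confidence in the correct direction (similarity metrics positive, RMSE
negative) while no metric tracks the acute task — the task dissociation the
package exists to measure.

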