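#' @import methods
NULL

## ---------------------------------------------------------------------------
## Phantom / study objects
## ---------------------------------------------------------------------------

#' SubjectVolume: a multi-slice magnitude brain image with lesion truth
#'
#' Container for one simulated (or loaded) subject: a stack of 2D magnitude
#' slices, voxel geometry, boolean truth masks for focal acute lesions and
#' diffuse chronic white-matter lesions, and the ordinal chronic burden grade
#' (0--3, Fazekas-like: 0 absent, 1 punctate caps, 2 beginning confluence,
#' 3 large confluent areas).
#'
#' @slot subjectID character label.
#' @slot image numeric 3D array (rows x cols x slices), nonnegative.
#' @slot voxelSpacing numeric length-3, mm per axis.
#' @slot acuteMask,chronicMask logical arrays matching `image`.
#' @slot chronicGrade integer in 0..3; 0 iff `chronicMask` is empty.
#' @slot hasAcute logical; FALSE iff `acuteMask` is empty.
#' @export
setClass("SubjectVolume",
  representation(subjectID = "character", image = "array",
                 voxelSpacing = "numeric", acuteMask = "array",
                 chronicMask = "array", chronicGrade = "integer",
                 hasAcute = "logical"))

setValidity("SubjectVolume", function(object) {
  msg <- character()
  if (length(dim(object@image)) != 3L) msg <- c(msg, "image must be a 3D array")
  if (any(object@image < 0)) msg <- c(msg, "intensities must be nonnegative")
  if (!identical(dim(object@acuteMask), dim(object@image)))
    msg <- c(msg, "acuteMask shape must match image")
  if (!identical(dim(object@chronicMask), dim(object@image)))
    msg <- c(msg, "chronicMask shape must match image")
  if (!(object@chronicGrade %in% 0:3)) msg <- c(msg, "chronicGrade must be in 0..3")
  if ((object@chronicGrade == 0L) != (sum(object@chronicMask) == 0L))
    msg <- c(msg, "chronicGrade == 0 must coincide with an empty chronicMask")
  if (!object@hasAcute && sum(object@acuteMask) > 0L)
    msg <- c(msg, "acuteMask must be empty for acute-negative subjects")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' ObserverModel: a simulated rater
#'
#' Maps post-reconstruction lesion conspicuity to a 1--5 Likert diagnostic
#' confidence score through a latent-variable threshold model:
#' `latent = slope * conspicuity + raterBias + acuteFloor * [task == "acute"]
#' + N(0, noiseSD)`, and the Likert score is 1 plus the number of thresholds
#' below the latent value (clamped to 1..5).  `acuteFloor` stands for the
#' conspicuity contributed by the never-degraded diffusion-weighted channel
#' that anchors the acute task.
#'
#' @slot raterBias numeric offset on the latent scale.
#' @slot slope numeric conspicuity gain.
#' @slot noiseSD nonnegative latent noise standard deviation.
#' @slot thresholds 4 strictly ascending category cut points.
#' @slot acuteFloor numeric additive floor for the acute task.
#' @export
setClass("ObserverModel",
  representation(raterBias = "numeric", slope = "numeric", noiseSD = "numeric",
                 thresholds = "numeric", acuteFloor = "numeric"))

setValidity("ObserverModel", function(object) {
  msg <- character()
  if (length(object@thresholds) != 4L || any(diff(object@thresholds) <= 0))
    msg <- c(msg, "thresholds must be 4 strictly ascending values")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' StudyDataset: a complete simulated observer study
#'
#' @slot subjects list of [SubjectVolume-class] objects.
#' @slot RValues integer acceleration factors (1 = fully sampled reference).
#' @slot ratings data.frame of rating records, one row per
#'   (subject, R, rater, task) with columns `subject`, `R`, `rater`, `task`,
#'   `answer`, `confidence`.
#' @slot iqm data.frame of per-slice image-quality records with columns
#'   `subject`, `R`, `slice`, `metric`, `value` (undersampled R only).
#' @slot seed integer master seed.
#' @slot params list of generation parameters (manifest).
#' @export
setClass("StudyDataset",
  representation(subjects = "list", RValues = "integer", ratings = "data.frame",
                 iqm = "data.frame", seed = "integer", params = "list"))

setValidity("StudyDataset", function(object) {
  r <- object@ratings
  need <- c("subject", "R", "rater", "task", "answer", "confidence")
  if (!all(need %in% names(r))) return("ratings is missing required columns")
  if (nrow(r) && !all(r$confidence %in% 1:5)) return("confidence must be in 1..5")
  nTask <- table(r$task)
  nExp <- length(object@subjects) * length(object@RValues) *
    length(unique(r$rater))
  if (nrow(r) && any(nTask != nExp))
    return("ratings per task must equal n_subjects * |R_values| * n_raters")
  TRUE
})

## ---------------------------------------------------------------------------
## Sampling / reconstruction objects
## ---------------------------------------------------------------------------

#' MaskSpec: variable-density Cartesian undersampling specification
#'
#' The sampling density is 1 over the central `centerFraction` of phase-encode
#' lines and decays polynomially, `(1 - |r|)^decayP`, with normalized distance
#' `r` from the grid center, plus an additive offset tuned so the expected
#' number of sampled lines equals `nPE / RNominal`.
#'
#' @slot RNominal nominal acceleration factor (>= 1).
#' @slot centerFraction fully sampled central fraction, default 1/8.
#' @slot decayP polynomial decay rate, default 7.
#' @slot nPE number of phase-encode lines.
#' @slot seed integer seed for the Monte-Carlo mask draw.
#' @export
setClass("MaskSpec",
  representation(RNominal = "numeric", centerFraction = "numeric",
                 decayP = "numeric", nPE = "integer", seed = "integer"))

setValidity("MaskSpec", function(object) {
  msg <- character()
  if (object@RNominal < 1) msg <- c(msg, "RNominal must be >= 1")
  if (object@centerFraction <= 0 || object@centerFraction > 1)
    msg <- c(msg, "centerFraction must be in (0, 1]")
  if (object@decayP < 0) msg <- c(msg, "decayP must be >= 0")
  if (object@nPE < 2L) msg <- c(msg, "nPE must be >= 2")
  if (length(msg)) msg else TRUE
})

#' SamplingMask: a drawn phase-encode undersampling pattern
#'
#' @slot lines logical vector of length `nPE`; TRUE = line acquired.
#' @slot RRealized `nPE / sum(lines)`.
#' @slot spec the generating [MaskSpec-class].
#' @export
setClass("SamplingMask",
  representation(lines = "logical", RRealized = "numeric", spec = "MaskSpec"))

setValidity("SamplingMask", function(object) {
  msg <- character()
  if (length(object@lines) != object@spec@nPE)
    msg <- c(msg, "lines length must equal spec nPE")
  if (!all(object@lines[centerLineIndices(object@spec)]))
    msg <- c(msg, "all central lines must be sampled")
  if (abs(object@RRealized - object@spec@nPE / sum(object@lines)) > 1e-9)
    msg <- c(msg, "RRealized inconsistent with lines")
  if (length(msg)) msg else TRUE
})

#' ReconConfig: compressed-sensing reconstruction settings
#'
#' The reconstruction solves `argmin_x 1/2 ||M F x - y||^2 + lambda ||W x||_1`
#' with unitary DFT `F` and unitary Daubechies-4 wavelet `W`, by monotone
#' FISTA with unit step.
#'
#' @slot lambda l1-wavelet regularization weight, default 0.01.
#' @slot waveletLevels decomposition levels, default 4.
#' @slot maxIter iteration cap, default 200.
#' @slot tol relative objective-change stopping tolerance, default 1e-6.
#' @slot stepRule "fixed" (unit step; the operator norm is exactly 1).
#' @export
setClass("ReconConfig",
  representation(lambda = "numeric", waveletLevels = "integer",
                 maxIter = "integer", tol = "numeric", stepRule = "character"))

setValidity("ReconConfig", function(object) {
  msg <- character()
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (object@waveletLevels < 1L) msg <- c(msg, "waveletLevels must be >= 1")
  if (!object@stepRule %in% c("fixed", "backtracking"))
    msg <- c(msg, "stepRule must be 'fixed' or 'backtracking'")
  if (length(msg)) msg else TRUE
})

#' ReconResult: output of the CS solver for one slice
#'
#' @slot image magnitude image of the final iterate.
#' @slot objectiveTrace objective value per iteration (non-increasing).
#' @slot nIter iterations used.
#' @slot converged TRUE if the tolerance was reached before `maxIter`.
#' @export
setClass("ReconResult",
  representation(image = "matrix", objectiveTrace = "numeric",
                 nIter = "integer", converged = "logical"))

setValidity("ReconResult", function(object) {
  if (any(!is.finite(object@objectiveTrace)))
    return("objectiveTrace must be finite")
  tr <- object@objectiveTrace
  if (length(tr) > 1 && tr[length(tr)] > tr[1] + 1e-9)
    return("final objective must not exceed initial objective")
  TRUE
})

## ---------------------------------------------------------------------------
## Statistics objects
## ---------------------------------------------------------------------------

#' AgreementResult: Gwet's weighted agreement coefficient
#'
#' @slot ac2 the coefficient in [-1, 1].
#' @slot variance Gwet's linearized variance estimate.
#' @slot ci95 symmetric normal-approximation 95% confidence interval.
#' @export
setClass("AgreementResult",
  representation(ac2 = "numeric", variance = "numeric", ci95 = "numeric"))

setValidity("AgreementResult", function(object) {
  msg <- character()
  if (abs(object@ac2) > 1 + 1e-12) msg <- c(msg, "ac2 must be in [-1, 1]")
  if (length(object@ci95) != 2L) msg <- c(msg, "ci95 must have length 2")
  else if (object@ac2 < object@ci95[1] - 1e-12 ||
           object@ac2 > object@ci95[2] + 1e-12)
    msg <- c(msg, "ci95 must contain ac2")
  if (length(msg)) msg else TRUE
})

#' LogisticFit: constrained-logistic subjective-vs-objective regression
#'
#' Model `y = b1 + (b2 - b1) / (1 + exp(-(x - b3)/b4))` fit by bounded
#' nonlinear least squares, with the asymptotes constrained to the 0--100
#' confidence scale and the slope sign fixed by the rank correlation of the
#' data.
#'
#' @slot beta named numeric length 4: lower/upper asymptote, inflection, scale.
#' @slot ssr sum of squared residuals.
#' @slot srocc Spearman rank-order correlation of x and y (NA if degenerate).
#' @slot signedResiduals,absResiduals residual vectors (abs = |signed|).
#' @slot residualKurtosis m4/m2^2 kurtosis of the signed residuals.
#' @export
setClass("LogisticFit",
  representation(beta = "numeric", ssr = "numeric", srocc = "numeric",
                 signedResiduals = "numeric", absResiduals = "numeric",
                 residualKurtosis = "numeric"))

setValidity("LogisticFit", function(object) {
  msg <- character()
  if (length(object@beta) != 4L) msg <- c(msg, "beta must have length 4")
  if (abs(object@ssr - sum(object@signedResiduals^2)) >
      1e-6 * max(1, object@ssr))
    msg <- c(msg, "ssr must equal the sum of squared signed residuals")
  if (max(abs(object@absResiduals - abs(object@signedResiduals))) > 1e-12)
    msg <- c(msg, "absResiduals must equal |signedResiduals|")
  if (length(msg)) msg else TRUE
})
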