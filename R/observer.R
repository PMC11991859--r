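## Simulated rater: post-reconstruction lesion conspicuity drives a latent
## confidence variable that is cut into a 1--5 Likert score.

#' Construct an ObserverModel
#'
#' @param raterBias latent-scale offset of this rater.
#' @param slope conspicuity-to-latent gain.
#' @param noiseSD latent Gaussian noise s.d.
#' @param thresholds 4 strictly ascending Likert cut points.
#' @param acuteFloor additive latent floor for the acute task (the
#'   never-degraded diffusion channel keeps the acute target conspicuous
#'   regardless of how the FLAIR-like image is degraded).
#' @return an [ObserverModel-class].
#' @export
ObserverModel <- function(raterBias = 0, slope = 1, noiseSD = 0.5,
                          thresholds = c(1, 2, 3, 4), acuteFloor = 0) {
  new("ObserverModel", raterBias = raterBias, slope = slope,
      noiseSD = noiseSD, thresholds = thresholds, acuteFloor = acuteFloor)
}

#' Default simulated-rater panel
#'
#' Three raters sharing one set of Likert thresholds and differing only by a
#' small latent bias (this keeps the model identifiable for
#' parameter-recovery checks).  The shared parameters are calibrated so that,
#' on the default phantom study, chronic-task confidence is high at full
#' sampling and degrades as acceleration masks the diffuse lesions, while
#' the acute task stays pinned at the top of the scale.
#'
#' @param nRaters number of raters (default 3).
#' @return list of [ObserverModel-class] objects.
#' @export
defaultObserverModels <- function(nRaters = 3L) {
  biases <- c(0, -0.25, 0.25, -0.12, 0.12)
  lapply(seq_len(nRaters), function(i)
    ObserverModel(raterBias = biases[((i - 1L) %% 5L) + 1L],
                  slope = 1, noiseSD = 0.33,
                  thresholds = c(0.0, 0.75, 1.5, 2.25),
                  acuteFloor = 0.2))
}

## dilate a logical slice by spreading + threshold (approximate, determinate)
.spreadMask <- function(mask, sigma) gaussianBlurFFT(mask * 1, sigma) > 0.02

#' Lesion conspicuity of a reconstructed volume
#'
#' Contrast-to-noise of the task's lesion set: mean intensity over the truth
#' mask minus mean over a surrounding lesion-free background band, divided by
#' a robust noise estimate (scaled median absolute deviation of the band
#' intensities; robust to sparse CS artifact outliers, while rising with the
#' noise-like aliasing that masks diffuse lesions).  Subjects without a
#' lesion for the task return the fixed `refConspicuity`, standing for the
#' confidence of reading a clean negative.
#'
#' @param recon real 3D array aligned with the truth volume.
#' @param truth a [SubjectVolume-class] providing the masks.
#' @param task `"acute"` or `"chronic"`.
#' @param refConspicuity value returned when the task mask is empty
#'   (default 6).
#' @return scalar conspicuity.
#' @export
conspicuity <- function(recon, truth, task = c("chronic", "acute"),
                        refConspicuity = 6) {
  task <- match.arg(task)
  stopifnot(is(truth, "SubjectVolume"))
  if (!identical(dim(recon), dim(truth@image)))
    stop("recon shape must match the truth volume")
  if (length(recon) == 0) stop("empty image")
  mask <- if (task == "acute") truth@acuteMask else truth@chronicMask
  if (sum(mask) == 0) return(refConspicuity)
  otherMask <- if (task == "acute") truth@chronicMask else truth@acuteMask
  lesionVals <- numeric(0); bandVals <- numeric(0)
  for (s in seq_len(dim(recon)[3])) {
    ms <- mask[, , s]
    if (!any(ms)) next
    sl <- recon[, , s]
    outer <- .spreadMask(ms, 4)
    innerEx <- .spreadMask(ms, 1.2)
    q99 <- stats::quantile(sl, 0.99)
    ## normal-appearing tissue: exclude background/CSF below and the bright
    ## scalp rim above
    brain <- sl > 0.35 * q99 & sl < 0.85 * q99
    band <- outer & !innerEx & brain & !otherMask[, , s]
    if (sum(band) < 20) band <- outer & !innerEx & brain
    lesionVals <- c(lesionVals, sl[ms])
    bandVals <- c(bandVals, sl[band])
  }
  sigma <- stats::mad(bandVals)
  if (sigma <= 0) sigma <- .Machine$double.eps
  (mean(lesionVals) - mean(bandVals)) / sigma
}

#' Simulate a Likert confidence score
#'
#' Latent confidence is `slope * conspicuity + raterBias +
#' acuteFloor * [task == "acute"] + N(0, noiseSD)`; the Likert score is 1
#' plus the number of thresholds below the latent value, clamped to 1..5.
#'
#' @param recon real 3D array (reconstructed series).
#' @param truth the generating [SubjectVolume-class].
#' @param task `"acute"` or `"chronic"`.
#' @param obs an [ObserverModel-class].
#' @param seed integer seed for the latent noise.
#' @param refConspicuity passed to [conspicuity()].
#' @return integer Likert score in 1..5.
#' @export
simulateConfidence <- function(recon, truth, task, obs, seed = 1L,
                               refConspicuity = 6) {
  stopifnot(is(obs, "ObserverModel"))
  task <- match.arg(task, c("chronic", "acute"))
  cv <- conspicuity(recon, truth, task, refConspicuity)
  latent <- withLocalSeed(seed, {
    obs@slope * cv + obs@raterBias +
      (task == "acute") * obs@acuteFloor + rnorm(1, 0, obs@noiseSD)
  })
  as.integer(min(5L, max(1L, 1L + sum(latent > obs@thresholds))))
}
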