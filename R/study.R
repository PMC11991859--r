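## End-to-end synthetic observer study: phantoms -> k-space -> undersampling
## -> CS reconstruction -> metric battery -> simulated Likert confidence.

## 18-subject template mirroring the source population: 2 healthy controls,
## 12 confirmed acute-positive patients, 4 clinically suspected cases of
## which 2 were acute-positive and 2 acute-negative on follow-up.
.subjectTemplate <- function(nSubjects) {
  types <- c(rep("acute-positive", 12), "suspected-positive",
             "suspected-positive", "suspected-negative", "suspected-negative",
             "healthy", "healthy")
  types[((seq_len(nSubjects) - 1L) %% length(types)) + 1L]
}

#' Generate a complete synthetic observer study
#'
#' Simulates the full design: `nSubjects` phantoms spanning healthy,
#' acute-positive and acute-negative cases with a spread of chronic burden
#' grades; fully sampled noisy k-space per subject; one variable-density mask
#' and CS reconstruction per (subject, R); the slice-wise five-metric quality
#' battery against the fully sampled reference (undersampled R only); and a
#' Likert confidence score per (subject, R, rater, task) from the simulated
#' observer panel.  With the default design (18 subjects, R = 1..7, 3
#' raters) this yields 126 series per rater per task and 378 rating records
#' per task (54 per R value).  Deterministic for a fixed seed.
#'
#' @param nSubjects number of subjects (default 18).
#' @param RValues integer acceleration factors including 1 (default 1:7).
#' @param nRaters number of raters (default 3; must match `obsModels`).
#' @param obsModels list of [ObserverModel-class] objects.
#' @param seed master seed; every stream below is derived from it.
#' @param shape slice dimensions (default 128 x 128).
#' @param nSlices slices per subject (default 3).
#' @param kspaceNoiseSD acquisition noise as image-domain intensity s.d.
#'   (default 0.01, i.e. 2% of white matter level).
#' @param centerFraction,decayP sampling-density parameters (defaults 1/8, 7).
#' @param reconConfig CS settings; the study default caps iterations at 60
#'   with tolerance 1e-4, where reconstruction quality has plateaued for
#'   these phantoms.
#' @param computeIQM compute the metric battery (default TRUE)?
#' @param refConspicuity fixed conspicuity for lesion-free subjects.
#' @return a [StudyDataset-class].
#' @export
generateStudy <- function(nSubjects = 18L, RValues = 1:7, nRaters = 3L,
                          obsModels = defaultObserverModels(nRaters),
                          seed = 1L, shape = c(128L, 128L), nSlices = 3L,
                          kspaceNoiseSD = 0.01, centerFraction = 1 / 8,
                          decayP = 7,
                          reconConfig = ReconConfig(maxIter = 60L,
                                                    tol = 1e-4),
                          computeIQM = TRUE, refConspicuity = 6) {
  if (length(RValues) == 0) stop("RValues must be nonempty")
  if (nRaters != length(obsModels))
    stop("nRaters must equal the number of observer models")
  RValues <- sort(unique(as.integer(RValues)))
  seed <- as.integer(seed)
  types <- .subjectTemplate(nSubjects)
  grades <- withLocalSeed(seed, {
    g <- sample(0:3, nSubjects, replace = TRUE,
                prob = c(0.12, 0.45, 0.25, 0.18))
    g[types == "healthy"] <- sample(0:1, sum(types == "healthy"),
                                    replace = TRUE, prob = c(0.7, 0.3))
    g
  })
  hasA <- types %in% c("acute-positive", "suspected-positive")
  subjects <- vector("list", nSubjects)
  ratingRows <- list()
  iqmRows <- list()
  nonConverged <- 0L
  for (si in seq_len(nSubjects)) {
    id <- sprintf("s%02d", si)
    vol <- generatePhantom(id, grades[si], hasA[si], shape = shape,
                           nSlices = nSlices, seed = seed)
    subjects[[si]] <- vol
    kst <- simulateKspace(vol, noiseSD = kspaceNoiseSD * sqrt(prod(shape)),
                          seed = seed + 7L)
    ## fully sampled reference (R = 1 reconstruction)
    refVol <- array(0, dim(kst))
    for (s in seq_len(dim(kst)[3])) refVol[, , s] <- zeroFill(kst[, , s])
    for (R in RValues) {
      if (R == 1L) {
        recon <- refVol
      } else {
        maskSeed <- (seed * 97L + si * 131L + R * 17L) %% 2147483647L
        mk <- drawMask(MaskSpec(R, shape[1], centerFraction, decayP,
                                seed = maskSeed))
        recon <- withCallingHandlers(
          reconstructVolume(kst, mk, reconConfig),
          warning = function(w) {
            if (grepl("did not reach tol", conditionMessage(w))) {
              nonConverged <<- nonConverged + 1L
              invokeRestart("muffleWarning")
            }
          })
        if (computeIQM)
          iqmRows[[length(iqmRows) + 1L]] <-
            computeBattery(refVol, recon, id, R)
      }
      for (ri in seq_len(nRaters)) {
        for (task in c("chronic", "acute")) {
          confSeed <- (seed * 13L + si * 101L + R * 11L + ri * 7L +
                       (task == "acute") * 3L) %% 2147483647L
          conf <- simulateConfidence(recon, vol, task, obsModels[[ri]],
                                     seed = confSeed,
                                     refConspicuity = refConspicuity)
          ratingRows[[length(ratingRows) + 1L]] <- data.frame(
            subject = id, R = R, rater = paste0("rater", ri), task = task,
            answer = if (task == "acute") as.integer(hasA[si])
                     else grades[si],
            confidence = conf, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (nonConverged > 0)
    message(nonConverged, " of ", nSubjects * (length(RValues) - 1L),
            " reconstructions stopped at the iteration cap")
  ratings <- do.call(rbind, ratingRows)
  iqm <- if (length(iqmRows)) do.call(rbind, iqmRows) else
    data.frame(subject = character(), R = integer(), slice = integer(),
               metric = character(), value = numeric())
  params <- list(nSubjects = nSubjects, RValues = RValues, nRaters = nRaters,
                 shape = as.integer(shape), nSlices = as.integer(nSlices),
                 kspaceNoiseSD = kspaceNoiseSD,
                 centerFraction = centerFraction, decayP = decayP,
                 lambda = reconConfig@lambda,
                 maxIter = reconConfig@maxIter, tol = reconConfig@tol,
                 refConspicuity = refConspicuity,
                 grades = grades, types = types)
  new("StudyDataset", subjects = subjects, RValues = RValues,
      ratings = ratings, iqm = iqm, seed = seed, params = params)
}
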