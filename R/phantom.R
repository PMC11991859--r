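## Synthetic brain phantom with acute/chronic lesion truth.
##
## The phantom is deliberately minimal MR physics: a superellipse head with a
## smooth bias field and tissue texture, dark ventricles, a bright scalp rim,
## periventricular chronic hyperintensities whose extent maps the 0--3 burden
## grade, and (optionally) a compact high-contrast acute lesion blob.  The
## point is to reproduce the focal/high-contrast versus diffuse/low-contrast
## distinction between the two diagnostic targets, not anatomy.

.phantomGeometry <- function(n, m, sliceScale) {
  ## normalized coordinates; rows = phase-encode (anterior-posterior)
  yy <- matrix(seq(-1, 1, length.out = n), n, m)
  xx <- matrix(seq(-1, 1, length.out = m), n, m, byrow = TRUE)
  head <- (abs(xx / (0.72 * sliceScale))^3 +
           (abs(yy / (0.86 * sliceScale))^3)) <= 1
  inner <- (abs(xx / (0.66 * sliceScale))^3 +
            (abs(yy / (0.80 * sliceScale))^3)) <= 1
  ## two mirrored lateral ventricles: elongated ellipses beside the midline
  vent <- ((xx - 0.14)^2 / 0.012 + yy^2 / 0.11 <= 1) |
          ((xx + 0.14)^2 / 0.012 + yy^2 / 0.11 <= 1)
  vent <- vent & inner
  list(xx = xx, yy = yy, head = head, inner = inner, vent = vent)
}

## approximate pixel distance to the ventricle set via thresholded Gaussian
## spreading (deterministic, no morphology dependency)
.ventDistanceBands <- function(vent, sigmaPix) {
  sp <- gaussianBlurFFT(vent * 1, sigmaPix)
  sp / max(sp)
}

#' Generate a synthetic subject phantom
#'
#' Builds a [SubjectVolume-class]: a smooth head-like background with tissue
#' texture, dark ventricles, chronic periventricular hyperintensities whose
#' total area strictly increases with `grade` (0 = none, 1 = punctate caps,
#' 2 = caps plus thin halo, 3 = confluent extension into deep white matter),
#' and optionally one compact acute lesion blob with at least twice the
#' chronic lesion contrast.  Deterministic for a fixed
#' (`subjectID`, `grade`, `seed`).
#'
#' @param subjectID character label (also salts the random stream, so
#'   different subjects differ under one study seed).
#' @param grade integer chronic burden grade in 0..3.
#' @param hasAcute logical; add a focal acute lesion?
#' @param shape image dimensions, both >= 64 (default 128 x 128).
#' @param nSlices number of slices (default 3).
#' @param seed integer seed.
#' @return a [SubjectVolume-class].
#' @examples
#' v <- generatePhantom("s01", grade = 2, hasAcute = TRUE, seed = 1)
#' v
#' @export
generatePhantom <- function(subjectID, grade, hasAcute = FALSE,
                            shape = c(128L, 128L), nSlices = 3L, seed = 1L) {
  if (!(length(shape) == 2L && all(shape >= 64)))
    stop("shape must give two dimensions of at least 64 pixels")
  if (!(length(grade) == 1L && grade %in% 0:3))
    stop("grade must be a single integer in 0..3, got: ", grade)
  n <- as.integer(shape[1]); m <- as.integer(shape[2])
  px <- min(n, m) / 128           # geometry scale in "128-grid pixels"
  img <- array(0, c(n, m, nSlices))
  aMask <- array(FALSE, c(n, m, nSlices))
  cMask <- array(FALSE, c(n, m, nSlices))
  withLocalSeed(seed + labelHash(subjectID), {
    ## subject-level randomness shared across slices
    biasSeedField <- matrix(rnorm(n * m), n, m)
    acuteSlice <- sample.int(nSlices, 1)
    acuteSide <- sample(c(-1, 1), 1)
    ## lateral white matter, clear of both the ventricles (|x| < 0.25) and
    ## the scalp rim
    acutePos <- c(0.37 + runif(1, -0.03, 0.03), runif(1, -0.25, 0.18))
    acuteRad <- 0.055 + runif(1, 0, 0.02)
    for (s in seq_len(nSlices)) {
      sliceScale <- 1 - 0.10 * abs(s - (nSlices + 1) / 2) /
        max(1, (nSlices - 1) / 2)
      g <- .phantomGeometry(n, m, sliceScale)
      wm <- 0.5
      bias <- gaussianBlurFFT(biasSeedField, 18 * px)
      bias <- 0.05 * bias / max(abs(bias))
      texture <- gaussianBlurFFT(matrix(rnorm(n * m), n, m), 1.2 * px)
      texture <- 0.018 * texture / stats::sd(texture)
      slice <- ifelse(g$head, wm + bias + texture, 0)
      ## bright scalp rim
      rim <- g$head & !g$inner
      slice[rim] <- 0.68 + texture[rim]
      ## dark ventricles
      slice[g$vent] <- 0.14 + 0.5 * texture[g$vent]
      ## chronic periventricular lesions
      if (grade > 0) {
        spread <- .ventDistanceBands(g$vent, 2.5 * px)
        caps <- .ventDistanceBands(g$vent & (abs(g$yy) > 0.25), 2.0 * px)
        capM <- caps > 0.45 & !g$vent & g$inner
        lesion <- capM
        if (grade >= 2) lesion <- lesion | (spread > 0.42 & !g$vent & g$inner)
        if (grade == 3) lesion <- lesion | (spread > 0.22 & !g$vent & g$inner)
        prof <- gaussianBlurFFT(lesion * 1, 0.8 * px)
        slice <- slice + 0.09 * prof / max(prof)
        cMask[, , s] <- lesion
      }
      ## acute lesion: one compact high-contrast blob
      if (hasAcute && s == acuteSlice) {
        d2 <- (g$xx - acuteSide * acutePos[1])^2 + (g$yy - acutePos[2])^2
        blob <- exp(-d2 / (2 * acuteRad^2))
        blob[!g$inner] <- 0
        slice <- slice + 0.20 * blob
        aMask[, , s] <- blob > 0.5 & g$inner
      }
      img[, , s] <- pmax(slice, 0)
    }
  })
  new("SubjectVolume", subjectID = as.character(subjectID), image = img,
      voxelSpacing = c(250 / m, 250 / n, 5),
      acuteMask = aMask, chronicMask = cMask,
      chronicGrade = as.integer(grade), hasAcute = isTRUE(hasAcute))
}

#' Simulate fully sampled k-space for a subject volume
#'
#' Per-slice unnormalized centered 2D DFT of the magnitude image plus
#' independent complex Gaussian noise of standard deviation `noiseSD` per
#' real/imaginary channel.  At `noiseSD = 0` the inverse DFT recovers each
#' slice to numerical precision, and the DC sample equals the sum of slice
#' intensities.
#'
#' @param vol a [SubjectVolume-class].
#' @param noiseSD k-space noise standard deviation per channel.  For an
#'   n x m slice, image-domain noise s.d. is `noiseSD / sqrt(n*m)`.
#' @param seed integer seed for the noise stream.
#' @return complex 3D array (rows x cols x slices), DC-centered.
#' @export
simulateKspace <- function(vol, noiseSD = 0, seed = 1L) {
  stopifnot(is(vol, "SubjectVolume"))
  if (noiseSD < 0) stop("noiseSD must be nonnegative")
  d <- dim(vol@image)
  k <- array(0i, d)
  withLocalSeed(seed + labelHash(vol@subjectID), {
    for (s in seq_len(d[3])) {
      ks <- fft2c(vol@image[, , s])
      if (noiseSD > 0)
        ks <- ks + complex(real = rnorm(d[1] * d[2], 0, noiseSD),
                           imaginary = rnorm(d[1] * d[2], 0, noiseSD))
      k[, , s] <- ks
    }
  })
  k
}
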