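## Full-reference image quality metrics: RMSE, SSIM, FSIM, NQM, VIF.
##
## All metrics assume the pair has been normalized with normalizePair(), so
## the reference has unit maximum.  Metrics whose published constants are
## defined on an 8-bit scale (FSIM's T2, VIF's noise variance, SSIM via
## L = dynamic range) work on the normalized scale with L = 1 or rescale to
## 0..255 internally; every constant is surfaced as an argument.

## ---------------------------------------------------------------------------
## normalization
## ---------------------------------------------------------------------------

#' Normalization settings for metric computation
#'
#' @param mode `"reference-max"` (default; both images divided by the
#'   reference maximum, so the reference ranges 0..1 and RMSE is bounded by
#'   1 for test images within the reference range) or `"joint-percentile"`
#'   (divide by the given percentile of the pooled pair, robust to isolated
#'   bright artifacts).
#' @param percentile percentile in (0, 100] for the joint mode (default 99.9).
#' @return a list with class `"NormalizationConfig"`.
#' @export
NormalizationConfig <- function(mode = c("reference-max", "joint-percentile"),
                                percentile = 99.9) {
  mode <- match.arg(mode)
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]")
  structure(list(mode = mode, percentile = percentile),
            class = "NormalizationConfig")
}

#' Normalize a reference/test image pair
#'
#' Divides both images by one scaling constant derived from the reference
#' (its maximum, default) or from the pooled pair (percentile mode).  The
#' test image may exceed 1 after scaling.
#'
#' @param ref,test equally shaped numeric matrices; `ref` must not be all
#'   zero.
#' @param cfg a [NormalizationConfig()].
#' @return list with elements `ref` and `test`.
#' @export
normalizePair <- function(ref, test, cfg = NormalizationConfig()) {
  if (!identical(dim(ref), dim(test)))
    stop("ref and test must have the same shape")
  scale <- switch(cfg$mode,
    "reference-max" = max(ref),
    "joint-percentile" = stats::quantile(c(ref, test), cfg$percentile / 100,
                                         names = FALSE))
  if (scale <= 0) stop("reference image is all zero; cannot normalize")
  list(ref = ref / scale, test = test / scale)
}

## ---------------------------------------------------------------------------
## small filtering helpers
## ---------------------------------------------------------------------------

## separable "valid" convolution with a 1D kernel applied along both axes
.validConvSep <- function(x, k) {
  L <- length(k)
  n <- nrow(x); m <- ncol(x)
  out <- 0
  for (i in seq_len(L)) out <- out + k[i] * x[i:(n - L + i), , drop = FALSE]
  x <- out; out <- 0
  for (i in seq_len(L)) out <- out + k[i] * x[, i:(m - L + i), drop = FALSE]
  out
}

.gaussKernel <- function(size, sigma) {
  k <- exp(-((seq_len(size) - (size + 1) / 2)^2) / (2 * sigma^2))
  k / sum(k)
}

.fft2 <- function(x) .fft2Cpp(x + 0i, FALSE)
.ifft2 <- function(x) .fft2Cpp(x, TRUE)

## radial frequency grid (cycles per image) for an n x m image, uncentered
.radialFreq <- function(n, m) {
  fr <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1L):1L)) / n
  fc <- c(0:(floor(m / 2)), -((ceiling(m / 2) - 1L):1L)) / m
  sqrt(outer(fr^2, fc^2, "+"))
}

## ---------------------------------------------------------------------------
## RMSE and SSIM
## ---------------------------------------------------------------------------

#' Root mean square error
#'
#' On a reference-max normalized pair this lies in [0, 1] whenever the test
#' image stays within the reference intensity range (0 best, 1 worst).
#'
#' @param ref,test equally shaped numeric matrices (normalized pair).
#' @return nonnegative scalar.
#' @export
rmse <- function(ref, test) {
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  sqrt(mean((ref - test)^2))
}

#' Structural similarity index (mean SSIM)
#'
#' Local means, variances and covariance under a Gaussian window (11 x 11,
#' sigma 1.5, the original publication defaults), combined as
#' `((2 mu_x mu_y + C1)(2 s_xy + C2)) / ((mu_x^2 + mu_y^2 + C1)(s_x^2 + s_y^2
#' + C2))` with `C1 = (K1 L)^2`, `C2 = (K2 L)^2`, and averaged over the valid
#' window positions.
#'
#' @param ref,test equally shaped numeric matrices (normalized pair).
#' @param K1,K2 stabilization constants (defaults 0.01, 0.03).
#' @param sigma Gaussian window s.d. in pixels (default 1.5).
#' @param windowSize window side length (default 11).
#' @param L dynamic range (default 1, the normalized scale).
#' @return scalar in [-1, 1]; 1 iff the images are identical.
#' @export
ssim <- function(ref, test, K1 = 0.01, K2 = 0.03, sigma = 1.5,
                 windowSize = 11L, L = 1) {
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  if (any(dim(ref) < windowSize)) stop("image smaller than the SSIM window")
  w <- .gaussKernel(windowSize, sigma)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mu1 <- .validConvSep(ref, w); mu2 <- .validConvSep(test, w)
  s11 <- .validConvSep(ref * ref, w) - mu1^2
  s22 <- .validConvSep(test * test, w) - mu2^2
  s12 <- .validConvSep(ref * test, w) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

## ---------------------------------------------------------------------------
## FSIM: phase congruency + gradient similarity
## ---------------------------------------------------------------------------

## log-Gabor x angular-spread filter bank, cached per image size
.fsimBankCache <- new.env(parent = emptyenv())

.logGaborBank <- function(n, m, nscale = 4L, norient = 4L, minWavelength = 6,
                          mult = 2, sigmaOnf = 0.55) {
  key <- paste(n, m, nscale, norient, minWavelength, mult, sigmaOnf, sep = "_")
  hit <- .fsimBankCache[[key]]
  if (!is.null(hit)) return(hit)
  fr <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1L):1L)) / n
  fc <- c(0:(floor(m / 2)), -((ceiling(m / 2) - 1L):1L)) / m
  FR <- matrix(fr, n, m); FC <- matrix(fc, n, m, byrow = TRUE)
  radius <- sqrt(FR^2 + FC^2); radius[1, 1] <- 1
  theta <- atan2(-FR, FC)
  st <- sin(theta); ct <- cos(theta)
  thetaSigma <- pi / norient / 1.2
  bank <- vector("list", norient)
  for (o in seq_len(norient)) {
    ang <- (o - 1) * pi / norient
    ds <- st * cos(ang) - ct * sin(ang)
    dc <- ct * cos(ang) + st * sin(ang)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * thetaSigma^2))
    filters <- vector("list", nscale)
    for (s in seq_len(nscale)) {
      f0 <- 1 / (minWavelength * mult^(s - 1))
      lg <- exp(-(log(radius / f0))^2 / (2 * log(sigmaOnf)^2))
      lg[1, 1] <- 0
      filters[[s]] <- lg * spread
    }
    bank[[o]] <- filters
  }
  .fsimBankCache[[key]] <- bank
  bank
}

## Kovesi-style phase congruency map (no sigmoid weighting), one image
.phaseCongruency <- function(im, bank, noiseK = 2, mult = 2) {
  eps <- 1e-4
  FT <- .fft2(im)
  nscale <- length(bank[[1]])
  pc <- 0
  for (o in seq_along(bank)) {
    sumE <- 0; sumO <- 0; sumAn <- 0
    An1 <- NULL
    Es <- vector("list", nscale); Os <- vector("list", nscale)
    for (s in seq_len(nscale)) {
      resp <- .ifft2(FT * bank[[o]][[s]])
      E <- Re(resp); O <- Im(resp); An <- sqrt(E^2 + O^2)
      if (s == 1) An1 <- An
      Es[[s]] <- E; Os[[s]] <- O
      sumE <- sumE + E; sumO <- sumO + O; sumAn <- sumAn + An
    }
    XE <- sqrt(sumE^2 + sumO^2) + eps
    mE <- sumE / XE; mO <- sumO / XE
    energy <- 0
    for (s in seq_len(nscale)) {
      E <- Es[[s]]; O <- Os[[s]]
      energy <- energy + (E * mE + O * mO - abs(E * mO - O * mE))
    }
    tau <- stats::median(An1) / sqrt(log(4))
    totalTau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    T0 <- totalTau * (sqrt(pi / 2) + noiseK * sqrt((4 - pi) / 2))
    pc <- pc + pmax(energy - T0, 0) / (sumAn + eps)
  }
  pc
}

## Scharr gradient magnitude ("same" size, zero padding)
.scharrGradient <- function(im) {
  n <- nrow(im); m <- ncol(im)
  p <- matrix(0, n + 2, m + 2)
  p[2:(n + 1), 2:(m + 1)] <- im
  sub <- function(di, dj) p[(2 + di):(n + 1 + di), (2 + dj):(m + 1 + dj)]
  gx <- (3 * sub(-1, -1) + 10 * sub(0, -1) + 3 * sub(1, -1) -
         3 * sub(-1, 1) - 10 * sub(0, 1) - 3 * sub(1, 1)) / 16
  gy <- (3 * sub(-1, -1) + 10 * sub(-1, 0) + 3 * sub(-1, 1) -
         3 * sub(1, -1) - 10 * sub(1, 0) - 3 * sub(1, 1)) / 16
  sqrt(gx^2 + gy^2)
}

#' Feature similarity index (FSIM, luminance only)
#'
#' Phase congruency from a log-Gabor filter bank (4 scales x 4 orientations)
#' combined with Scharr gradient-magnitude similarity and weighted by the
#' pointwise maximum phase congruency.  Grayscale variant (no chrominance
#' term).  Internally works on a 0--255 scale so the published constants
#' `T1 = 0.85` (phase congruency) and `T2 = 160` (gradient) apply.
#'
#' @param ref,test equally shaped matrices, min dimension >= 32 (normalized
#'   pair).
#' @param T1,T2 similarity stabilization constants.
#' @return scalar in [0, 1]; 1 iff the inputs are identical.
#' @export
fsim <- function(ref, test, T1 = 0.85, T2 = 160) {
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  if (min(dim(ref)) < 32) stop("FSIM requires a minimum dimension of 32")
  r <- ref * 255; t <- test * 255
  ## FSIM downsamples large images to ~256 px minimum dimension
  step <- max(1, round(min(dim(r)) / 256))
  if (step > 1) {
    ri <- seq(1, nrow(r) - step + 1, by = step)
    ci <- seq(1, ncol(r) - step + 1, by = step)
    pool <- function(x) {
      acc <- 0
      for (a in 0:(step - 1)) for (b in 0:(step - 1))
        acc <- acc + x[ri + a, ci + b]
      acc / step^2
    }
    r <- pool(r); t <- pool(t)
  }
  bank <- .logGaborBank(nrow(r), ncol(r))
  pc1 <- .phaseCongruency(r, bank)
  pc2 <- .phaseCongruency(t, bank)
  g1 <- .scharrGradient(r); g2 <- .scharrGradient(t)
  sPC <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  sG <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  sum(sPC * sG * pcm) / sum(pcm)
}

## ---------------------------------------------------------------------------
## NQM: CSF-weighted, contrast-masked band SNR
## ---------------------------------------------------------------------------

## Mannos-Sakrison contrast sensitivity (normalized peak ~1)
.csf <- function(f) {
  a <- 2.6 * (0.0192 + 0.114 * f) * exp(-(0.114 * f)^1.1)
  a / 0.981
}

#' Noise quality measure (NQM)
#'
#' Weighted signal-to-noise ratio in decibels between contrast-sensitivity-
#' and masking-filtered versions of reference and test: both images are
#' decomposed into octave frequency bands, each band is weighted by the
#' Mannos-Sakrison contrast sensitivity at its center frequency, the band
#' error is attenuated where the reference band has high local contrast
#' (threshold-elevation masking), and `10 log10(signal power / error power)`
#' is returned.  Identical inputs give `+Inf` (used as the exact-match
#' sentinel; it only arises for the fully sampled reference, which is never
#' regressed).
#'
#' @param ref,test equally shaped matrices (normalized pair).
#' @param viewingAngle visual angle subtended by the image width, degrees
#'   (default 4; sets the cycles-per-degree mapping).
#' @param bandCenters band center frequencies in cycles/degree.
#' @param maskingStrength weight of the contrast-masking term (default 1).
#' @return scalar in dB, or `+Inf` for identical inputs.
#' @export
nqm <- function(ref, test, viewingAngle = 4,
                bandCenters = c(1, 2, 4, 8, 16), maskingStrength = 1) {
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  fGrid <- .radialFreq(nrow(ref), ncol(ref)) * ncol(ref) / viewingAngle
  FR <- .fft2(ref); FT <- .fft2(test)
  sigPow <- 0; errPow <- 0
  for (b in seq_along(bandCenters)) {
    f0 <- bandCenters[b]
    band <- exp(-(log2(pmax(fGrid, 1e-6) / f0))^2 / (2 * 0.5^2))
    band[1, 1] <- 0
    rb <- Re(.ifft2(FR * band))
    tb <- Re(.ifft2(FT * band))
    w <- .csf(f0)
    localC <- abs(rb) / (stats::sd(rb) + 1e-12)
    eb <- (rb - tb) / (1 + maskingStrength * localC)
    sigPow <- sigPow + sum((w * rb)^2)
    errPow <- errPow + sum((w * eb)^2)
  }
  if (errPow == 0) return(Inf)
  10 * log10(sigPow / errPow)
}

## ---------------------------------------------------------------------------
## VIF: Gaussian scale mixture information fidelity
## ---------------------------------------------------------------------------

.vifTerms <- function(s11, s22, s12, sigmaN) {
  eps <- 1e-10
  g <- s12 / (s11 + eps)
  sv <- s22 - g * s12
  zero1 <- s11 < eps
  g[zero1] <- 0; sv[zero1] <- s22[zero1]; s11[zero1] <- 0
  zero2 <- s22 < eps
  g[zero2] <- 0; sv[zero2] <- 0
  neg <- g < 0
  sv[neg] <- s22[neg]; g[neg] <- 0
  sv[sv < eps] <- eps
  list(num = sum(log10(1 + g^2 * s11 / (sv + sigmaN))),
       den = sum(log10(1 + s11 / sigmaN)))
}

#' Visual information fidelity (VIF)
#'
#' Ratio of the information the test image carries about the source to the
#' information the reference carries, under a Gaussian scale mixture model.
#' The default is the deterministic multiscale pixel-domain variant (local
#' Gaussian-window statistics at 4 dyadic scales, scalar channel gain and
#' additive visual noise); `domain = "wavelet"` uses the same per-coefficient
#' GSM approximation on Daubechies-4 subbands.  The two variants agree in
#' rank order on graded distortions.  1 for identical inputs; values above 1
#' occur for contrast-enhanced test images.
#'
#' @param ref,test equally shaped matrices (normalized pair).
#' @param sigmaN visual noise variance on the 0--255 scale (default 2).
#' @param domain `"pixel"` (default) or `"wavelet"`.
#' @return nonnegative scalar.
#' @export
vif <- function(ref, test, sigmaN = 2, domain = c("pixel", "wavelet")) {
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  domain <- match.arg(domain)
  r <- ref * 255; t <- test * 255
  num <- 0; den <- 0
  if (domain == "pixel") {
    for (scale in 1:4) {
      N <- 2^(4 - scale + 1) + 1
      w <- .gaussKernel(N, N / 5)
      if (scale > 1) {
        r <- .validConvSep(r, w)[seq(1, nrow(r) - N + 1, 2),
                                 seq(1, ncol(r) - N + 1, 2), drop = FALSE]
        t <- .validConvSep(t, w)[seq(1, nrow(t) - N + 1, 2),
                                 seq(1, ncol(t) - N + 1, 2), drop = FALSE]
      }
      mu1 <- .validConvSep(r, w); mu2 <- .validConvSep(t, w)
      s11 <- pmax(.validConvSep(r * r, w) - mu1^2, 0)
      s22 <- pmax(.validConvSep(t * t, w) - mu2^2, 0)
      s12 <- .validConvSep(r * t, w) - mu1 * mu2
      tm <- .vifTerms(s11, s22, s12, sigmaN)
      num <- num + tm$num; den <- den + tm$den
    }
  } else {
    lv <- 3L
    wr <- dwt2(r, lv); wt <- dwt2(t, lv)
    n <- nrow(r); m <- ncol(r)
    k <- .gaussKernel(5, 1)
    for (l in seq_len(lv)) {
      ## the three detail blocks at level l
      ri <- seq_len(n / 2^l); ci <- seq_len(m / 2^l)
      blocks <- list(list(ri, ci + m / 2^l), list(ri + n / 2^l, ci),
                     list(ri + n / 2^l, ci + m / 2^l))
      for (bl in blocks) {
        br <- wr[bl[[1]], bl[[2]], drop = FALSE]
        bt <- wt[bl[[1]], bl[[2]], drop = FALSE]
        if (min(dim(br)) < 5) next
        mu1 <- .validConvSep(br, k); mu2 <- .validConvSep(bt, k)
        s11 <- pmax(.validConvSep(br * br, k) - mu1^2, 0)
        s22 <- pmax(.validConvSep(bt * bt, k) - mu2^2, 0)
        s12 <- .validConvSep(br * bt, k) - mu1 * mu2
        tm <- .vifTerms(s11, s22, s12, sigmaN)
        num <- num + tm$num; den <- den + tm$den
      }
    }
  }
  if (den == 0) return(1)
  max(num / den, 0)
}

## ---------------------------------------------------------------------------
## battery and aggregation
## ---------------------------------------------------------------------------

#' Compute the five-metric battery slice-wise
#'
#' One record per (slice, metric): 5 x n_slices rows with columns `subject`,
#' `R`, `slice`, `metric`, `value`.  Each slice pair is normalized with
#' [normalizePair()] before metric computation.
#'
#' @param refVol,testVol equally shaped 3D arrays (reference = fully sampled
#'   reconstruction).
#' @param subject subject label for the records.
#' @param R acceleration factor for the records.
#' @param metrics subset of `c("RMSE","SSIM","FSIM","NQM","VIF")`.
#' @param normCfg a [NormalizationConfig()].
#' @return data.frame of IQM records.
#' @export
computeBattery <- function(refVol, testVol, subject, R,
                           metrics = c("RMSE", "SSIM", "FSIM", "NQM", "VIF"),
                           normCfg = NormalizationConfig()) {
  if (!identical(dim(refVol), dim(testVol)))
    stop("reference and test volumes must have equal slice counts and shape")
  metrics <- match.arg(metrics, several.ok = TRUE)
  nS <- dim(refVol)[3]
  rows <- vector("list", nS * length(metrics))
  i <- 0L
  for (s in seq_len(nS)) {
    np <- normalizePair(refVol[, , s], testVol[, , s], normCfg)
    for (met in metrics) {
      v <- switch(met,
        RMSE = rmse(np$ref, np$test),
        SSIM = ssim(np$ref, np$test),
        FSIM = fsim(np$ref, np$test),
        NQM = nqm(np$ref, np$test),
        VIF = vif(np$ref, np$test))
      i <- i + 1L
      rows[[i]] <- data.frame(subject = as.character(subject),
                              R = as.integer(R), slice = s, metric = met,
                              value = v, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate per-slice metric records to per-series scores
#'
#' Reduces slice-level records to one value per (subject, R, metric), by the
#' mean (default) or median over slices.  Non-finite values (the NQM
#' identical-input sentinel) are excluded from the reduction.
#'
#' @param records data.frame from [computeBattery()].
#' @param fun `"mean"` or `"median"`.
#' @return data.frame with columns `subject`, `R`, `metric`, `value`.
#' @export
aggregateSeries <- function(records, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  if (nrow(records) == 0) stop("no records to aggregate")
  f <- if (fun == "mean") mean else stats::median
  agg <- stats::aggregate(value ~ subject + R + metric,
                          data = records[is.finite(records$value), ],
                          FUN = f)
  agg[order(agg$subject, agg$R, agg$metric), , drop = FALSE]
}
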