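## Variable-density Cartesian phase-encode undersampling.
##
## A 1D line mask is drawn over the phase-encode axis (array dim 1) and
## replicated across the fully sampled frequency-encode axis.  The density is
## 1 over the central eighth of k-space (default) and falls off as
## (1 - |r|)^p away from the center (default p = 7), with an additive offset
## tuned so the expected line count matches the nominal acceleration.

#' Construct a MaskSpec
#'
#' @param RNominal nominal acceleration factor (>= 1).
#' @param nPE number of phase-encode lines.
#' @param centerFraction fully sampled central fraction of k-space
#'   (default 1/8).
#' @param decayP polynomial density decay rate (default 7).
#' @param seed seed for the Monte-Carlo mask draw.
#' @return a [MaskSpec-class] object.
#' @export
MaskSpec <- function(RNominal, nPE, centerFraction = 1 / 8, decayP = 7,
                     seed = 1L) {
  new("MaskSpec", RNominal = as.numeric(RNominal), nPE = as.integer(nPE),
      centerFraction = centerFraction, decayP = as.numeric(decayP),
      seed = as.integer(seed))
}

## indices of the fully sampled central block (ceiling(centerFraction * nPE)
## lines, centered on the half-sample grid center (nPE + 1) / 2; contains the
## DC line floor(nPE / 2) + 1)
centerLineIndices <- function(spec) {
  nc <- ceiling(spec@centerFraction * spec@nPE)
  start <- floor((spec@nPE - nc) / 2) + 1L
  seq.int(start, start + nc - 1L)
}

#' Variable-density sampling probability per phase-encode line
#'
#' Probability 1 on the central lines; elsewhere `(1 - |r|)^p` plus an
#' additive offset found by root bisection so that the expected number of
#' sampled lines equals `nPE / RNominal` (probabilities clipped to [0, 1]).
#' `r` is the distance from the grid center `(nPE + 1) / 2` normalized by
#' `nPE / 2`, so `|r| < 1` everywhere on the grid.
#'
#' @param spec a [MaskSpec-class].
#' @return numeric vector of length `nPE` with values in [0, 1].
#' @export
variableDensityPdf <- function(spec) {
  stopifnot(is(spec, "MaskSpec"))
  validObject(spec)
  n <- spec@nPE
  if (spec@RNominal == 1) return(rep(1, n))
  target <- n / spec@RNominal
  ctr <- centerLineIndices(spec)
  if (length(ctr) > target)
    stop("sampling budget unattainable: ", length(ctr),
         " fully sampled central lines exceed nPE/R = ", signif(target, 6),
         " lines")
  i <- seq_len(n)
  r <- abs(i - (n + 1) / 2) / (n / 2)
  base <- (1 - r)^spec@decayP
  out <- setdiff(i, ctr)
  want <- target - length(ctr)
  f <- function(cc) sum(pmin(1, pmax(0, base[out] + cc))) - want
  cc <- stats::uniroot(f, lower = -1, upper = 1, tol = 1e-12)$root
  pdf <- pmin(1, pmax(0, base + cc))
  pdf[ctr] <- 1
  pdf
}

## peak off-center magnitude of the point-spread function of a line mask
psfSidelobe <- function(lines) {
  p <- Mod(stats::fft(as.numeric(lines[ifftShiftIdx(length(lines))]),
                      inverse = TRUE)) / length(lines)
  max(p[-1])
}

#' Draw an undersampling mask by Monte-Carlo density sampling
#'
#' Repeats independent Bernoulli draws from the variable-density pdf up to
#' `nAttempts` times; among attempts whose realized acceleration is within
#' `tolerance` of nominal, returns the mask with the smallest peak sidelobe of
#' its point-spread function (the largest off-center magnitude of the inverse
#' DFT of the line pattern).  Deterministic for a fixed `spec` seed.
#'
#' @param spec a [MaskSpec-class].
#' @param pdf optional precomputed density from [variableDensityPdf()].
#' @param nAttempts number of Monte-Carlo draws (default 100).
#' @param tolerance relative tolerance on realized R (default 0.05).
#' @return a [SamplingMask-class].
#' @export
drawMask <- function(spec, pdf = variableDensityPdf(spec), nAttempts = 100L,
                     tolerance = 0.05) {
  stopifnot(is(spec, "MaskSpec"))
  n <- spec@nPE
  if (spec@RNominal == 1)
    return(new("SamplingMask", lines = rep(TRUE, n), RRealized = 1,
               spec = spec))
  best <- NULL
  bestSidelobe <- Inf
  closestR <- Inf
  withLocalSeed(spec@seed, {
    for (a in seq_len(nAttempts)) {
      lines <- stats::runif(n) < pdf
      rReal <- n / sum(lines)
      if (abs(rReal - spec@RNominal) > tolerance * spec@RNominal) {
        if (abs(rReal - spec@RNominal) < abs(closestR - spec@RNominal))
          closestR <- rReal
        next
      }
      sl <- psfSidelobe(lines)
      if (sl < bestSidelobe) {
        bestSidelobe <- sl
        best <- lines
      }
    }
  })
  if (is.null(best))
    stop("no mask within ", tolerance * 100, "% of R = ", spec@RNominal,
         " in ", nAttempts, " attempts (closest realized R: ",
         signif(closestR, 4), ")")
  new("SamplingMask", lines = best, RRealized = n / sum(best), spec = spec)
}

#' Apply a sampling mask to a k-space grid
#'
#' Zeroes the unsampled phase-encode lines (rows) of a DC-centered k-space
#' matrix; sampled lines are preserved bit-exactly.  The returned matrix
#' carries a logical `"sampled"` attribute recording the sampled locations.
#'
#' @param kspace complex matrix with `nrow == nPE` (phase-encode along rows).
#' @param mask a [SamplingMask-class].
#' @return masked complex matrix with attribute `sampled`.
#' @export
applyMask <- function(kspace, mask) {
  stopifnot(is(mask, "SamplingMask"))
  if (nrow(kspace) != length(mask@lines))
    stop("k-space phase-encode dimension (", nrow(kspace),
         ") does not match mask length (", length(mask@lines), ")")
  out <- kspace * mask@lines  # recycles down rows
  attr(out, "sampled") <- matrix(mask@lines, nrow(kspace), ncol(kspace))
  out
}
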