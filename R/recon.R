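## l1-wavelet regularized compressed-sensing reconstruction.
##
## Solves argmin_x 1/2 ||M F x - y||_2^2 + lambda ||W x||_1 with unitary
## centered DFT F, binary line mask M and unitary Daubechies-4 wavelet W, by
## monotone FISTA with unit step (the composite operator has Lipschitz
## constant exactly 1, so no step search is needed).  Input k-space follows
## the package convention (DC-centered, unnormalized forward DFT); the solver
## rescales to the orthonormal operator internally.

#' Construct a ReconConfig
#'
#' @param lambda l1 regularization weight (default 0.01, on the orthonormal
#'   operator scale).
#' @param waveletLevels Daubechies-4 decomposition levels (default 4).
#' @param maxIter iteration cap (default 200).
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @param stepRule "fixed" unit step (default) or "backtracking".
#' @return a [ReconConfig-class].
#' @export
ReconConfig <- function(lambda = 0.01, waveletLevels = 4L, maxIter = 200L,
                        tol = 1e-6, stepRule = "fixed") {
  new("ReconConfig", lambda = lambda, waveletLevels = as.integer(waveletLevels),
      maxIter = as.integer(maxIter), tol = tol, stepRule = stepRule)
}

## mask as a 0/1 row multiplier
.maskVec <- function(mask, kspace) {
  if (nrow(kspace) != length(mask@lines))
    stop("mask length does not match k-space phase-encode dimension")
  as.numeric(mask@lines)
}

#' Compressed-sensing objective value
#'
#' `1/2 ||M F x - y||^2 + lambda ||W x||_1` with `F` the orthonormal centered
#' 2D DFT and `W` the orthogonal wavelet transform.  `y` is given in the
#' package k-space convention (unnormalized DFT) and is rescaled internally,
#' so an image exactly consistent with fully sampled `y` has zero fidelity
#' term.
#'
#' @param x complex or real image matrix.
#' @param y masked DC-centered k-space matrix.
#' @param mask a [SamplingMask-class].
#' @param cfg a [ReconConfig-class].
#' @return finite nonnegative scalar.
#' @export
csObjective <- function(x, y, mask, cfg = ReconConfig()) {
  if (!identical(dim(x), dim(y))) stop("x and y must have the same shape")
  m <- .maskVec(mask, y)
  s <- sqrt(length(y))
  r <- m * fwdOrtho(x) - y / s
  0.5 * sum(Mod(r)^2) + cfg@lambda * sum(Mod(dwt2(x, cfg@waveletLevels)))
}

#' Zero-filled reconstruction
#'
#' Magnitude of the inverse DFT of the (zero-filled) k-space; the standard
#' baseline and the solver initialization.
#'
#' @param y DC-centered k-space matrix (package convention).
#' @return real magnitude matrix.
#' @export
zeroFill <- function(y) Mod(ifft2c(y))

#' Compressed-sensing reconstruction of undersampled k-space
#'
#' Monotone FISTA from the zero-filled initialization: at each iteration the
#' proximal-gradient candidate (soft-thresholding of the wavelet coefficients
#' by `lambda`) is accepted only if it does not increase the objective, which
#' makes the objective trace exactly non-increasing.  Stops when the relative
#' objective change falls below `tol` or after `maxIter` iterations; in the
#' latter case the result is returned with `converged = FALSE` and a warning.
#'
#' @param y masked DC-centered k-space matrix.
#' @param mask the [SamplingMask-class] used to produce `y`.
#' @param cfg a [ReconConfig-class].
#' @return a [ReconResult-class].
#' @export
csReconstruct <- function(y, mask, cfg = ReconConfig()) {
  m <- .maskVec(mask, y)
  .checkDyadic(y, cfg@waveletLevels)
  yt <- (y + 0i) / sqrt(length(y))  # orthonormal scale
  res <- .mfistaCpp(yt, m, cfg@lambda, cfg@waveletLevels, cfg@maxIter,
                    cfg@tol)
  if (!res$converged)
    warning("CS reconstruction did not reach tol = ", cfg@tol, " within ",
            cfg@maxIter, " iterations")
  new("ReconResult", image = Mod(res$x), objectiveTrace = res$trace,
      nIter = as.integer(res$nIter), converged = res$converged)
}

#' Reconstruct every slice of a k-space stack
#'
#' @param kstack complex 3D array (rows x cols x slices), DC-centered.
#' @param mask a [SamplingMask-class] applied to each slice.
#' @param cfg a [ReconConfig-class].
#' @return real 3D array of magnitude reconstructions.
#' @export
reconstructVolume <- function(kstack, mask, cfg = ReconConfig()) {
  d <- dim(kstack)
  out <- array(0, d)
  full <- all(mask@lines)
  for (s in seq_len(d[3])) {
    ks <- applyMask(kstack[, , s], mask)
    out[, , s] <- if (full && cfg@lambda == 0) zeroFill(ks)
      else csReconstruct(ks, mask, cfg)@image
  }
  out
}
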