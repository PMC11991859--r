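## Centered 2D DFT helpers.
##
## Package-wide k-space convention: arrays are DC-centered (the zero-frequency
## sample sits at [floor(n/2)+1, floor(m/2)+1]) and use the *unnormalized*
## forward DFT, so the DC sample equals the sum of image intensities.  The
## reconstruction operators rescale internally to the orthonormal DFT.

fftShiftIdx <- function(n) c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))
ifftShiftIdx <- function(n) {
  if (ceiling(n / 2) + 1L > n) return(seq_len(n))
  c((ceiling(n / 2) + 1L):n, seq_len(ceiling(n / 2)))
}

fftShift2 <- function(x) x[fftShiftIdx(nrow(x)), fftShiftIdx(ncol(x)), drop = FALSE]
ifftShift2 <- function(x) x[ifftShiftIdx(nrow(x)), ifftShiftIdx(ncol(x)), drop = FALSE]

## unnormalized centered forward DFT (DC = sum of intensities)
fft2c <- function(x) fftShift2(stats::fft(x))

## exact inverse of fft2c
ifft2c <- function(k) stats::fft(ifftShift2(k), inverse = TRUE) / length(k)

## orthonormal pair used by the CS objective (unitary F)
fwdOrtho <- function(x) fft2c(x) / sqrt(length(x))
adjOrtho <- function(k) ifft2c(k) * sqrt(length(k))

## Separable Gaussian low-pass in the frequency domain (periodic boundary);
## used for smooth random fields and multiscale filtering.
gaussianBlurFFT <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- nrow(x); m <- ncol(x)
  fr <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1L):1L)) / n
  fc <- c(0:(floor(m / 2)), -((ceiling(m / 2) - 1L):1L)) / m
  hr <- exp(-2 * pi^2 * sigma^2 * fr^2)
  hc <- exp(-2 * pi^2 * sigma^2 * fc^2)
  H <- outer(hr, hc)
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / (n * m)
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards.  All stochastic operations in the package go
## through this so results are reproducible and side-effect free.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Small deterministic hash of a label into [0, 10^6); used to decorrelate
## per-subject streams derived from one study seed.
labelHash <- function(x) {
  v <- utf8ToInt(as.character(x))
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 1000003
  as.integer(h)
}
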