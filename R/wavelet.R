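## Orthogonal Daubechies-4 (4-tap) discrete wavelet transform with periodic
## boundary handling.  This is the sparsifying transform of the compressed-
## sensing reconstruction; it is unitary, so the proximal-gradient solver can
## use a fixed unit step.  Works on real or complex matrices.

.db4Lo <- local({
  s3 <- sqrt(3)
  c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
})
.db4Hi <- c(.db4Lo[4], -.db4Lo[3], .db4Lo[2], -.db4Lo[1])

## one analysis level along rows (dim 1): returns rbind(approx, detail)
.dwtCols <- function(x) {
  n <- nrow(x)
  i <- seq_len(n / 2)
  out <- x * 0
  a <- 0; d <- 0
  for (k in 1:4) {
    rows <- ((2L * i + k - 3L) %% n) + 1L
    a <- a + .db4Lo[k] * x[rows, , drop = FALSE]
    d <- d + .db4Hi[k] * x[rows, , drop = FALSE]
  }
  out[i, ] <- a
  out[i + n / 2, ] <- d
  out
}

## one synthesis level along rows: input rbind(approx, detail)
.idwtCols <- function(w) {
  n <- nrow(w)
  i <- seq_len(n / 2)
  a <- w[i, , drop = FALSE]
  d <- w[i + n / 2, , drop = FALSE]
  x <- w * 0
  for (k in 1:4) {
    rows <- ((2L * i + k - 3L) %% n) + 1L
    x[rows, ] <- x[rows, ] + .db4Lo[k] * a + .db4Hi[k] * d
  }
  x
}

.checkDyadic <- function(x, levels) {
  n <- nrow(x); m <- ncol(x)
  if (n %% 2^levels != 0 || m %% 2^levels != 0)
    stop("matrix dimensions (", n, "x", m, ") must be divisible by 2^levels = ",
         2^levels)
}

#' Two-dimensional periodic Daubechies-4 wavelet transform
#'
#' Forward (`dwt2`) and inverse (`idwt2`) separable orthogonal wavelet
#' transform with the 4-tap Daubechies filter and periodic boundaries, in the
#' standard in-place Mallat layout (approximation block in the top-left
#' corner).  The transform is unitary: `idwt2(dwt2(x)) == x` and coefficient
#' energy equals image energy.
#'
#' @param x real or complex matrix; both dimensions must be divisible by
#'   `2^levels`.
#' @param levels integer number of decomposition levels (default 4).
#' @return matrix of the same shape: wavelet coefficients (`dwt2`) or the
#'   reconstructed image (`idwt2`).
#' @examples
#' x <- matrix(rnorm(64), 8, 8)
#' w <- dwt2(x, levels = 2)
#' max(abs(idwt2(w, levels = 2) - x))  # ~1e-15
#' @export
dwt2 <- function(x, levels = 4L) {
  .checkDyadic(x, levels)
  w <- x
  n <- nrow(x); m <- ncol(x)
  for (l in seq_len(levels)) {
    idx <- seq_len(n / 2^(l - 1)); jdx <- seq_len(m / 2^(l - 1))
    blk <- w[idx, jdx, drop = FALSE]
    blk <- .dwtCols(blk)
    blk <- t(.dwtCols(t(blk)))
    w[idx, jdx] <- blk
  }
  w
}

#' @rdname dwt2
#' @export
idwt2 <- function(x, levels = 4L) {
  .checkDyadic(x, levels)
  w <- x
  n <- nrow(x); m <- ncol(x)
  for (l in rev(seq_len(levels))) {
    idx <- seq_len(n / 2^(l - 1)); jdx <- seq_len(m / 2^(l - 1))
    blk <- w[idx, jdx, drop = FALSE]
    blk <- t(.idwtCols(t(blk)))
    blk <- .idwtCols(blk)
    w[idx, jdx] <- blk
  }
  w
}

#' Soft-thresholding (proximal operator of the l1 norm)
#'
#' Elementwise `sign(w) * max(|w| - t, 0)`; for complex input the magnitude is
#' shrunk and the phase preserved.
#'
#' @param w numeric or complex array.
#' @param t nonnegative threshold.
#' @return array of the same shape.
#' @export
softThreshold <- function(w, t) {
  if (t < 0) stop("threshold must be nonnegative")
  a <- Mod(w)
  s <- pmax(a - t, 0)
  scale <- ifelse(a > 0, s / a, 0)
  w * scale
}
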