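# brute-force centered unnormalized 2D DFT (O(N^4)), independent of fft()
bruteDFT2c <- function(x) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0i, n, m)
  rc <- floor(n / 2) + 1; cc <- floor(m / 2) + 1
  for (u in 1:n) for (v in 1:m) {
    acc <- 0i
    for (a in 1:n) for (b in 1:m)
      acc <- acc + x[a, b] *
        exp(-2i * pi * ((u - rc) * (a - 1) / n + (v - cc) * (b - 1) / m))
    out[u, v] <- acc
  }
  out
}

# literal one-level periodic Daubechies-4 analysis by explicit convolution
bruteDWT1Level <- function(x) {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  step <- function(v, f) {
    n <- length(v)
    vapply(seq_len(n / 2), function(i)
      sum(f * v[((2 * (i - 1) + 0:3) %% n) + 1]), v[1] * 0)
  }
  oneAxis <- function(mat) {
    apply(mat, 2, function(col) c(step(col, h), step(col, g)))
  }
  t(oneAxis(t(oneAxis(x))))
}

test_that("the CS objective matches a term-by-term brute-force evaluation", {
  withr::with_seed(31, {
    x <- matrix(rnorm(16), 4, 4)
    yFull <- bruteDFT2c(x) + matrix(complex(real = rnorm(16),
                                            imaginary = rnorm(16)), 4)
    mk <- new("SamplingMask", lines = c(FALSE, TRUE, TRUE, FALSE),
              RRealized = 2, spec = MaskSpec(2, 4L, centerFraction = 0.5))
    y <- yFull * c(0, 1, 1, 0)
    cfg <- ReconConfig(lambda = 0.03, waveletLevels = 1L)
    fidelity <- 0.5 * sum(Mod(c(0, 1, 1, 0) * bruteDFT2c(x) - y)^2) / 16
    l1 <- sum(Mod(bruteDWT1Level(x)))
    expect_equal(csObjective(x, y, mk, cfg), fidelity + 0.03 * l1,
                 tolerance = 1e-10)
  })
})

test_that("trivial objective values are exact", {
  mk <- drawMask(MaskSpec(1, 16L))
  z <- matrix(0, 16, 16)
  expect_equal(csObjective(z, z + 0i, mk, ReconConfig(lambda = 0.5)), 0)
  withr::with_seed(32, x <- matrix(abs(rnorm(256)), 16))
  y <- csIQA:::fft2c(x)
  expect_lt(csObjective(x, y, mk, ReconConfig(lambda = 0)), 1e-20)
})

test_that("full sampling with no regularization reproduces the inverse DFT", {
  withr::with_seed(33, img <- matrix(abs(rnorm(64^2)), 64))
  y <- csIQA:::fft2c(img)
  full <- drawMask(MaskSpec(1, 64L))
  r <- csReconstruct(y, full, ReconConfig(lambda = 0, maxIter = 20))
  expect_lt(max(abs(r@image - img)) / max(img), 1e-6)
})

test_that("the objective trace is non-increasing and recon beats zero-fill", {
  # a slice that is genuinely sparse in the wavelet domain: keep the top 3%
  # of coefficients of the phantom slice
  w <- dwt2(fixtureSlice(), 4)
  thr <- quantile(abs(w), 0.97)
  v <- pmax(idwt2(w * (abs(w) > thr), 4), 0)
  y0 <- csIQA:::fft2c(v)
  mk <- drawMask(MaskSpec(3, 64L, seed = 5))
  y <- applyMask(y0, mk)
  r <- suppressWarnings(
    csReconstruct(y, mk, ReconConfig(lambda = 0.002, maxIter = 150,
                                     tol = 1e-10)))
  expect_true(all(diff(r@objectiveTrace) <= 1e-9))
  # the magnitude CS image honours the measured data better than the
  # magnitude zero-filled image
  fidelity <- function(img) {
    0.5 * sum(Mod(as.numeric(maskLines(mk)) * csIQA:::fft2c(img) - y)^2) /
      length(y)
  }
  expect_lt(fidelity(r@image), fidelity(zeroFill(y)))
})

test_that("reaching the iteration cap warns and flags non-convergence", {
  v <- fixtureSlice()
  mk <- drawMask(MaskSpec(3, 64L, seed = 5))
  y <- applyMask(csIQA:::fft2c(v), mk)
  expect_warning(r <- csReconstruct(y, mk, ReconConfig(maxIter = 3)),
                 "did not reach")
  expect_false(r@converged)
})

test_that("zero-filling handles identity, empty, and single-line inputs", {
  withr::with_seed(34, img <- matrix(abs(rnorm(32 * 32)), 32))
  y <- csIQA:::fft2c(img)
  expect_equal(zeroFill(y), img, tolerance = 1e-12)
  expect_equal(zeroFill(matrix(0i, 32, 32)), matrix(0, 32, 32))
  # only the central phase-encode line: magnitude constant down each column
  y1 <- matrix(0i, 32, 32)
  y1[17, ] <- y[17, ]
  zf <- zeroFill(y1)
  expect_lt(max(apply(zf, 2, function(col) diff(range(col)))), 1e-12)
})

test_that("reconstruction error grows with acceleration on average", {
  errs <- sapply(1:10, function(sd) {
    v <- imageData(generatePhantom(paste0("r", sd), 2, TRUE,
                                   shape = c(64, 64), nSlices = 1,
                                   seed = sd))[, , 1]
    y0 <- csIQA:::fft2c(v)
    sapply(c(2, 4, 6), function(R) {
      mk <- drawMask(MaskSpec(R, 64L, seed = sd * 10 + R))
      r <- suppressWarnings(
        csReconstruct(applyMask(y0, mk), mk, ReconConfig(maxIter = 60,
                                                         tol = 1e-4)))
      sqrt(mean((r@image - v)^2)) / max(v)
    })
  })
  avg <- rowMeans(errs)
  expect_true(all(diff(avg) > 0))
})
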