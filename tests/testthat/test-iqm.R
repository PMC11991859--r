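test_that("normalization scales by the reference constant", {
  withr::with_seed(41, {
    ref <- matrix(runif(64^2, 0, 200), 64)
    np <- normalizePair(ref, ref)
    expect_equal(max(np$ref), 1)
    expect_identical(np$ref, np$test)
    test <- ref * 1.5
    np <- normalizePair(ref, test)
    expect_equal(max(np$test), 1.5, tolerance = 1e-12)
    expect_error(normalizePair(ref * 0, ref), "all zero")
    npj <- normalizePair(ref, test, NormalizationConfig("joint-percentile",
                                                        100))
    expect_equal(max(npj$test), 1)
  })
})

test_that("RMSE matches hand arithmetic and its brute-force oracle", {
  expect_equal(rmse(matrix(1, 2, 2), matrix(c(0.5, 1, 1, 1), 2)), 0.25)
  expect_equal(rmse(matrix(1, 8, 8), matrix(0, 8, 8)), 1)
  withr::with_seed(42, {
    a <- matrix(runif(256), 16); b <- matrix(runif(256), 16)
    acc <- 0
    for (i in 1:16) for (j in 1:16) acc <- acc + (a[i, j] - b[i, j])^2
    expect_equal(rmse(a, b), sqrt(acc / 256), tolerance = 1e-12)
  })
})

test_that("all five metrics take their identity values on equal inputs", {
  ref <- fixtureSlice()
  np <- normalizePair(ref, ref)
  expect_equal(rmse(np$ref, np$test), 0)
  expect_equal(ssim(np$ref, np$test), 1)
  expect_equal(fsim(np$ref, np$test), 1, tolerance = 1e-8)
  expect_identical(nqm(np$ref, np$test), Inf)
  expect_equal(vif(np$ref, np$test), 1, tolerance = 1e-9)
})

test_that("SSIM matches an independent sliding-window oracle", {
  withr::with_seed(43, {
    ref <- matrix(runif(32^2), 32)
    test <- ref + matrix(rnorm(32^2, 0, 0.1), 32)
    expect_equal(ssim(ref, test), ssimOracle(ref, test), tolerance = 1e-6)
  })
})

test_that("SSIM closed forms hold for degenerate inputs", {
  # constant images: variance terms vanish, luminance term remains
  a <- matrix(0.5, 32, 32); b <- matrix(0.25, 32, 32)
  C1 <- (0.01)^2
  expect_equal(ssim(a, b), (2 * 0.5 * 0.25 + C1) / (0.5^2 + 0.25^2 + C1),
               tolerance = 1e-12)
  # anti-correlated structure gives a negative covariance term
  pat <- matrix(rep(c(0.2, 0.8), 16 * 32), 32)
  expect_lt(ssim(pat, 1 - pat), 0)
})

test_that("similarity metrics fall and RMSE rises with noise level", {
  sig <- c(0.01, 0.05, 0.1, 0.2)
  ref <- fixtureSlice()
  tests <- noiseSweep(sig)
  vals <- sapply(tests, function(tst) {
    np <- normalizePair(ref, tst)
    c(rmse = rmse(np$ref, np$test), ssim = ssim(np$ref, np$test),
      fsim = fsim(np$ref, np$test), nqm = nqm(np$ref, np$test),
      vif = vif(np$ref, np$test), vifw = vif(np$ref, np$test,
                                             domain = "wavelet"))
  })
  expect_true(all(diff(vals["rmse", ]) > 0))
  for (m in c("ssim", "fsim", "nqm", "vif", "vifw"))
    expect_true(all(diff(vals[m, ]) < 0), info = m)
})

test_that("the two VIF variants agree in rank order on the noise sweep", {
  sig <- seq(0.02, 0.2, length.out = 8)
  ref <- fixtureSlice()
  tests <- noiseSweep(sig, seed = 9)
  vp <- sapply(tests, function(tst) {
    np <- normalizePair(ref, tst); vif(np$ref, np$test)
  })
  vw <- sapply(tests, function(tst) {
    np <- normalizePair(ref, tst); vif(np$ref, np$test, domain = "wavelet")
  })
  expect_gt(srocc(vp, vw), 0.95)
})

test_that("FSIM is symmetric and VIF rewards pure contrast gain", {
  ref <- fixtureSlice()
  tst <- noiseSweep(0.05, seed = 10)[[1]]
  np <- normalizePair(ref, tst)
  expect_equal(fsim(np$ref, np$test), fsim(np$test, np$ref),
               tolerance = 1e-12)
  npg <- normalizePair(ref, 1.2 * ref)
  expect_gte(vif(npg$ref, npg$test), 1)
  expect_error(fsim(matrix(1, 16, 16), matrix(1, 16, 16)), "minimum")
})

test_that("NQM is zero dB when the unmasked error equals the signal", {
  ref <- fixtureSlice()
  np <- normalizePair(ref, 2 * ref)
  # bands of test = 2 x bands of ref, so band error == band signal
  expect_equal(nqm(np$ref, np$test, maskingStrength = 0), 0,
               tolerance = 1e-9)
})

test_that("the battery emits 5 records per slice and round-trips CSV", {
  v <- generatePhantom("b1", 1, FALSE, shape = c(64, 64), nSlices = 28,
                       seed = 6)
  recs <- computeBattery(imageData(v), imageData(v), "b1", 1)
  expect_equal(nrow(recs), 140)  # 28 slices x 5 metrics
  expect_true(all(recs$value[recs$metric == "RMSE"] == 0))
  expect_true(all(recs$value[recs$metric == "SSIM"] == 1))
  expect_true(all(is.infinite(recs$value[recs$metric == "NQM"])))
  path <- tempfile(fileext = ".csv")
  writeIQMCSV(recs, path)
  back <- readIQMCSV(path)
  expect_equal(back$value, recs$value)
  expect_equal(back$metric, recs$metric)
})

test_that("series aggregation reduces slices by mean or median", {
  recs <- data.frame(subject = "s", R = 2L, slice = 1:3, metric = "SSIM",
                     value = c(0, 0, 1))
  expect_equal(aggregateSeries(recs)$value, 1 / 3)
  expect_equal(aggregateSeries(recs, "median")$value, 0)
  recs2 <- data.frame(subject = "s", R = 2L, slice = 1:2, metric = "VIF",
                      value = c(0.2, 0.4))
  expect_equal(aggregateSeries(recs2)$value, 0.3)
})
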