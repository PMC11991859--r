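# hand-coded rank-then-Pearson oracle
sroccOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

test_that("SROCC hits its extremes and matches the ranking oracle", {
  x <- c(0.1, 0.4, 0.5, 0.9, 1.3)
  expect_equal(srocc(x, exp(x)), 1)
  expect_equal(srocc(x, -x^3), -1)
  xt <- c(1, 2, 2, 3); yt <- c(1, 2, 3, 4)
  expect_equal(srocc(xt, yt), sroccOracle(xt, yt), tolerance = 1e-12)
  withr::with_seed(61, {
    a <- rnorm(30); b <- rnorm(30)
    expect_equal(srocc(a, b), sroccOracle(a, b), tolerance = 1e-12)
  })
})

test_that("SROCC is invariant under strictly monotone transforms", {
  withr::with_seed(62, {
    x <- runif(40); y <- runif(40)
  })
  base <- srocc(x, y)
  expect_equal(srocc(exp(3 * x), y), base)
  expect_equal(srocc(x, -1 / (1 + y)), base)
})

test_that("a noiseless logistic is recovered to high precision", {
  beta <- c(0, 100, 0.5, 0.1)
  x <- seq(0, 1, length.out = 50)
  y <- beta[1] + (beta[2] - beta[1]) / (1 + exp(-(x - beta[3]) / beta[4]))
  fit <- fitConstrainedLogistic(x, y)
  expect_lt(max(abs(fitBeta(fit) - beta)), 1e-3)
  expect_lt(fitSSR(fit), 1e-6)
  expect_equal(fitSROCC(fit), 1)
})

test_that("a constant response yields the flat fit with SSR zero", {
  x <- seq(0, 1, length.out = 20)
  expect_warning(fit <- fitConstrainedLogistic(x, rep(100, 20)),
                 "zero variance")
  expect_equal(fitSSR(fit), 0)
  expect_true(is.na(fitSROCC(fit)))
  expect_equal(unname(fitBeta(fit)[1]), 100)
})

test_that("the fit is invariant to joint permutation of the points", {
  withr::with_seed(63, {
    x <- runif(60)
    y <- pmin(100, pmax(0, 100 / (1 + exp(-(x - 0.4) / 0.15)) + rnorm(60, 0, 5)))
    p <- sample(60)
  })
  f1 <- fitConstrainedLogistic(x, y)
  f2 <- fitConstrainedLogistic(x[p], y[p])
  expect_equal(fitBeta(f1), fitBeta(f2), tolerance = 1e-8)
  expect_equal(fitSSR(f1), fitSSR(f2), tolerance = 1e-8)
})

test_that("the fit never does worse than the best constant predictor", {
  withr::with_seed(64, {
    for (rep in 1:5) {
      x <- runif(30)
      y <- runif(30, 0, 100)
      fit <- fitConstrainedLogistic(x, y)
      expect_lte(fitSSR(fit), sum((y - mean(y))^2) + 1e-6)
    }
  })
})

test_that("parameters are recovered from noisy data within 10% of range", {
  beta <- c(5, 95, 0.5, 0.12)
  errs <- withr::with_seed(65, {
    sapply(1:20, function(s) {
      x <- runif(108)
      y <- beta[1] + (beta[2] - beta[1]) / (1 + exp(-(x - beta[3]) / beta[4])) +
        rnorm(108, 0, 5)
      abs(fitBeta(fitConstrainedLogistic(x, pmin(100, pmax(0, y)))) - beta)
    })
  })
  medErr <- apply(errs, 1, median)
  range <- c(100, 100, 1, 1)  # asymptote scale, x-range for location/scale
  expect_true(all(medErr < 0.1 * range))
})

test_that("identical residuals give no significant performance difference", {
  withr::with_seed(66, {
    x <- runif(30); y <- runif(30, 0, 100)
  })
  f <- fitConstrainedLogistic(x, y)
  mat <- iqmPerformanceMatrix(list(A = f, B = f))
  expect_equal(unname(mat[1, 2]), 1)
  expect_equal(unname(mat[2, 1]), 1)
})

test_that("systematically smaller residuals are detected one-sidedly", {
  withr::with_seed(67, resB <- abs(rnorm(30, 1, 0.2)))
  mk <- function(r) new("LogisticFit", beta = rep(0, 4), ssr = sum(r^2),
                        srocc = 0.5, signedResiduals = r, absResiduals = abs(r),
                        residualKurtosis = 3)
  fits <- list(A = mk(resB / 2), B = mk(resB))
  mat <- iqmPerformanceMatrix(fits, m = 20)
  expect_lt(mat["A", "B"], 0.05)
  expect_gt(mat["B", "A"], 0.9)
})

test_that("five copies of one metric produce an all-nonsignificant matrix", {
  withr::with_seed(68, {
    x <- runif(40); y <- pmin(100, pmax(0, 60 * x + rnorm(40, 0, 10)))
  })
  f <- fitConstrainedLogistic(x, y)
  fits <- setNames(rep(list(f), 5), c("RMSE", "SSIM", "FSIM", "NQM", "VIF"))
  mat <- iqmPerformanceMatrix(fits)
  expect_true(all(mat[!is.na(mat)] >= 0.05))
})

test_that("summaries tabulate and rank fits", {
  withr::with_seed(69, {
    x <- runif(40)
    yA <- pmin(100, pmax(0, 100 / (1 + exp(-(x - 0.5) / 0.1)) + rnorm(40, 0, 3)))
    yB <- pmin(100, pmax(0, 100 / (1 + exp(-(x - 0.5) / 0.1)) + rnorm(40, 0, 25)))
  })
  fits <- list(good = fitConstrainedLogistic(x, yA),
               bad = fitConstrainedLogistic(x, yB))
  sm <- summarizeFits(fits, "chronic")
  expect_equal(nrow(sm$table), 2)
  expect_equal(sm$rankBySSR[1], "good")
  one <- summarizeFits(fits["good"], "acute")
  expect_equal(nrow(one$table), 1)
  expect_null(one$performance)
})
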