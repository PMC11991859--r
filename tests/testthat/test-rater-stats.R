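test_that("Likert rescaling maps 1..5 onto 0..100", {
  expect_equal(rescaleLikert(1), 0)
  expect_equal(rescaleLikert(3), 50)
  expect_equal(rescaleLikert(5), 100)
  expect_equal(rescaleLikert(c(2, 4)), c(25, 75))
  expect_error(rescaleLikert(0), "1..5")
})

test_that("AC2 is exactly 1 with zero variance for identical raters", {
  withr::with_seed(51, ra <- sample(1:5, 126, replace = TRUE))
  res <- gwetAC2(ra, ra)
  expect_equal(agreementCoef(res), 1)
  expect_equal(res@variance, 0)
  expect_equal(res@ci95, c(1, 1))
})

test_that("AC2 matches the hand-computed 4-item worked example", {
  # a = (1,2,3,4), b = (1,2,3,5), q = 5, quadratic weights:
  # pa = (3 + 15/16)/4 = 63/64
  # pi = (.25,.25,.25,.125,.125); sum pi(1-pi) = 0.78125
  # T_w = 25 - 100/16 = 18.75; pe = 18.75/20 * 0.78125 = 0.732421875
  # AC2 = (63/64 - pe)/(1 - pe) = 0.251953125 / 0.267578125
  res <- gwetAC2(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(agreementCoef(res), 0.251953125 / 0.267578125,
               tolerance = 1e-12)
})

test_that("maximal disagreement drives AC2 negative", {
  expect_lt(agreementCoef(gwetAC2(rep(1, 20), rep(5, 20))), 0)
})

test_that("AC2 is symmetric and invariant to order-preserving relabeling", {
  withr::with_seed(52, {
    a <- sample(1:5, 60, replace = TRUE)
    b <- pmin(5, pmax(1, a + sample(-1:1, 60, replace = TRUE)))
  })
  expect_equal(agreementCoef(gwetAC2(a, b)), agreementCoef(gwetAC2(b, a)))
  relabel <- c(10, 20, 30, 40, 50)
  expect_equal(agreementCoef(gwetAC2(relabel[a], relabel[b],
                                     categories = relabel)),
               agreementCoef(gwetAC2(a, b)), tolerance = 1e-12)
})

test_that("the panel coefficient agrees with the pairwise one for 2 raters", {
  withr::with_seed(53, {
    a <- sample(1:5, 40, replace = TRUE)
    b <- pmin(5, pmax(1, a + sample(-1:1, 40, replace = TRUE)))
  })
  expect_equal(agreementCoef(gwetAC2Panel(cbind(a, b))),
               agreementCoef(gwetAC2(a, b)), tolerance = 1e-12)
  m3 <- cbind(a, b, a)
  expect_true(abs(agreementCoef(gwetAC2Panel(m3))) <= 1)
})

test_that("kurtosis follows its reference values", {
  withr::with_seed(54, x <- rnorm(1e5))
  expect_equal(sampleKurtosis(x), 3, tolerance = 0.05)
  expect_equal(sampleKurtosis(rep(c(-1, 1), 10)), 1)
  # ceiling pile-up: 95% of mass at one category
  pile <- c(rep(5, 95), rep(1, 5))
  expect_gt(sampleKurtosis(pile), 4)
  expect_error(sampleKurtosis(rep(2, 10)), "zero variance")
  expect_error(sampleKurtosis(1:3), "at least 4")
})

test_that("six positive differences give the textbook exact p-value", {
  res <- wilcoxonSignedRank(2:7, 1:6, "greater")
  expect_equal(res$pValue, 1 / 64)
  expect_equal(res$statistic, 21)
  expect_equal(res$method, "exact")
})

test_that("the exact branch matches full sign-pattern enumeration", {
  withr::with_seed(55, {
    for (n in 4:10) {
      a <- sample(1:5, n, replace = TRUE)
      b <- sample(1:5, n, replace = TRUE)
      if (all(a == b)) a[1] <- a[1] %% 5 + 1
      for (alt in c("two.sided", "greater", "less")) {
        expect_equal(wilcoxonSignedRank(a, b, alt)$pValue,
                     enumerateSignedRankP(a, b, alt), tolerance = 1e-12,
                     info = paste(n, alt))
      }
    }
  })
})

test_that("the exact branch agrees with wilcox.test when ties are absent", {
  withr::with_seed(56, {
    a <- rnorm(10); b <- rnorm(10)
  })
  ours <- wilcoxonSignedRank(a, b, "two.sided")
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(ours$pValue, unname(ref$p.value), tolerance = 1e-12)
})

test_that("under the null the approximate branch is not anticonservative", {
  hits <- withr::with_seed(57, {
    sum(replicate(100, {
      a <- rnorm(40); b <- a + rnorm(40)
      wilcoxonSignedRank(a, b)$pValue > 0.05
    }))
  })
  expect_gte(hits, 90)
})

test_that("all-zero differences are rejected as undefined", {
  expect_error(wilcoxonSignedRank(1:5, 1:5), "all differences are zero")
})

test_that("Bonferroni scales and caps p-values and never decreases them", {
  expect_equal(bonferroniAdjust(0.01, 6), 0.06)
  expect_equal(bonferroniAdjust(0.5, 10), 1)
  expect_equal(bonferroniAdjust(0.0007, 6), 0.0042)
  withr::with_seed(58, p <- runif(20))
  expect_true(all(bonferroniAdjust(p, 20) >= p))
  expect_true(all(bonferroniAdjust(p, 20) <= 1))
  expect_error(bonferroniAdjust(c(0.1, 0.2), 1), "at least")
})

test_that("confidenceVsR flags all-identical confidences as degenerate", {
  rt <- expand.grid(subject = paste0("s", 1:6), R = 1:4,
                    rater = c("r1", "r2"), task = "chronic",
                    stringsAsFactors = FALSE)
  rt$answer <- 1L; rt$confidence <- 5L
  cv <- confidenceVsR(rt, "chronic")
  expect_true(all(cv$tests$degenerate))
  expect_true(all(!cv$tests$significant))
  expect_equal(cv$perR$median, rep(5, 4))
})

test_that("confidenceVsR detects a built-in confidence drop", {
  withr::with_seed(59, {
    rt <- expand.grid(subject = paste0("s", 1:9), R = 1:5,
                      rater = c("r1", "r2", "r3"), task = "chronic",
                      stringsAsFactors = FALSE)
    rt$answer <- 1L
    rt$confidence <- pmin(5L, pmax(1L, 5L - (rt$R >= 3) * 2L +
                                     sample(-1:1, nrow(rt), TRUE)))
  })
  cv <- confidenceVsR(rt, "chronic")
  expect_true(all(cv$tests$significant[cv$tests$R >= 3]))
  expect_error(confidenceVsR(rt[rt$R > 1, ], "chronic"), "R = 1")
})
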