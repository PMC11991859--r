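test_that("invalid grades and shapes are rejected", {
  expect_error(generatePhantom("x", 4, seed = 1), "grade")
  expect_error(generatePhantom("x", -1, seed = 1), "grade")
  expect_error(generatePhantom("x", 1, shape = c(32, 64), seed = 1), "shape")
})

test_that("a healthy phantom has empty truth masks", {
  v <- generatePhantom("h1", 0, hasAcute = FALSE, shape = c(64, 64), seed = 2)
  expect_equal(sum(chronicMask(v)), 0)
  expect_equal(sum(acuteMask(v)), 0)
  expect_true(all(imageData(v) >= 0))
})

test_that("phantom generation is deterministic and subject-specific", {
  a <- generatePhantom("s1", 2, TRUE, shape = c(64, 64), seed = 9)
  b <- generatePhantom("s1", 2, TRUE, shape = c(64, 64), seed = 9)
  expect_identical(imageData(a), imageData(b))
  expect_identical(chronicMask(a), chronicMask(b))
  c <- generatePhantom("s2", 2, TRUE, shape = c(64, 64), seed = 9)
  expect_false(identical(imageData(a), imageData(c)))
})

test_that("chronic lesion area strictly increases with grade", {
  for (sd in c(1, 7)) {
    counts <- sapply(0:3, function(g)
      sum(chronicMask(generatePhantom("s1", g, FALSE, seed = sd))))
    expect_true(all(diff(counts) > 0))
    expect_equal(counts[1], 0)
  }
})

test_that("acute lesions are at least twice as conspicuous as chronic ones", {
  base <- generatePhantom("s1", 3, FALSE, seed = 4)
  acute <- generatePhantom("s1", 3, TRUE, seed = 4)
  dAcute <- imageData(acute) - imageData(base)
  expect_gt(max(dAcute), 0.15)
  # chronic added contrast: compare grade-3 against grade-0 of the same
  # subject (same geometry stream)
  none <- generatePhantom("s1", 0, FALSE, seed = 4)
  dChronic <- imageData(base) - imageData(none)
  expect_gte(max(dAcute), 2 * max(dChronic))
})

test_that("simulated k-space matches its DFT oracle and inverts cleanly", {
  v <- generatePhantom("k1", 1, FALSE, shape = c(64, 64), nSlices = 2,
                       seed = 3)
  k <- simulateKspace(v, noiseSD = 0)
  s1 <- imageData(v)[, , 1]
  # DC sample (grid center) equals the sum of slice intensities
  expect_equal(Re(k[33, 33, 1]), sum(s1), tolerance = 1e-9)
  expect_equal(Im(k[33, 33, 1]), 0, tolerance = 1e-9)
  expect_lt(max(Mod(csIQA:::ifft2c(k[, , 1]) - s1)) / max(s1), 1e-9)
})

test_that("k-space noise is seed-dependent with a shared clean component", {
  v <- generatePhantom("k1", 1, FALSE, shape = c(64, 64), nSlices = 1,
                       seed = 3)
  k0 <- simulateKspace(v, noiseSD = 0)
  ka <- simulateKspace(v, noiseSD = 5, seed = 1)
  kb <- simulateKspace(v, noiseSD = 5, seed = 2)
  expect_false(identical(ka, kb))
  # the noise realizations differ but share the clean component
  na <- ka - k0; nb <- kb - k0
  expect_equal(sd(Re(na)), 5, tolerance = 0.2)
  expect_lt(abs(mean(Re(na))), 0.5)
  expect_false(identical(na, nb))
  expect_error(simulateKspace(v, noiseSD = -1), "nonnegative")
})
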