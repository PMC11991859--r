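# a hand-built truth volume: uniform tissue with a known bright lesion block
makeToyTruth <- function(lesionBoost = 0.2, texture = 0.01) {
  n <- 64
  img <- array(0.5, c(n, n, 1))
  withr::with_seed(5, img[, , 1] <- img[, , 1] +
                     matrix(runif(n * n, -texture, texture), n))
  cm <- array(FALSE, c(n, n, 1))
  cm[28:36, 28:36, 1] <- TRUE
  img[, , 1][cm[, , 1]] <- img[, , 1][cm[, , 1]] + lesionBoost
  new("SubjectVolume", subjectID = "toy", image = img,
      voxelSpacing = c(1, 1, 1), acuteMask = array(FALSE, c(n, n, 1)),
      chronicMask = cm, chronicGrade = 2L, hasAcute = FALSE)
}

test_that("conspicuity is contrast over robust band spread", {
  v <- makeToyTruth(lesionBoost = 0.2, texture = 0.01)
  cv <- conspicuity(imageData(v), v, "chronic")
  # contrast 0.2 over a band whose MAD is that of uniform(-0.01, 0.01)
  expect_gt(cv, 10)
  # degrading the image with noise lowers conspicuity
  withr::with_seed(6, noisy <- imageData(v) +
                     array(rnorm(64 * 64, 0, 0.05), c(64, 64, 1)))
  expect_lt(conspicuity(noisy, v, "chronic"), cv / 2)
})

test_that("lesion-free subjects get the fixed reference conspicuity", {
  v <- makeToyTruth()
  expect_equal(conspicuity(imageData(v), v, "acute", refConspicuity = 6), 6)
  expect_equal(conspicuity(imageData(v), v, "acute", refConspicuity = 2), 2)
})

test_that("the Likert score is computable by hand at zero latent noise", {
  v <- makeToyTruth()
  obs <- ObserverModel(raterBias = 0.1, slope = 0.5, noiseSD = 0,
                       thresholds = c(1, 2, 3, 4), acuteFloor = 0)
  cv <- conspicuity(imageData(v), v, "chronic")
  latent <- 0.5 * cv + 0.1
  expect_equal(simulateConfidence(imageData(v), v, "chronic", obs),
               as.integer(min(5, max(1, 1 + sum(latent > c(1, 2, 3, 4))))))
})

test_that("a large acute floor pins the score at 5 for any degradation", {
  v <- makeToyTruth()
  obs <- ObserverModel(slope = 1, noiseSD = 0, thresholds = c(1, 2, 3, 4),
                       acuteFloor = 50)
  withr::with_seed(7, bad <- array(runif(64 * 64, 0, 1), c(64, 64, 1)))
  expect_equal(simulateConfidence(bad, v, "acute", obs), 5L)
  expect_equal(simulateConfidence(imageData(v), v, "acute", obs), 5L)
})

test_that("degradation below the lowest threshold floors the score at 1", {
  v <- makeToyTruth()
  obs <- ObserverModel(raterBias = -1, slope = 1, noiseSD = 0,
                       thresholds = c(1, 2, 3, 4), acuteFloor = 0)
  # wreck the image so measured conspicuity collapses
  withr::with_seed(8, bad <- imageData(v) * 0 + 0.5 +
                     array(rnorm(64 * 64, 0, 0.2), c(64, 64, 1)))
  bad <- pmax(bad, 0)
  expect_equal(simulateConfidence(bad, v, "chronic", obs), 1L)
})

test_that("shape mismatches and invalid models are rejected", {
  v <- makeToyTruth()
  expect_error(conspicuity(array(1, c(32, 32, 1)), v, "chronic"), "shape")
  expect_error(ObserverModel(thresholds = c(3, 2, 1, 0)), "ascending")
  expect_error(ObserverModel(noiseSD = -1), "nonnegative")
})
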