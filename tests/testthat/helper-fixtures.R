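# Shared fixtures, built in code at test time.

# a deterministic 64x64 brain-like slice (cached per session)
fixtureSlice <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- imageData(generatePhantom("fix01", grade = 2,
                                          hasAcute = TRUE,
                                          shape = c(64, 64), nSlices = 1,
                                          seed = 42))[, , 1]
    cache
  }
})

# additive-Gaussian degradations of the fixture slice at increasing noise
noiseSweep <- function(sigmas, seed = 7) {
  ref <- fixtureSlice()
  withr::with_seed(seed, lapply(sigmas, function(s)
    ref + matrix(rnorm(length(ref), 0, s * max(ref)), nrow(ref))))
}

# independently coded sliding-window SSIM oracle (explicit per-window loops)
ssimOracle <- function(x, y, K1 = 0.01, K2 = 0.03, sigma = 1.5, win = 11,
                       L = 1) {
  off <- (win - 1) / 2
  w1 <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  W <- outer(w1, w1); W <- W / sum(W)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- c()
  for (i in (1 + off):(nrow(x) - off)) for (j in (1 + off):(ncol(x) - off)) {
    px <- x[(i - off):(i + off), (j - off):(j + off)]
    py <- y[(i - off):(i + off), (j - off):(j + off)]
    mx <- sum(W * px); my <- sum(W * py)
    vx <- sum(W * px^2) - mx^2; vy <- sum(W * py^2) - my^2
    cxy <- sum(W * px * py) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# brute-force signed-rank p-value by enumerating all 2^n sign patterns
enumerateSignedRankP <- function(a, b, alternative) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  sums <- vapply(0:(2^n - 1), function(bits) {
    signs <- as.logical(bitwAnd(bits, 2^(0:(n - 1))))
    sum(rk[signs])
  }, numeric(1))
  pGE <- mean(sums >= V - 1e-9)
  pLE <- mean(sums <= V + 1e-9)
  switch(alternative,
         greater = pGE, less = pLE,
         two.sided = min(1, 2 * min(pGE, pLE)))
}
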