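## Agreement, Gaussianity, and confidence-versus-acceleration statistics on
## rating records.

#' Rescale a 1--5 Likert score to the 0--100 confidence scale
#'
#' `25 * (s - 1)`: 1 means 0% confidence, 3 means 50%, 5 means 100%.
#'
#' @param s integer vector with values in 1..5.
#' @return numeric vector in 0..100.
#' @export
rescaleLikert <- function(s) {
  if (!all(s %in% 1:5)) stop("Likert scores must lie in 1..5")
  25 * (s - 1)
}

## core of Gwet's weighted agreement coefficient for an n x r rating matrix
.gwetAC2Core <- function(mat, categories) {
  n <- nrow(mat); r <- ncol(mat)
  q <- length(categories)
  if (n < 2) stop("need at least 2 rated items")
  if (!all(mat %in% categories)) stop("ratings outside the category set")
  ki <- matrix(match(mat, categories), n, r)
  kk <- seq_len(q)
  W <- 1 - outer(kk, kk, function(a, b) (a - b)^2) / (q - 1)^2
  ## r_ik: per-item category counts
  rik <- matrix(0, n, q)
  for (j in seq_len(r))
    rik[cbind(seq_len(n), ki[, j])] <- rik[cbind(seq_len(n), ki[, j])] + 1
  rStarIk <- rik %*% W                       # weighted counts
  paI <- rowSums(rik * (rStarIk - 1)) / (r * (r - 1))
  pa <- mean(paI)
  piK <- colMeans(rik / r)
  Tw <- sum(W)
  peFactor <- Tw / (q * (q - 1))
  pe <- peFactor * sum(piK * (1 - piK))
  if (abs(1 - pe) < 1e-12)
    stop("degenerate margin: chance agreement equals 1, AC2 undefined")
  gamma <- (pa - pe) / (1 - pe)
  ## Gwet's linearized variance
  gammaI <- (paI - pe) / (1 - pe)
  peI <- peFactor * as.numeric((rik / r) %*% (1 - piK))
  gammaStar <- gammaI - 2 * (1 - gamma) * (peI - pe) / (1 - pe)
  v <- sum((gammaStar - gamma)^2) / (n * (n - 1))
  new("AgreementResult", ac2 = gamma, variance = v,
      ci95 = gamma + c(-1, 1) * 1.96 * sqrt(max(v, 0)))
}

#' Gwet's quadratic-weighted agreement coefficient (AC2) for two raters
#'
#' Chance-corrected weighted agreement: `AC2 = (pa - pe) / (1 - pe)` with
#' quadratic weights `w_kl = 1 - (k - l)^2 / (q - 1)^2`, observed weighted
#' agreement `pa`, and Gwet's chance term
#' `pe = T_w / (q (q - 1)) * sum_k pi_k (1 - pi_k)` where `pi_k` is the mean
#' propensity of category k and `T_w` the total weight mass.  Unlike kappa it
#' stays stable under strongly skewed marginal distributions.  The variance
#' is Gwet's linearization; the 95% CI is the symmetric normal interval.
#'
#' @param ratingsA,ratingsB equal-length score vectors (length >= 2).
#' @param categories the ordered category set (default 1:5).
#' @return an [AgreementResult-class].
#' @examples
#' gwetAC2(c(1, 2, 3, 4, 5, 5), c(1, 2, 3, 4, 5, 5))  # identical -> 1
#' @export
gwetAC2 <- function(ratingsA, ratingsB, categories = 1:5) {
  if (length(ratingsA) != length(ratingsB)) stop("rating vectors differ in length")
  .gwetAC2Core(cbind(ratingsA, ratingsB), categories)
}

#' Multi-rater Gwet AC2
#'
#' The same coefficient generalized to a panel: rows are items, columns are
#' raters.
#'
#' @param mat integer matrix (items x raters), >= 2 columns.
#' @param categories ordered category set (default 1:5).
#' @return an [AgreementResult-class].
#' @export
gwetAC2Panel <- function(mat, categories = 1:5) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least two raters")
  .gwetAC2Core(mat, categories)
}

#' Non-excess sample kurtosis
#'
#' `m4 / m2^2` with central sample moments (a normal distribution gives 3).
#' Values in [2, 4] are conventionally read as consistent with Gaussianity
#' here; a hard pile-up at one category drives kurtosis far above 4.
#'
#' @param x numeric vector, length >= 4, nonzero variance.
#' @return scalar kurtosis.
#' @export
sampleKurtosis <- function(x) {
  if (length(x) < 4) stop("need at least 4 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance: kurtosis undefined")
  mean((x - m)^4) / m2^2
}

#' Wilcoxon signed-rank test with exact tie-aware reference distribution
#'
#' Paired test on `a - b`.  Zero differences are dropped (Wilcoxon's original
#' convention); tied absolute differences receive average ranks.  For up to
#' `exactLimit` nonzero differences the null distribution of the
#' positive-rank sum is computed exactly by convolution over the (possibly
#' half-integer) ranks, which remains exact under ties; beyond that a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param a,b equal-length paired numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` (a > b), or `"less"`.
#' @param exactLimit maximum n for the exact branch (default 12).
#' @return list with `statistic` (positive-rank sum V), `pValue`, `n`
#'   (nonzero pairs), and `method`.
#' @export
wilcoxonSignedRank <- function(a, b,
                               alternative = c("two.sided", "greater", "less"),
                               exactLimit = 12L) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("paired vectors differ in length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("all differences are zero: the signed-rank test is undefined")
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  if (n <= exactLimit) {
    ## exact distribution of V over the 2^n sign assignments, by convolution
    ## on doubled ranks (integers even under average-rank ties)
    r2 <- round(2 * rk)
    tot <- sum(r2)
    cnt <- numeric(tot + 1)
    cnt[1] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), cnt[seq_len(tot + 1 - r)])
      cnt <- cnt + shifted
    }
    cnt <- cnt / 2^n
    v2 <- round(2 * V)
    pGE <- sum(cnt[(v2 + 1):(tot + 1)])
    pLE <- sum(cnt[1:(v2 + 1)])
    p <- switch(alternative,
                greater = pGE, less = pLE,
                two.sided = min(1, 2 * min(pGE, pLE)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(rk)
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48)
    p <- switch(alternative,
      greater = stats::pnorm((V - mu - 0.5) / sig, lower.tail = FALSE),
      less = stats::pnorm((V - mu + 0.5) / sig),
      two.sided = min(1, 2 * stats::pnorm((abs(V - mu) - 0.5) / sig,
                                          lower.tail = FALSE)))
    method <- "normal-approximation"
  }
  list(statistic = V, pValue = p, n = n, method = method)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` elementwise; `m` defaults to the number of p-values and
#' may be larger (never smaller).
#'
#' @param p p-value vector in [0, 1].
#' @param m number of comparisons.
#' @return adjusted p-values capped at 1.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be at least the number of p-values")
  pmin(1, p * m)
}

#' Pooled confidence versus acceleration factor
#'
#' Pools confidence scores across raters for one task, summarizes each R
#' with boxplot statistics, and tests each undersampled R against the fully
#' sampled reference with the paired Wilcoxon signed-rank test (paired by
#' subject and rater), Bonferroni-corrected over the R > 1 comparisons.
#' Comparisons where every paired difference is zero are undefined for the
#' test and reported as non-significant with `degenerate = TRUE`.
#'
#' @param ratings rating records data.frame (see [StudyDataset-class]).
#' @param task `"chronic"` or `"acute"`.
#' @param alternative passed to [wilcoxonSignedRank()] (default two-sided).
#' @return list with `perR` (boxplot statistics per R) and `tests`
#'   (statistic, raw and adjusted p, significance flag per R > 1).
#' @export
confidenceVsR <- function(ratings, task = c("chronic", "acute"),
                          alternative = "two.sided") {
  task <- match.arg(task)
  rt <- ratings[ratings$task == task, , drop = FALSE]
  if (!any(rt$R == 1)) stop("ratings must include the R = 1 reference")
  Rs <- sort(unique(rt$R))
  perR <- do.call(rbind, lapply(Rs, function(R) {
    v <- rt$confidence[rt$R == R]
    bs <- grDevices::boxplot.stats(v)
    data.frame(R = R, n = length(v), median = bs$stats[3], q1 = bs$stats[2],
               q3 = bs$stats[4], lower = bs$stats[1], upper = bs$stats[5],
               nOutliers = length(bs$out))
  }))
  ref <- rt[rt$R == 1, c("subject", "rater", "confidence")]
  comparisons <- setdiff(Rs, 1L)
  if (length(comparisons) == 0L)
    return(list(perR = perR,
                tests = data.frame(R = integer(), statistic = numeric(),
                                   pRaw = numeric(), degenerate = logical(),
                                   pAdj = numeric(), significant = logical())))
  tests <- do.call(rbind, lapply(comparisons, function(R) {
    cur <- rt[rt$R == R, c("subject", "rater", "confidence")]
    mg <- merge(ref, cur, by = c("subject", "rater"),
                suffixes = c("Ref", "Cur"))
    res <- tryCatch(
      wilcoxonSignedRank(mg$confidenceRef, mg$confidenceCur, alternative),
      error = function(e) NULL)
    if (is.null(res))
      data.frame(R = R, statistic = NA_real_, pRaw = NA_real_,
                 degenerate = TRUE)
    else
      data.frame(R = R, statistic = res$statistic, pRaw = res$pValue,
                 degenerate = FALSE)
  }))
  tests$pAdj <- ifelse(tests$degenerate, NA_real_,
                       bonferroniAdjust(ifelse(tests$degenerate, 1,
                                               tests$pRaw),
                                        length(comparisons)))
  tests$significant <- !tests$degenerate & !is.na(tests$pAdj) &
    tests$pAdj < 0.05
  list(perR = perR, tests = tests)
}
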