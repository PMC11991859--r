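## Subjective-versus-objective correlation: constrained logistic regression
## of 0--100 confidence on metric scores, Spearman correlation, and the
## residual-based pairwise metric performance matrix.

#' Spearman rank-order correlation coefficient
#'
#' Pearson correlation of average-ranked values (tie-aware).
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return scalar in [-1, 1] (NA if either vector is constant).
#' @export
srocc <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 3) stop("need at least 3 points")
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

.logistic4 <- function(beta, x)
  beta[1] + (beta[2] - beta[1]) / (1 + exp(-(x - beta[3]) / beta[4]))

#' Fit a constrained logistic regression of confidence on metric scores
#'
#' Model `y = b1 + (b2 - b1) / (1 + exp(-(x - b3)/b4))` by bounded nonlinear
#' least squares: asymptotes `b1, b2` constrained to the 0--100 confidence
#' scale, and the slope sign of `b4` fixed by the sign of the Spearman
#' correlation of the data so the curve is monotone in the empirically
#' observed direction.  Five deterministic initializations are polished with
#' L-BFGS-B and the lowest-SSR solution kept, making the fit deterministic.
#' A zero-variance response yields the flat fit with a warning (SROCC
#' undefined).
#'
#' @param x metric scores per (series, rater) point, nonconstant, >= 5.
#' @param y confidence on the 0--100 scale, same length.
#' @return a [LogisticFit-class].
#' @examples
#' x <- seq(0, 1, length.out = 50)
#' y <- 100 / (1 + exp(-(x - 0.5) / 0.1))
#' fitConstrainedLogistic(x, y)
#' @export
fitConstrainedLogistic <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 5) stop("need at least 5 points")
  if (stats::sd(x) == 0) stop("x has zero spread; nothing to regress on")
  if (stats::sd(y) == 0) {
    warning("response has zero variance: returning the flat fit; ",
            "SROCC undefined")
    res <- numeric(length(y))
    return(new("LogisticFit",
               beta = c(lower = y[1], upper = y[1],
                        inflection = stats::median(x), scale = diff(range(x))),
               ssr = 0, srocc = NA_real_, signedResiduals = res,
               absResiduals = res, residualKurtosis = NA_real_))
  }
  rho <- srocc(x, y)
  dirPos <- is.na(rho) || rho >= 0
  rg <- diff(range(x))
  sBounds <- if (dirPos) c(rg * 1e-3, rg * 20) else c(-rg * 20, -rg * 1e-3)
  lower <- c(0, 0, min(x) - 2 * rg, min(sBounds))
  upper <- c(100, 100, max(x) + 2 * rg, max(sBounds))
  obj <- function(b) sum((y - .logistic4(b, x))^2)
  qx <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  s0 <- if (dirPos) rg / 4 else -rg / 4
  starts <- list(
    c(max(0, min(y)), min(100, max(y)), qx[2], s0),
    c(max(0, min(y)), min(100, max(y)), qx[1], s0 / 2),
    c(max(0, min(y)), min(100, max(y)), qx[3], s0 * 2),
    c(0, 100, qx[2], s0),
    c(mean(y) - stats::sd(y), min(100, mean(y) + stats::sd(y)), qx[2], s0 / 4))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500, factr = 10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  ## polish from the winner
  fit <- tryCatch(
    stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 1000, factr = 1)),
    error = function(e) best)
  if (fit$value > best$value) fit <- best
  res <- y - .logistic4(fit$par, x)
  kur <- if (stats::sd(res) > 0) sampleKurtosis(res) else NA_real_
  new("LogisticFit",
      beta = stats::setNames(fit$par,
                             c("lower", "upper", "inflection", "scale")),
      ssr = fit$value, srocc = rho, signedResiduals = res,
      absResiduals = abs(res), residualKurtosis = kur)
}

#' Pairwise metric performance matrix from fit residuals
#'
#' For every ordered pair of metrics, a one-sided Wilcoxon signed-rank test
#' of whether the row metric's absolute fit residuals are smaller than the
#' column metric's (the residual vectors must be paired on the same
#' (series, rater) index), Bonferroni-adjusted over all ordered pairs
#' (m = 20 for five metrics).  A significant cell means the row metric
#' tracks confidence better than the column metric.  Identical residual
#' vectors give adjusted p = 1.
#'
#' @param fits named list of [LogisticFit-class] objects, equal lengths.
#' @param m correction count (default: number of ordered pairs).
#' @return matrix of adjusted p-values with NA diagonal.
#' @export
iqmPerformanceMatrix <- function(fits, m = length(fits) * (length(fits) - 1)) {
  k <- length(fits)
  if (k < 2) stop("need at least two fitted metrics")
  lens <- vapply(fits, function(f) length(f@absResiduals), integer(1))
  if (length(unique(lens)) != 1)
    stop("fits are not paired: residual vectors differ in length")
  nm <- names(fits)
  out <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    ri <- fits[[i]]@absResiduals; rj <- fits[[j]]@absResiduals
    p <- tryCatch(wilcoxonSignedRank(ri, rj, "less")$pValue,
                  error = function(e) 1)  # all-zero differences: no evidence
    out[i, j] <- min(1, p * m)
  }
  out
}

#' Summarize fits per metric and rank metric performance
#'
#' Tabulates SSR, residual kurtosis and SROCC per metric and emits the two
#' rank orders (ascending SSR; descending |SROCC|), plus the pairwise
#' residual performance matrix.
#'
#' @param fits named list of [LogisticFit-class] objects (one per metric).
#' @param task label recorded in the output.
#' @return list with `table` (data.frame), `rankBySSR`, `rankBySROCC`,
#'   and `performance` (adjusted p matrix, NULL for a single metric).
#' @export
summarizeFits <- function(fits, task = "") {
  if (length(fits) < 1) stop("need at least one fit")
  tab <- data.frame(
    task = task, metric = names(fits),
    ssr = vapply(fits, fitSSR, numeric(1)),
    residualKurtosis = vapply(fits, function(f) f@residualKurtosis,
                              numeric(1)),
    srocc = vapply(fits, fitSROCC, numeric(1)),
    row.names = NULL)
  list(table = tab,
       rankBySSR = tab$metric[order(tab$ssr)],
       rankBySROCC = tab$metric[order(-abs(tab$srocc))],
       performance = if (length(fits) >= 2) iqmPerformanceMatrix(fits)
                     else NULL)
}
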