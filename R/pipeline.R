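## End-to-end orchestration: study generation -> agreement gate ->
## confidence-versus-R statistics -> constrained-logistic correlation
## summary, plus a plain-text report.

#' Regression points for one task and metric
#'
#' Joins per-series aggregated metric scores (undersampled R only) with the
#' per-(series, rater) 0--100 confidence scores, the point set the logistic
#' model is fit to.
#'
#' @param study a [StudyDataset-class] with IQM records.
#' @param task `"chronic"` or `"acute"`.
#' @param metric one of the battery metric names.
#' @param aggregate slice reduction, `"mean"` or `"median"`.
#' @return data.frame with columns `subject`, `R`, `rater`, `x` (metric),
#'   `y` (confidence 0--100).
#' @export
regressionPoints <- function(study, task = c("chronic", "acute"),
                             metric = "SSIM", aggregate = "mean") {
  task <- match.arg(task)
  agg <- aggregateSeries(iqmRecords(study), aggregate)
  agg <- agg[agg$metric == metric, c("subject", "R", "value")]
  rt <- ratings(study)
  rt <- rt[rt$task == task & rt$R > 1,
           c("subject", "R", "rater", "confidence")]
  mg <- merge(rt, agg, by = c("subject", "R"))
  data.frame(subject = mg$subject, R = mg$R, rater = mg$rater,
             x = mg$value, y = rescaleLikert(mg$confidence))
}

#' Pairwise and panel agreement for both tasks
#'
#' @param study a [StudyDataset-class] (or a ratings data.frame).
#' @return nested list: per task, the three pairwise [AgreementResult-class]
#'   objects, the panel coefficient, and the minimum pairwise AC2.
#' @export
studyAgreement <- function(study) {
  rt <- if (is(study, "StudyDataset")) ratings(study) else study
  out <- list()
  for (task in c("chronic", "acute")) {
    sub <- rt[rt$task == task, c("subject", "R", "rater", "confidence")]
    wide <- stats::reshape(sub, idvar = c("subject", "R"),
                           timevar = "rater", direction = "wide")
    mat <- as.matrix(wide[, -(1:2), drop = FALSE])
    raters <- sub("^confidence\\.", "", colnames(mat))
    pairs <- utils::combn(ncol(mat), 2, simplify = FALSE)
    pw <- lapply(pairs, function(p) gwetAC2(mat[, p[1]], mat[, p[2]]))
    names(pw) <- vapply(pairs, function(p)
      paste(raters[p[1]], raters[p[2]], sep = "-"), character(1))
    out[[task]] <- list(
      pairwise = pw,
      panel = gwetAC2Panel(mat),
      minPairwise = min(vapply(pw, agreementCoef, numeric(1))))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a study, then computes: inter-rater agreement per
#' task with the AC2 > 0.80 pooling gate, pooled confidence-versus-R boxplot
#' statistics and Bonferroni-corrected Wilcoxon tests, pooled-confidence
#' kurtosis per task, and — when undersampled metric records exist — the
#' constrained-logistic fit, SROCC, residual kurtosis and pairwise
#' performance matrix per metric and task.  With `RValues = {1}` only, the
#' correlation stage is skipped with a message (no undersampled points
#' exist).
#'
#' @param study a [StudyDataset-class], or NULL to generate one from
#'   `manifest`.
#' @param manifest list of [generateStudy()] arguments (at least `seed`).
#' @param verbose emit stage messages (default TRUE)?
#' @return list bundle: `study`, `agreement`, `confidence` (per task),
#'   `kurtosis` (per task), `fits`, `summaries` (per task), `pooled`
#'   (logical pooling gate per task).
#' @export
runPipeline <- function(study = NULL, manifest = list(seed = 1L),
                        verbose = TRUE) {
  say <- function(...) if (verbose) message("[csIQA] ", ...)
  if (is.null(study)) {
    say("generating study (seed ", manifest$seed, ")")
    study <- do.call(generateStudy, manifest)
  }
  rt <- ratings(study)
  say("computing inter-rater agreement")
  agreement <- studyAgreement(study)
  pooled <- vapply(agreement, function(a) a$minPairwise > 0.80, logical(1))
  for (task in names(pooled))
    say(sprintf("%s task: min pairwise AC2 = %.3f (pooling %s)", task,
                agreement[[task]]$minPairwise,
                if (pooled[task]) "allowed" else "NOT justified"))
  say("confidence versus acceleration")
  confidence <- list(chronic = confidenceVsR(rt, "chronic"),
                     acute = confidenceVsR(rt, "acute"))
  kurt <- vapply(c(chronic = "chronic", acute = "acute"), function(task)
    tryCatch(sampleKurtosis(rt$confidence[rt$task == task]),
             error = function(e) NA_real_), numeric(1))
  fits <- NULL; summaries <- NULL
  if (length(setdiff(study@RValues, 1L)) == 0L) {
    say("no undersampled series: correlation stage skipped")
  } else if (nrow(iqmRecords(study)) == 0L) {
    say("no IQM records in the study: correlation stage skipped")
  } else {
    metrics <- sort(unique(iqmRecords(study)$metric))
    fits <- list(); summaries <- list()
    for (task in c("chronic", "acute")) {
      say("fitting constrained logistic models (", task, " task)")
      taskFits <- lapply(stats::setNames(metrics, metrics), function(met) {
        pts <- regressionPoints(study, task, met)
        suppressWarnings(fitConstrainedLogistic(pts$x, pts$y))
      })
      fits[[task]] <- taskFits
      summaries[[task]] <- summarizeFits(taskFits, task)
    }
  }
  list(study = study, agreement = agreement, confidence = confidence,
       kurtosis = kurt, fits = fits, summaries = summaries, pooled = pooled)
}

#' Human-readable summary of a pipeline bundle
#'
#' Prints the agreement table, per-R confidence statistics with adjusted
#' p-values, and (when present) the per-metric fit summary and pairwise
#' performance matrix for each task.
#'
#' @param bundle list from [runPipeline()].
#' @return the bundle, invisibly.
#' @export
studyReport <- function(bundle) {
  cat("== Inter-rater agreement (Gwet AC2, quadratic weights) ==\n")
  for (task in names(bundle$agreement)) {
    a <- bundle$agreement[[task]]
    cat(sprintf(" %s task: panel %.3f | pairwise:", task,
                agreementCoef(a$panel)))
    for (nm in names(a$pairwise))
      cat(sprintf(" %s %.3f", nm, agreementCoef(a$pairwise[[nm]])))
    cat("\n")
  }
  cat("\n== Pooled confidence versus R ==\n")
  for (task in names(bundle$confidence)) {
    cv <- bundle$confidence[[task]]
    cat(sprintf(" %s task (pooled kurtosis %.1f):\n", task,
                bundle$kurtosis[[task]]))
    tab <- merge(cv$perR, cv$tests, by = "R", all.x = TRUE)
    for (i in seq_len(nrow(tab)))
      cat(sprintf("  R=%d median %.1f [%.1f, %.1f]%s\n", tab$R[i],
                  tab$median[i], tab$q1[i], tab$q3[i],
                  if (is.na(tab$pAdj[i])) ""
                  else sprintf(" adj p = %.4g%s", tab$pAdj[i],
                               if (isTRUE(tab$significant[i])) " *" else "")))
  }
  if (!is.null(bundle$summaries)) {
    for (task in names(bundle$summaries)) {
      sm <- bundle$summaries[[task]]
      cat(sprintf("\n== Metric fits (%s task) ==\n", task))
      print(sm$table, row.names = FALSE, digits = 3)
      cat(" rank by SSR:  ", paste(sm$rankBySSR, collapse = " > "), "\n")
      cat(" rank by SROCC:", paste(sm$rankBySROCC, collapse = " > "), "\n")
      if (!is.null(sm$performance)) {
        cat(" pairwise residual test (row better than column, adj p):\n")
        print(round(sm$performance, 4))
      }
    }
  }
  invisible(bundle)
}
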