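## Accessor generics and show methods.

#' @describeIn SubjectVolume number of slices
#' @param object,x a SubjectVolume
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @export
setMethod("nSlices", "SubjectVolume", function(x) dim(x@image)[3])

#' @describeIn SubjectVolume the intensity array (rows x cols x slices)
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @export
setMethod("imageData", "SubjectVolume", function(x) x@image)

#' @describeIn SubjectVolume logical acute-lesion truth mask
#' @export
setGeneric("acuteMask", function(x) standardGeneric("acuteMask"))
#' @export
setMethod("acuteMask", "SubjectVolume", function(x) x@acuteMask)

#' @describeIn SubjectVolume logical chronic-lesion truth mask
#' @export
setGeneric("chronicMask", function(x) standardGeneric("chronicMask"))
#' @export
setMethod("chronicMask", "SubjectVolume", function(x) x@chronicMask)

#' @describeIn SubjectVolume ordinal chronic lesion burden grade (0--3)
#' @export
setGeneric("chronicGrade", function(x) standardGeneric("chronicGrade"))
#' @export
setMethod("chronicGrade", "SubjectVolume", function(x) x@chronicGrade)

#' @describeIn SubjectVolume subject identifier
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @export
setMethod("subjectID", "SubjectVolume", function(x) x@subjectID)

#' @describeIn SubjectVolume TRUE if the subject carries an acute lesion
#' @export
setGeneric("hasAcute", function(x) standardGeneric("hasAcute"))
#' @export
setMethod("hasAcute", "SubjectVolume", function(x) x@hasAcute)

setMethod("show", "SubjectVolume", function(object) {
  d <- dim(object@image)
  cat("SubjectVolume '", object@subjectID, "': ", d[1], "x", d[2], " x ",
      d[3], " slices\n", sep = "")
  cat("  chronic grade:", object@chronicGrade,
      "| acute lesion:", object@hasAcute, "\n")
  cat("  chronic/acute mask voxels:", sum(object@chronicMask), "/",
      sum(object@acuteMask), "\n")
})

#' @describeIn SamplingMask logical acquired-line vector
#' @param x,object a SamplingMask
#' @export
setGeneric("maskLines", function(x) standardGeneric("maskLines"))
#' @export
setMethod("maskLines", "SamplingMask", function(x) x@lines)

#' @describeIn SamplingMask realized acceleration `nPE / #acquired`
#' @export
setGeneric("realizedR", function(x) standardGeneric("realizedR"))
#' @export
setMethod("realizedR", "SamplingMask", function(x) x@RRealized)

setMethod("show", "SamplingMask", function(object) {
  cat("SamplingMask: ", sum(object@lines), "/", length(object@lines),
      " phase-encode lines (R nominal ", object@spec@RNominal,
      ", realized ", round(object@RRealized, 3), ")\n", sep = "")
})

setMethod("show", "ReconResult", function(object) {
  tr <- object@objectiveTrace
  cat("ReconResult: ", nrow(object@image), "x", ncol(object@image),
      " magnitude image; ", object@nIter, " iterations (converged: ",
      object@converged, ")\n", sep = "")
  if (length(tr))
    cat("  objective ", signif(tr[1], 6), " -> ", signif(tr[length(tr)], 6),
        "\n", sep = "")
})

#' @describeIn StudyDataset rating records data.frame
#' @param x,object a StudyDataset
#' @export
setGeneric("ratings", function(x) standardGeneric("ratings"))
#' @export
setMethod("ratings", "StudyDataset", function(x) x@ratings)

#' @describeIn StudyDataset per-slice image-quality metric records
#' @export
setGeneric("iqmRecords", function(x) standardGeneric("iqmRecords"))
#' @export
setMethod("iqmRecords", "StudyDataset", function(x) x@iqm)

#' @describeIn StudyDataset list of SubjectVolume objects
#' @export
setGeneric("studySubjects", function(x) standardGeneric("studySubjects"))
#' @export
setMethod("studySubjects", "StudyDataset", function(x) x@subjects)

setMethod("show", "StudyDataset", function(object) {
  cat("StudyDataset:", length(object@subjects), "subjects x R in {",
      paste(object@RValues, collapse = ","), "} x",
      length(unique(object@ratings$rater)), "raters\n")
  cat("  ", nrow(object@ratings), "rating records;",
      nrow(object@iqm), "IQM records; seed", object@seed, "\n")
})

#' @describeIn AgreementResult the agreement coefficient
#' @param x,object an AgreementResult
#' @export
setGeneric("agreementCoef", function(x) standardGeneric("agreementCoef"))
#' @export
setMethod("agreementCoef", "AgreementResult", function(x) x@ac2)

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("Gwet AC2 = %.3f (95%% CI %.3f to %.3f)\n", object@ac2,
              object@ci95[1], object@ci95[2]))
})

#' @describeIn LogisticFit fitted parameter vector
#' @param x,object a LogisticFit
#' @export
setGeneric("fitBeta", function(x) standardGeneric("fitBeta"))
#' @export
setMethod("fitBeta", "LogisticFit", function(x) x@beta)

#' @describeIn LogisticFit sum of squared residuals
#' @export
setGeneric("fitSSR", function(x) standardGeneric("fitSSR"))
#' @export
setMethod("fitSSR", "LogisticFit", function(x) x@ssr)

#' @describeIn LogisticFit Spearman rank-order correlation
#' @export
setGeneric("fitSROCC", function(x) standardGeneric("fitSROCC"))
#' @export
setMethod("fitSROCC", "LogisticFit", function(x) x@srocc)

#' @describeIn LogisticFit signed residual vector
#' @export
setGeneric("fitResiduals", function(x) standardGeneric("fitResiduals"))
#' @export
setMethod("fitResiduals", "LogisticFit", function(x) x@signedResiduals)

setMethod("show", "LogisticFit", function(object) {
  cat("Constrained logistic fit:\n")
  cat(sprintf("  beta = (%.3f, %.3f, %.4g, %.4g)\n", object@beta[1],
              object@beta[2], object@beta[3], object@beta[4]))
  cat(sprintf("  SSR = %.4g | SROCC = %.3f | residual kurtosis = %.2f\n",
              object@ssr, object@srocc, object@residualKurtosis))
})
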