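## Formats and serialization: NIfTI volumes, rating/IQM CSV tables with
## schema validation, JSON study manifests.

#' Read an image volume
#'
#' Reads a 3D magnitude volume from NIfTI (via RNifti) or accepts an
#' in-memory numeric array (`format = "array"`).  Returns the intensity grid
#' and voxel spacing.  DICOM series input is not supported by this build;
#' convert to NIfTI first.
#'
#' @param path file path (NIfTI) or a numeric array (`format = "array"`).
#' @param format `"nifti"` or `"array"`.
#' @param voxelSpacing spacing override for array input (mm per axis).
#' @return list with `image` (3D array) and `voxelSpacing`.
#' @export
readVolume <- function(path, format = c("nifti", "array"),
                       voxelSpacing = c(1, 1, 1)) {
  format <- match.arg(format)
  if (format == "array") {
    img <- path
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    if (length(dim(img)) != 3L) stop("array input must be 2D or 3D")
    return(list(image = unclass(img), voxelSpacing = voxelSpacing))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  nim <- RNifti::readNifti(path)
  img <- as.array(nim)
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  sp <- RNifti::pixdim(nim)
  if (length(sp) < 3L || any(sp[1:3] <= 0))
    stop("volume is missing valid voxel spacing")
  list(image = img, voxelSpacing = sp[1:3])
}

#' Write a volume (or SubjectVolume image stack) as NIfTI
#'
#' @param vol a [SubjectVolume-class] or 3D numeric array.
#' @param path output file path (`.nii` / `.nii.gz`).
#' @param voxelSpacing spacing for plain arrays (ignored for SubjectVolume).
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path, voxelSpacing = c(1, 1, 1)) {
  if (is(vol, "SubjectVolume")) {
    img <- vol@image
    voxelSpacing <- vol@voxelSpacing
  } else img <- vol
  nim <- RNifti::asNifti(img)
  RNifti::pixdim(nim) <- voxelSpacing
  RNifti::writeNifti(nim, path)
  invisible(path)
}

.ratingsSchema <- c("subject", "R", "rater", "task", "answer", "confidence")
.iqmSchema <- c("subject", "R", "slice", "metric", "value")

#' Write / read rating records as CSV
#'
#' Schema: `subject,R,rater,task,answer,confidence`.  The reader validates
#' the header and value ranges.
#'
#' @param ratings rating records data.frame.
#' @param path CSV path.
#' @return `writeRatingsCSV`: the path, invisibly; `readRatingsCSV`: the
#'   validated data.frame.
#' @export
writeRatingsCSV <- function(ratings, path) {
  stopifnot(all(.ratingsSchema %in% names(ratings)))
  utils::write.csv(ratings[, .ratingsSchema], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRatingsCSV
#' @export
readRatingsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .ratingsSchema))
    stop("ratings CSV has schema (", paste(names(df), collapse = ","),
         "); expected (", paste(.ratingsSchema, collapse = ","), ")")
  if (!all(df$confidence %in% 1:5)) stop("confidence outside 1..5")
  if (!all(df$task %in% c("chronic", "acute"))) stop("unknown task labels")
  df
}

#' Write / read per-slice IQM records as CSV
#'
#' Schema: `subject,R,slice,metric,value` (the NQM identical-input sentinel
#' `Inf` round-trips).
#'
#' @param records IQM records data.frame.
#' @param path CSV path.
#' @return `writeIQMCSV`: the path, invisibly; `readIQMCSV`: the validated
#'   data.frame.
#' @export
writeIQMCSV <- function(records, path) {
  stopifnot(all(.iqmSchema %in% names(records)))
  utils::write.csv(records[, .iqmSchema], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIQMCSV
#' @export
readIQMCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .iqmSchema))
    stop("IQM CSV has schema (", paste(names(df), collapse = ","),
         "); expected (", paste(.iqmSchema, collapse = ","), ")")
  df
}

#' Write / read the study manifest as JSON
#'
#' The manifest (seed plus every generation parameter) is sufficient to
#' regenerate the whole study bit-identically with [generateStudy()].
#'
#' @param study a [StudyDataset-class] (or a manifest list for the writer).
#' @param path JSON path.
#' @return `writeManifest`: the path, invisibly; `readManifest`: the
#'   manifest list.
#' @export
writeManifest <- function(study, path) {
  manifest <- if (is(study, "StudyDataset"))
    c(list(seed = study@seed,
           version = as.character(utils::packageVersion("csIQA"))),
      study@params)
  else study
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
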