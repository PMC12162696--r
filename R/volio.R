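## NIfTI, lookup-table and clinical-table I/O. Volumes are stored as
## NIfTI-1; the lookup table travels as JSON beside the label image; the
## clinical table is plain CSV with a fixed dialect.

.checkNiftiArray <- function(img, path) {
  d <- dim(img)
  if (length(d) != 3L)
    stop("'", path, "' is not a 3-D image (dims: ",
         paste(d, collapse = " x "), ")", call. = FALSE)
  vs <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vs)) || any(vs <= 0))
    stop("'", path, "' has non-positive voxel sizes", call. = FALSE)
  list(values = array(as.numeric(img), dim = d), voxelSize = as.numeric(vs))
}

#' Read and write scalar brain volumes
#'
#' `readVolume()` loads a 3-D NIfTI-1 file into a [BrainVolume], taking
#' voxel sizes from the header; `writeVolume()` writes one back. Data
#' round-trip bit-exactly for integer-valued arrays and to float precision
#' otherwise.
#'
#' @param path a NIfTI-1 file (`.nii` or `.nii.gz`)
#' @param mirrorAxis axis implementing the left/right reflection (default 1)
#' @param units units tag for the values, see [BrainVolume()]
#' @param x a [BrainVolume]
#' @return `readVolume()` a [BrainVolume]; `writeVolume()` the path,
#'   invisibly.
#' @export
readVolume <- function(path, mirrorAxis = 1L, units = "activity") {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  nd <- .checkNiftiArray(RNifti::readNifti(path), path)
  BrainVolume(nd$values, nd$voxelSize, mirrorAxis = mirrorAxis,
              units = units)
}

#' @rdname readVolume
#' @export
writeVolume <- function(x, path) {
  stopifnot(is(x, "BrainVolume"))
  img <- RNifti::asNifti(x@values)
  RNifti::pixdim(img) <- voxelSize(x)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are stored as NIfTI volumes; any nonzero voxel is `TRUE` on read.
#'
#' @param path a NIfTI-1 file
#' @param mirrorAxis mirror axis, as in [readVolume()]
#' @param x a [BrainMask]
#' @return `readMask()` a [BrainMask]; `writeMask()` the path, invisibly.
#' @export
readMask <- function(path, mirrorAxis = 1L) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  nd <- .checkNiftiArray(RNifti::readNifti(path), path)
  BrainMask(nd$values != 0, nd$voxelSize, mirrorAxis = mirrorAxis)
}

#' @rdname readMask
#' @export
writeMask <- function(x, path) {
  stopifnot(is(x, "BrainMask"))
  img <- RNifti::asNifti(array(as.integer(x@values), dim = dim(x)))
  RNifti::pixdim(img) <- voxelSize(x)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read and write a label atlas (NIfTI labels + JSON lookup table)
#'
#' @param labelsPath NIfTI file of integer labels (0 = background)
#' @param lutPath JSON file: an array of objects with fields `label`,
#'   `region`, `lobe`, `hemisphere`
#' @param mirrorAxis mirror axis, as in [readVolume()]
#' @param x a [BrainAtlas]
#' @return `readAtlas()` a [BrainAtlas]; `writeAtlas()` invisibly, the paths.
#' @export
readAtlas <- function(labelsPath, lutPath, mirrorAxis = 1L) {
  if (!file.exists(labelsPath))
    stop("no such file: '", labelsPath, "'", call. = FALSE)
  if (!file.exists(lutPath))
    stop("no such file: '", lutPath, "'", call. = FALSE)
  nd <- .checkNiftiArray(RNifti::readNifti(labelsPath), labelsPath)
  lut <- jsonlite::fromJSON(lutPath)
  BrainAtlas(round(nd$values), lut, nd$voxelSize, mirrorAxis = mirrorAxis)
}

#' @rdname readAtlas
#' @export
writeAtlas <- function(x, labelsPath, lutPath) {
  stopifnot(is(x, "BrainAtlas"))
  img <- RNifti::asNifti(x@labels)
  RNifti::pixdim(img) <- voxelSize(x)
  RNifti::writeNifti(img, labelsPath, datatype = "int16")
  jsonlite::write_json(atlasLut(x), lutPath, auto_unbox = FALSE,
                       digits = NA)
  invisible(c(labelsPath, lutPath))
}

.clinicalCols <- c("subject_id", "affected_side", "nihss", "mrs", "timepoint")

#' Read, validate and write the per-subject clinical table
#'
#' The table is comma-separated UTF-8 with a header and columns
#' `subject_id`, `affected_side` (`L`/`R`), `nihss` (integer 0-42), `mrs`
#' (integer 0-6) and `timepoint` (`pre`/`post`). Score ranges are enforced
#' and duplicate (subject_id, timepoint) rows rejected.
#'
#' @param path CSV file
#' @param x a data.frame with the columns above
#' @return a validated data.frame of subject records (possibly 0 rows)
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0 && ncol(raw) <= 1 && !all(.clinicalCols %in% names(raw)))
    return(validateClinicalTable(
      stats::setNames(data.frame(character(), character(), integer(),
                                 integer(), character()), .clinicalCols)))
  validateClinicalTable(raw)
}

#' @rdname readClinicalTable
#' @export
validateClinicalTable <- function(x) {
  miss <- setdiff(.clinicalCols, names(x))
  if (length(miss))
    stop("clinical table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- x[.clinicalCols]
  x$nihss <- as.integer(x$nihss)
  x$mrs <- as.integer(x$mrs)
  if (nrow(x)) {
    if (!all(x$affected_side %in% c("L", "R")))
      stop("affected_side must be 'L' or 'R'", call. = FALSE)
    if (!all(x$timepoint %in% c("pre", "post")))
      stop("timepoint must be 'pre' or 'post'", call. = FALSE)
    if (anyNA(x$nihss) || any(x$nihss < 0 | x$nihss > 42))
      stop("nihss must be an integer in 0..42", call. = FALSE)
    if (anyNA(x$mrs) || any(x$mrs < 0 | x$mrs > 6))
      stop("mrs must be an integer in 0..6", call. = FALSE)
    if (anyDuplicated(x[c("subject_id", "timepoint")]))
      stop("duplicate (subject_id, timepoint) rows", call. = FALSE)
  }
  rownames(x) <- NULL
  x
}

#' @rdname readClinicalTable
#' @param path output CSV file
#' @export
writeClinicalTable <- function(x, path) {
  x <- validateClinicalTable(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
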