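## S4 containers for the voxel-wise asymmetry pipeline. All gridded objects
## share the BrainGrid contract: voxel dimensions in mm plus the axis whose
## index reversal implements the left<->right reflection.

#' @rdname gridAccessors
#' @name gridAccessors
#' @title Grid geometry accessors
#' @description `voxelSize()` returns the voxel dimensions in mm,
#'   `mirrorAxis()` the axis (1-based) whose reversal reflects left/right.
#' @param x a gridded object
NULL

setClass("BrainGrid", representation("VIRTUAL",
  voxelSize  = "numeric",
  mirrorAxis = "integer"
))

setValidity("BrainGrid", function(object) {
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive finite values (mm)")
  if (length(object@mirrorAxis) != 1L || is.na(object@mirrorAxis) ||
      !object@mirrorAxis %in% 1:3)
    return("mirrorAxis must be 1, 2 or 3")
  TRUE
})

#' BrainVolume: a 3-D scalar brain volume
#'
#' Holds PET activity (kBq/mL), SUVR or arbitrary scalar values on a regular
#' grid, together with voxel dimensions and the mirror-axis convention.
#'
#' @param values numeric 3-D array
#' @param voxelSize numeric(3), voxel dimensions in mm
#' @param mirrorAxis integer in 1..3; reversal of this axis is the
#'   left/right reflection (default 1, the first spatial axis)
#' @param units one of `"activity"` (kBq/mL), `"SUVR"`, `"arbitrary"`
#' @param x a `BrainVolume`
#' @return `BrainVolume()` returns a validated object; `volumeData()` the
#'   raw array; `volumeUnits()` the units tag.
#' @examples
#' v <- BrainVolume(array(1, c(4, 4, 4)), voxelSize = c(2, 2, 2))
#' voxelVolumeMl(v)
#' @aliases BrainVolume-class volumeData volumeUnits
#' @export BrainVolume
#' @exportClass BrainVolume
setClass("BrainVolume", contains = "BrainGrid", representation(
  values = "array",
  units  = "character"
))

setValidity("BrainVolume", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a 3-D array")
  if (!is.numeric(object@values))
    return("values must be numeric")
  if (length(object@units) != 1L ||
      !object@units %in% c("activity", "SUVR", "arbitrary"))
    return("units must be one of 'activity', 'SUVR', 'arbitrary'")
  TRUE
})

BrainVolume <- function(values, voxelSize, mirrorAxis = 1L,
                        units = "arbitrary") {
  new("BrainVolume", values = as.array(values),
      voxelSize = as.numeric(voxelSize),
      mirrorAxis = as.integer(mirrorAxis), units = units)
}

#' BrainMask: a binary mask on the pipeline grid
#'
#' @param values logical 3-D array (numeric input is binarised as `!= 0`)
#' @param voxelSize numeric(3) voxel dimensions in mm
#' @param mirrorAxis integer in 1..3
#' @param x a `BrainMask`
#' @return `BrainMask()` a validated object; `maskData()` the logical array.
#' @aliases BrainMask-class maskData
#' @export BrainMask
#' @exportClass BrainMask
setClass("BrainMask", contains = "BrainGrid", representation(
  values = "array"
))

setValidity("BrainMask", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a 3-D array")
  if (!is.logical(object@values))
    return("values must be logical")
  if (anyNA(object@values))
    return("mask values must be TRUE/FALSE, not NA")
  TRUE
})

BrainMask <- function(values, voxelSize, mirrorAxis = 1L) {
  v <- as.array(values)
  if (!is.logical(v)) {
    storage.mode(v) <- "double"
    v <- array(v != 0, dim = dim(v))
  }
  new("BrainMask", values = v, voxelSize = as.numeric(voxelSize),
      mirrorAxis = as.integer(mirrorAxis))
}

#' BrainAtlas: an integer label map with a region lookup table
#'
#' The lookup table maps each nonzero label to a region name, a lobe
#' (`FL`, `TL`, `PL`, `OL` or `other`) and a hemisphere (`L`, `R` or
#' `midline`). A valid atlas is left/right symmetric: reflecting the label
#' array and swapping `L`/`R` labels in the table reproduces the original
#' array (see [mirror()]).
#'
#' @param labels integer 3-D array; 0 = background
#' @param lut data.frame with columns `label`, `region`, `lobe`, `hemisphere`
#' @param voxelSize numeric(3) mm
#' @param mirrorAxis integer in 1..3
#' @param x a `BrainAtlas`
#' @return `BrainAtlas()` a validated object; `atlasLabels()` the integer
#'   array; `atlasLut()` the lookup table.
#' @aliases BrainAtlas-class atlasLabels atlasLut
#' @export BrainAtlas
#' @exportClass BrainAtlas
setClass("BrainAtlas", contains = "BrainGrid", representation(
  labels = "array",
  lut    = "data.frame"
))

setValidity("BrainAtlas", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3-D array")
  if (!is.integer(object@labels))
    return("labels must be an integer array")
  need <- c("label", "region", "lobe", "hemisphere")
  if (!all(need %in% names(object@lut)))
    return(sprintf("lut must have columns %s", paste(need, collapse = ", ")))
  if (!all(object@lut$lobe %in% c("FL", "TL", "PL", "OL", "other")))
    return("lut lobe must be FL, TL, PL, OL or other")
  if (!all(object@lut$hemisphere %in% c("L", "R", "midline")))
    return("lut hemisphere must be L, R or midline")
  present <- setdiff(unique(as.vector(object@labels)), 0L)
  if (!all(present %in% object@lut$label))
    return("every nonzero label in the array must appear in the lut")
  if (anyDuplicated(object@lut$label))
    return("duplicate labels in lut")
  TRUE
})

BrainAtlas <- function(labels, lut, voxelSize, mirrorAxis = 1L) {
  lb <- as.array(labels)
  storage.mode(lb) <- "integer"
  lut <- as.data.frame(lut)
  lut$label <- as.integer(lut$label)
  new("BrainAtlas", labels = lb, lut = lut,
      voxelSize = as.numeric(voxelSize), mirrorAxis = as.integer(mirrorAxis))
}

#' AsymmetryMap: per-voxel asymmetry index in percent
#'
#' Produced by [aiMap()]. `values` holds the asymmetry index (percent) where
#' the voxel is valid and `NA` elsewhere; `valid` flags voxels that lie on
#' the affected side, are not infarct-pair excluded, and have a positive,
#' finite denominator for the chosen method.
#'
#' @param x an `AsymmetryMap`
#' @return `aiValues()` the percent array (`NA` where invalid), `aiValid()`
#'   the validity array, `aiMethod()` `"AI1"` or `"AI2"`, `affectedSide()`
#'   `"L"` or `"R"`.
#' @aliases AsymmetryMap-class aiValues aiValid aiMethod affectedSide
#' @exportClass AsymmetryMap
setClass("AsymmetryMap", contains = "BrainGrid", representation(
  values       = "array",
  valid        = "array",
  method       = "character",
  affectedSide = "character"
))

setValidity("AsymmetryMap", function(object) {
  if (!identical(dim(object@values), dim(object@valid)))
    return("values and valid must share a grid")
  if (!is.logical(object@valid))
    return("valid must be logical")
  if (!object@method %in% c("AI1", "AI2"))
    return("method must be AI1 or AI2")
  if (!object@affectedSide %in% c("L", "R"))
    return("affectedSide must be L or R")
  if (any(!is.finite(object@values[object@valid])))
    return("values must be finite wherever valid")
  TRUE
})

## ---- shared grid methods ----

#' @export
setMethod("dim", "BrainVolume", function(x) dim(x@values))
#' @export
setMethod("dim", "BrainMask", function(x) dim(x@values))
#' @export
setMethod("dim", "BrainAtlas", function(x) dim(x@labels))
#' @export
setMethod("dim", "AsymmetryMap", function(x) dim(x@values))

#' @rdname gridAccessors
setMethod("voxelSize", "BrainGrid", function(x) x@voxelSize)
#' @rdname gridAccessors
setMethod("mirrorAxis", "BrainGrid", function(x) x@mirrorAxis)

#' @rdname voxelVolumeMl
setMethod("voxelVolumeMl", "BrainGrid", function(x) prod(x@voxelSize) / 1000)

#' @rdname BrainVolume
setMethod("volumeData", "BrainVolume", function(x) x@values)
#' @rdname BrainVolume
setMethod("volumeUnits", "BrainVolume", function(x) x@units)
#' @rdname BrainMask
setMethod("maskData", "BrainMask", function(x) x@values)
#' @rdname BrainAtlas
setMethod("atlasLabels", "BrainAtlas", function(x) x@labels)
#' @rdname BrainAtlas
setMethod("atlasLut", "BrainAtlas", function(x) x@lut)
#' @rdname AsymmetryMap
setMethod("aiValues", "AsymmetryMap", function(x) x@values)
#' @rdname AsymmetryMap
setMethod("aiValid", "AsymmetryMap", function(x) x@valid)
#' @rdname AsymmetryMap
setMethod("aiMethod", "AsymmetryMap", function(x) x@method)
#' @rdname AsymmetryMap
setMethod("affectedSide", "AsymmetryMap", function(x) x@affectedSide)

## index-reversal along the mirror axis
flipAxis <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' @rdname mirror
setMethod("mirror", "BrainVolume", function(x) {
  initialize(x, values = flipAxis(x@values, x@mirrorAxis))
})
#' @rdname mirror
setMethod("mirror", "BrainMask", function(x) {
  initialize(x, values = flipAxis(x@values, x@mirrorAxis))
})
#' @rdname mirror
setMethod("mirror", "BrainAtlas", function(x) {
  initialize(x, labels = flipAxis(x@labels, x@mirrorAxis))
})
#' @rdname mirror
setMethod("mirror", "AsymmetryMap", function(x) {
  initialize(x, values = flipAxis(x@values, x@mirrorAxis),
             valid = flipAxis(x@valid, x@mirrorAxis))
})

## ---- show methods ----

.gridLine <- function(x) {
  sprintf("%s grid, voxels %s mm, mirror axis %d",
          paste(dim(x), collapse = " x "),
          paste(format(voxelSize(x), trim = TRUE), collapse = " x "),
          mirrorAxis(x))
}

setMethod("show", "BrainVolume", function(object) {
  cat("BrainVolume (", object@units, ")\n  ", .gridLine(object), "\n",
      "  value range: ",
      paste(format(range(object@values, finite = TRUE), digits = 4),
            collapse = " .. "), "\n", sep = "")
})

setMethod("show", "BrainMask", function(object) {
  cat("BrainMask\n  ", .gridLine(object), "\n  ",
      sum(object@values), " of ", length(object@values),
      " voxels set\n", sep = "")
})

setMethod("show", "BrainAtlas", function(object) {
  cat("BrainAtlas\n  ", .gridLine(object), "\n  ",
      nrow(object@lut), " regions: ",
      paste(utils::head(object@lut$region, 10), collapse = ", "),
      if (nrow(object@lut) > 10) ", ..." else "", "\n", sep = "")
})

setMethod("show", "AsymmetryMap", function(object) {
  v <- object@values[object@valid]
  cat("AsymmetryMap (", object@method, ", affected side ",
      object@affectedSide, ")\n  ", .gridLine(object), "\n  ",
      sum(object@valid), " valid voxels",
      if (length(v)) paste0("; AI range ",
        paste(format(range(v), digits = 4), collapse = " .. "), " %"),
      "\n", sep = "")
})

## internal: insist two gridded objects live on one grid
stopifnotSameGrid <- function(x, y, what = "inputs") {
  if (!identical(dim(x), dim(y)) ||
      max(abs(voxelSize(x) - voxelSize(y))) > 1e-9 ||
      mirrorAxis(x) != mirrorAxis(y))
    stop(what, " must share one grid (dimensions, voxel size, mirror axis)",
         call. = FALSE)
  invisible(TRUE)
}

## internal: logical array selecting one hemisphere. Lower indices along the
## mirror axis are "L". For an odd-sized axis the central slice is midline
## and belongs to neither hemisphere.
hemisphereSelector <- function(x, side = c("L", "R")) {
  side <- match.arg(side)
  d <- dim(x)
  ax <- mirrorAxis(x)
  n <- d[ax]
  half <- n %/% 2
  keep <- if (side == "L") seq_len(half) else seq.int(n - half + 1L, n)
  sel <- array(FALSE, d)
  idx <- rep(list(quote(expr = )), 3)
  idx[[ax]] <- keep
  do.call(`[<-`, c(list(sel), idx, list(value = TRUE)))
}
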