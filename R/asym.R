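## Core asymmetry-index machinery: infarct-pair exclusion, voxel-wise
## AI1/AI2 maps, threshold volumetry and regional aggregation.
##
## Orientation convention: ipsilateral = affected hemisphere, contralateral
## = unaffected hemisphere, so hypometabolism on the affected side gives
## positive AI and a >10% threshold selects it.

#' Infarct-pair exclusion mask
#'
#' A voxel is excluded from asymmetry analysis if it or its mirror partner
#' is infarcted: the exclusion is the union of the infarct mask with its
#' reflection, removing infarctions on both the ipsilateral and
#' contralateral sides.
#'
#' @param infarct a [BrainMask] of the infarct core
#' @return a [BrainMask]; symmetric under [mirror()]
#' @export
exclusionMask <- function(infarct) {
  stopifnot(is(infarct, "BrainMask"))
  initialize(infarct,
             values = maskData(infarct) | maskData(mirror(infarct)))
}

#' Voxel-wise asymmetry-index map
#'
#' For every affected-side voxel with value \eqn{S_{ipsi}} and mirror
#' partner value \eqn{S_{contra}}, computes (in percent)
#' \deqn{AI_1 = 100 \cdot (S_{contra} - S_{ipsi}) / S_{contra}}
#' \deqn{AI_2 = 100 \cdot 2 (S_{contra} - S_{ipsi}) /
#'       (S_{contra} + S_{ipsi}).}
#' A voxel is valid iff it lies on the affected side (the midline slice of
#' an odd-sized mirror axis belongs to neither side), is not excluded, both
#' values are finite and the method's denominator is positive. Both indices
#' are invariant to global scaling of the input, so either raw activity or
#' SUVR volumes may be supplied.
#'
#' @param suvr a [BrainVolume] (SUVR or activity)
#' @param affectedSide `"L"` or `"R"`
#' @param method `"AI1"` (contralateral-normalized) or `"AI2"`
#'   (bilateral-mean-normalized)
#' @param exclusion optional [BrainMask] of excluded voxels, typically
#'   [exclusionMask()] of the infarct
#' @return an [AsymmetryMap]
#' @examples
#' v <- BrainVolume(array(c(0.9, 1.0), c(2, 1, 1)), c(2, 2, 2))
#' aiValues(aiMap(v, "L", "AI1"))[1, 1, 1]  # 10
#' @export
aiMap <- function(suvr, affectedSide = c("L", "R"),
                  method = c("AI1", "AI2"), exclusion = NULL) {
  stopifnot(is(suvr, "BrainVolume"))
  affectedSide <- match.arg(affectedSide)
  method <- match.arg(method)
  ipsi <- volumeData(suvr)
  contra <- volumeData(mirror(suvr))
  excl <- if (is.null(exclusion)) {
    array(FALSE, dim(suvr))
  } else {
    stopifnot(is(exclusion, "BrainMask"))
    stopifnotSameGrid(suvr, exclusion, "volume and exclusion mask")
    maskData(exclusion)
  }
  hemi <- hemisphereSelector(suvr, affectedSide)
  denom <- if (method == "AI1") contra else (contra + ipsi) / 2
  valid <- hemi & !excl & is.finite(ipsi) & is.finite(contra) & denom > 0
  ai <- array(NA_real_, dim(suvr))
  ai[valid] <- 100 * (contra[valid] - ipsi[valid]) / denom[valid]
  new("AsymmetryMap", values = ai, valid = valid, method = method,
      affectedSide = affectedSide, voxelSize = voxelSize(suvr),
      mirrorAxis = mirrorAxis(suvr))
}

#' Closed-form AI2 as a function of AI1
#'
#' With both indices written as fractions of the same voxel pair,
#' \eqn{AI_2 = 2 AI_1 / (2 - AI_1)}. Used as an analytic oracle for the
#' voxel-wise identity between the two maps and for converting thresholds
#' between methods (an AI2 cut of `t` equals an AI1 cut of
#' `2 t / (2 + t)`).
#'
#' @param a AI1 as a fraction (vectorised); must satisfy `a < 2`
#' @return AI2 as a fraction
#' @examples
#' ai2OfAi1(0.10)          # 0.10526...
#' ai2OfAi1(0.2 / 2.1)     # 0.10
#' @export
ai2OfAi1 <- function(a) {
  if (any(a >= 2)) stop("AI1 fraction must be < 2", call. = FALSE)
  2 * a / (2 - a)
}

#' Threshold the asymmetry map into a hypometabolic mask
#'
#' Selects valid voxels whose AI strictly exceeds the threshold (default
#' 10 percent, the decreased-metabolism rule). Negative AI (affected-side
#' hypermetabolism) is retained in the map but never selected.
#'
#' @param map an [AsymmetryMap]
#' @param thresholdPct threshold in percent (default 10)
#' @return a [BrainMask] of hypometabolic voxels
#' @export
hypometabolicMask <- function(map, thresholdPct = 10) {
  stopifnot(is(map, "AsymmetryMap"), thresholdPct > 0)
  sel <- map@valid & !is.na(map@values) & map@values > thresholdPct
  sel[is.na(sel)] <- FALSE
  BrainMask(sel, voxelSize(map), mirrorAxis(map))
}

#' Regional hypometabolic volume and percentage
#'
#' For each lobe (FL, TL, PL, OL) and for the whole affected hemisphere:
#' the evaluable set is the affected-side voxels of that region that are
#' valid under the AI method (which already removes infarct-pair-excluded
#' voxels and undefined denominators); hypometabolic volume is
#' `count(hypo & evaluable) * voxel mL` and the percentage is taken of the
#' evaluable regional volume. The hemisphere row aggregates all
#' affected-side parcels of the atlas (midline parcels such as the pons are
#' never included). A region with an empty evaluable set is returned with
#' `NA` measures, not zero.
#'
#' @param hypo a [BrainMask] from [hypometabolicMask()]
#' @param atlas a [BrainAtlas]
#' @param map the [AsymmetryMap] the mask came from (supplies validity,
#'   affected side and method)
#' @return a data.frame with columns `region` (`FL`, `TL`, `PL`, `OL`,
#'   `hemisphere`), `method`, `volume_ml`, `percentage`, `evaluable_ml`
#' @export
regionalQuantify <- function(hypo, atlas, map) {
  stopifnot(is(hypo, "BrainMask"), is(atlas, "BrainAtlas"),
            is(map, "AsymmetryMap"))
  stopifnotSameGrid(hypo, atlas, "mask and atlas")
  stopifnotSameGrid(hypo, map, "mask and AI map")
  side <- affectedSide(map)
  lut <- atlasLut(atlas)
  labels <- atlasLabels(atlas)
  valid <- aiValid(map)
  h <- maskData(hypo)
  voxMl <- voxelVolumeMl(atlas)
  sideLabels <- lut$label[lut$hemisphere == side]
  regionLabels <- list(
    FL = lut$label[lut$lobe == "FL" & lut$hemisphere == side],
    TL = lut$label[lut$lobe == "TL" & lut$hemisphere == side],
    PL = lut$label[lut$lobe == "PL" & lut$hemisphere == side],
    OL = lut$label[lut$lobe == "OL" & lut$hemisphere == side],
    hemisphere = sideLabels)
  rows <- lapply(names(regionLabels), function(rg) {
    inRegion <- array(labels %in% regionLabels[[rg]], dim(labels))
    evaluable <- inRegion & valid
    nEval <- sum(evaluable)
    if (nEval == 0L)
      return(data.frame(region = rg, method = aiMethod(map),
                        volume_ml = NA_real_, percentage = NA_real_,
                        evaluable_ml = NA_real_))
    nHypo <- sum(h & evaluable)
    data.frame(region = rg, method = aiMethod(map),
               volume_ml = nHypo * voxMl,
               percentage = 100 * nHypo / nEval,
               evaluable_ml = nEval * voxMl)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
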