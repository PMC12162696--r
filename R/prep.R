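## Preprocessing: Van-Cittert partial-volume correction and SUVR
## normalization against a reference-region mask (pons).

#' Parameters for Van-Cittert partial-volume correction
#'
#' @param psfSigma Gaussian point-spread-function standard deviation, mm
#'   (>= 0; 0 makes the correction a no-op). Default 3 mm, the scale of a
#'   clinical PET reconstruction filter.
#' @param iterations number of update steps (>= 0; default 10)
#' @param relaxation relaxation factor in (0, 2) (default 1)
#' @param clamp clamp negative intermediate values to zero (default TRUE)
#' @return a validated `pvcParams` list
#' @export
pvcParams <- function(psfSigma = 3, iterations = 10L, relaxation = 1,
                      clamp = TRUE) {
  if (psfSigma < 0) stop("psfSigma must be >= 0", call. = FALSE)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  if (relaxation <= 0 || relaxation >= 2)
    stop("relaxation must lie in (0, 2)", call. = FALSE)
  structure(list(psfSigma = psfSigma, iterations = as.integer(iterations),
                 relaxation = relaxation, clamp = isTRUE(clamp)),
            class = "pvcParams")
}

#' Van-Cittert iterative deconvolution
#'
#' Classic additive Van-Cittert update for partial-volume correction: with
#' observed image \eqn{g} and Gaussian kernel \eqn{h},
#' \deqn{f_0 = g, \qquad f_{k+1} = f_k + \alpha (g - h \otimes f_k),}
#' optionally clamping negatives to zero after each step. With
#' `psfSigma = 0` or `iterations = 0` the input is returned unchanged.
#'
#' @param volume a [BrainVolume] with finite values
#' @param params a [pvcParams()]
#' @return the corrected [BrainVolume]
#' @export
vanCittert <- function(volume, params = pvcParams()) {
  stopifnot(is(volume, "BrainVolume"), inherits(params, "pvcParams"))
  g <- volumeData(volume)
  if (any(!is.finite(g)))
    stop("volume contains non-finite values", call. = FALSE)
  if (params$psfSigma == 0 || params$iterations == 0L)
    return(volume)
  vs <- voxelSize(volume)
  f <- g
  for (k in seq_len(params$iterations)) {
    f <- f + params$relaxation * (g - gaussianSmooth(f, params$psfSigma, vs))
    if (params$clamp) f[f < 0] <- 0
  }
  initialize(volume, values = f)
}

#' SUVR normalization against a reference region
#'
#' Divides every voxel by the mean value within the reference mask (the
#' pons in this pipeline), so the reference-region mean of the output is 1.
#' The result is scale-invariant: `suvrNormalize(c * v, ref)` equals
#' `suvrNormalize(v, ref)` for any `c > 0`.
#'
#' @param volume a [BrainVolume]
#' @param reference a nonempty [BrainMask] on the same grid with positive
#'   mean value under `volume`
#' @return a [BrainVolume] with units `"SUVR"`
#' @export
suvrNormalize <- function(volume, reference) {
  stopifnot(is(volume, "BrainVolume"), is(reference, "BrainMask"))
  stopifnotSameGrid(volume, reference, "volume and reference mask")
  sel <- maskData(reference)
  if (!any(sel)) stop("reference mask is empty", call. = FALSE)
  m <- mean(volumeData(volume)[sel])
  if (!is.finite(m) || m <= 0)
    stop("reference-region mean must be positive and finite (got ",
         format(m), ")", call. = FALSE)
  initialize(volume, values = volumeData(volume) / m, units = "SUVR")
}
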