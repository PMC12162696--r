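## Separable 3-D Gaussian convolution, used both as the phantom's
## point-spread-function model and as the Van-Cittert kernel. Implemented as
## a banded convolution matrix per axis with row-renormalised truncated
## kernels, so constant volumes are preserved exactly at the edges and the
## operator commutes with the mirror reflection.

.convMatrix <- function(n, sigmaVox) {
  radius <- ceiling(4 * sigmaVox)
  if (2L * radius + 1L > n)
    stop("PSF kernel (radius ", radius,
         " voxels) is larger than the volume axis (", n, " voxels)",
         call. = FALSE)
  off <- outer(seq_len(n), seq_len(n), `-`)
  K <- exp(-off^2 / (2 * sigmaVox^2))
  K[abs(off) > radius] <- 0
  K / rowSums(K)
}

.convAxis <- function(v, K, axis) {
  d <- dim(v)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(v, perm), nrow = d[axis])
  aperm(array(K %*% m, dim = d[perm]), order(perm))
}

#' Gaussian smoothing of a 3-D volume
#'
#' Separable Gaussian blur with standard deviation `sigmaMm` (mm), converted
#' per axis to voxel units. The kernel is truncated at 4 standard deviations
#' and renormalised near the edges, so a constant volume is left unchanged.
#' `sigmaMm = 0` is the identity.
#'
#' @param x a [BrainVolume] or a bare numeric 3-D array
#' @param sigmaMm Gaussian standard deviation in mm (single value, >= 0)
#' @param voxelSize voxel dimensions in mm; taken from `x` when it is a
#'   [BrainVolume]
#' @return an object of the same type as `x`, smoothed
#' @export
gaussianSmooth <- function(x, sigmaMm, voxelSize = NULL) {
  stopifnot(length(sigmaMm) == 1L, is.finite(sigmaMm), sigmaMm >= 0)
  isVol <- is(x, "BrainVolume")
  v <- if (isVol) x@values else as.array(x)
  if (length(dim(v)) != 3L) stop("x must be 3-D", call. = FALSE)
  vs <- if (isVol) voxelSize(x) else as.numeric(voxelSize)
  if (length(vs) != 3L || any(vs <= 0))
    stop("voxelSize must be 3 positive values", call. = FALSE)
  if (sigmaMm > 0) {
    for (ax in 1:3) {
      sVox <- sigmaMm / vs[ax]
      if (sVox > 1e-8)
        v <- .convAxis(v, .convMatrix(dim(v)[ax], sVox), ax)
    }
  }
  if (isVol) initialize(x, values = v) else v
}
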