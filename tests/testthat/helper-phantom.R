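# Shared desk-scale fixtures: a coarse 24 x 28 x 24 grid of 6 mm voxels
# keeps every construction fast while preserving all geometric properties.

smallShape <- c(24L, 28L, 24L)
smallVox <- c(6, 6, 6)

smallSpec <- function(seed, ...) {
  args <- list(...)
  defaults <- list(shape = smallShape, voxelSize = smallVox,
                   shellRadius = 20, infarctRadius = 9, seed = seed)
  do.call(phantomSpec, utils::modifyList(defaults, args))
}

smallCohortSpec <- function(seed, n = 6L, ...) {
  cohortSpec(n = n, shape = smallShape, voxelSize = smallVox,
             shellRadiusRange = c(16, 22), infarctRadiusRange = c(7, 10),
             psfSigma = 0, noiseSd = 0, seed = seed, ...)
}

# brute-force mirror partner lookup: explicit index arithmetic, independent
# of flipAxis / mirror()
bruteMirror <- function(a, axis) {
  d <- dim(a)
  out <- array(a[1], d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)
    idx[axis] <- d[axis] + 1L - idx[axis]
    out[idx[1], idx[2], idx[3]] <- a[i, j, k]
  }
  out
}
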