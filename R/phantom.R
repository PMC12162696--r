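## Synthetic brain phantoms: a left/right-symmetric ellipsoidal "brain"
## partitioned into lobar octants, a midline pons, and a one-sided spherical
## infarct core surrounded by a hypometabolic shell. Geometry is kept
## deliberately simple so ground truth (membership counts) is closed-form.

## evaluate expr under a given RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed))
    stop("a seed is required for reproducible generation", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## mm coordinates with the grid centre at the origin; index reversal along
## any axis maps a coordinate to its negative.
.axisCoords <- function(n, vox) (seq_len(n) - (n + 1) / 2) * vox

## shared geometry: coordinate arrays, brain ellipsoid, pons sphere
.phantomGeometry <- function(shape, voxelSize, mirrorAxis = 1L) {
  stopifnot(length(shape) == 3L, length(voxelSize) == 3L)
  others <- setdiff(1:3, mirrorAxis)
  apAxis <- others[1]          # anterior-posterior
  siAxis <- others[2]          # superior-inferior
  cs <- lapply(1:3, function(a) .axisCoords(shape[a], voxelSize[a]))
  x <- array(0, shape); y <- array(0, shape); z <- array(0, shape)
  ix <- slice.index(x, mirrorAxis)
  iy <- slice.index(x, apAxis)
  iz <- slice.index(x, siAxis)
  x[] <- cs[[mirrorAxis]][ix]
  y[] <- cs[[apAxis]][iy]
  z[] <- cs[[siAxis]][iz]
  semi <- 0.44 * shape * voxelSize            # ellipsoid semi-axes, mm
  a <- semi[mirrorAxis]; b <- semi[apAxis]; c <- semi[siAxis]
  brain <- (x / a)^2 + (y / b)^2 + (z / c)^2 <= 1
  ponsCenter <- c(0, -0.10 * b, -0.55 * c)    # (LR, AP, SI) mm
  ponsRadius <- max(0.14 * c, 2 * max(voxelSize))
  pons <- (x - ponsCenter[1])^2 + (y - ponsCenter[2])^2 +
    (z - ponsCenter[3])^2 <= ponsRadius^2
  list(x = x, y = y, z = z, semi = c(a, b, c), brain = brain,
       pons = pons & brain)
}

#' Build the simplified lobar atlas and pons reference mask
#'
#' Partitions an ellipsoidal brain into frontal, temporal, parietal and
#' occipital parcels per hemisphere (8 labels) by quadrants of the
#' anterior-posterior and superior-inferior axes, plus a midline pons
#' sphere (label 9). The label map is symmetric under [mirror()] with the
#' L/R labels swapped. This is a coarse stand-in for a full anatomical
#' parcellation; hemispheric and lobar volumetry only needs consistent,
#' symmetric region membership.
#'
#' @param shape integer(3) grid dimensions (each >= 8)
#' @param voxelSize numeric(3) voxel dimensions, mm
#' @param mirrorAxis left/right axis (default 1)
#' @return a list with elements `atlas` (a [BrainAtlas]) and `pons`
#'   (a [BrainMask] of the reference region)
#' @examples
#' at <- makeAtlas(c(24, 28, 24), c(6, 6, 6))
#' table(atlasLut(at$atlas)$hemisphere)
#' @export
makeAtlas <- function(shape, voxelSize, mirrorAxis = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("grid too small for a 9-parcel atlas (need every dim >= 8)",
         call. = FALSE)
  g <- .phantomGeometry(shape, voxelSize, mirrorAxis)
  lobe <- ifelse(g$y > 0,
                 ifelse(g$z > 0, 1L, 2L),    # FL / TL (anterior)
                 ifelse(g$z > 0, 3L, 4L))    # PL / OL (posterior)
  labels <- array(0L, shape)
  left <- g$x < 0; right <- g$x > 0
  labels[g$brain & left]  <- lobe[g$brain & left]
  labels[g$brain & right] <- lobe[g$brain & right] + 4L
  labels[g$pons] <- 9L
  lut <- data.frame(
    label = 1:9,
    region = c("frontal_L", "temporal_L", "parietal_L", "occipital_L",
               "frontal_R", "temporal_R", "parietal_R", "occipital_R",
               "pons"),
    lobe = c("FL", "TL", "PL", "OL", "FL", "TL", "PL", "OL", "other"),
    hemisphere = c(rep("L", 4), rep("R", 4), "midline"),
    stringsAsFactors = FALSE)
  list(atlas = BrainAtlas(labels, lut, voxelSize, mirrorAxis),
       pons = BrainMask(g$pons, voxelSize, mirrorAxis))
}

#' Specification of a single synthetic subject
#'
#' Defines the grid, symmetric per-lobe baseline uptake, and a one-sided
#' lesion: a spherical infarct core (uptake scaled by `1 - fInfarct`)
#' surrounded by a hypometabolic shell (uptake scaled by `1 - f`). The
#' volume is then blurred with a Gaussian point-spread function and
#' Gaussian noise is added, both seeded.
#'
#' @param shape,voxelSize grid geometry (defaults 48 x 56 x 48 voxels of
#'   3 mm: a desk-scale head-sized grid)
#' @param baseline named numeric: baseline uptake (kBq/mL) for lobes
#'   `FL`, `TL`, `PL`, `OL`; applied symmetrically to both hemispheres
#' @param ponsBaseline baseline uptake in the pons reference region
#' @param lesionCenter lesion centre in mm grid coordinates (LR, AP, SI),
#'   or `NULL` to place it automatically within the affected hemisphere
#' @param infarctRadius,shellRadius infarct core and shell outer radius, mm
#'   (`shellRadius >= infarctRadius`)
#' @param f fractional uptake reduction in the shell, in `[0, 1)`
#' @param fInfarct fractional reduction inside the infarct core (> `f`)
#' @param side affected hemisphere, `"L"` or `"R"`
#' @param psfSigma point-spread-function standard deviation, mm (>= 0)
#' @param noiseSd additive Gaussian noise standard deviation, same units as
#'   `baseline` (>= 0)
#' @param seed integer seed; required
#' @param mirrorAxis left/right axis (default 1)
#' @return a validated `phantomSpec` list
#' @export
phantomSpec <- function(shape = c(48L, 56L, 48L), voxelSize = c(3, 3, 3),
                        baseline = c(FL = 10, TL = 9.5, PL = 10.5, OL = 9),
                        ponsBaseline = 8,
                        lesionCenter = NULL,
                        infarctRadius = 5, shellRadius = 12,
                        f = 0.2, fInfarct = 0.8, side = "L",
                        psfSigma = 0, noiseSd = 0, seed,
                        mirrorAxis = 1L) {
  if (missing(seed)) stop("phantomSpec requires a seed", call. = FALSE)
  stopifnot(all(c("FL", "TL", "PL", "OL") %in% names(baseline)))
  if (any(baseline <= 0) || ponsBaseline <= 0)
    stop("baseline uptake values must be positive", call. = FALSE)
  if (f < 0 || f >= 1) stop("f must be in [0, 1)", call. = FALSE)
  if (fInfarct <= f || fInfarct > 1)
    stop("fInfarct must satisfy f < fInfarct <= 1", call. = FALSE)
  if (shellRadius < infarctRadius)
    stop("shellRadius must be >= infarctRadius", call. = FALSE)
  if (psfSigma < 0 || noiseSd < 0)
    stop("psfSigma and noiseSd must be >= 0", call. = FALSE)
  side <- match.arg(side, c("L", "R"))
  structure(list(shape = as.integer(shape), voxelSize = as.numeric(voxelSize),
                 baseline = baseline, ponsBaseline = ponsBaseline,
                 lesionCenter = lesionCenter,
                 infarctRadius = infarctRadius, shellRadius = shellRadius,
                 f = f, fInfarct = fInfarct, side = side,
                 psfSigma = psfSigma, noiseSd = noiseSd,
                 seed = as.integer(seed), mirrorAxis = as.integer(mirrorAxis)),
            class = "phantomSpec")
}

## default lesion centre: lateral in the affected hemisphere, slightly
## anterior and superior, in mm grid coordinates (LR, AP, SI)
.defaultLesionCenter <- function(semi, side, shellRadius) {
  sgn <- if (side == "L") -1 else 1
  c(sgn * max(0.45 * semi[1], shellRadius + semi[1] * 0.06),
    0.12 * semi[2], 0.18 * semi[3])
}

#' Generate one synthetic subject
#'
#' Builds the activity volume, infarct mask and geometric ground truth for a
#' [phantomSpec()]. Uptake equals the lobe baseline, scaled by `1 - f` in
#' the shell and `1 - fInfarct` in the infarct core, then blurred
#' (`psfSigma`) and degraded with additive Gaussian noise (`noiseSd`), both
#' under the spec's seed. Ground truth reflects the pre-blur geometry.
#'
#' @param spec a [phantomSpec()]
#' @return a list: `volume` ([BrainVolume], units `"activity"`), `infarct`
#'   ([BrainMask]), `truth` (list: `infarct`, `shell` masks, `f`,
#'   `shellVolumeMl`, `burden` = shell volume x f), `atlas`, `pons`
#' @examples
#' s <- makeSubject(phantomSpec(shape = c(24, 28, 24), voxelSize = c(6, 6, 6),
#'                              shellRadius = 18, infarctRadius = 8, seed = 1))
#' s$truth$shellVolumeMl
#' @export
makeSubject <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  g <- .phantomGeometry(spec$shape, spec$voxelSize, spec$mirrorAxis)
  am <- makeAtlas(spec$shape, spec$voxelSize, spec$mirrorAxis)
  labels <- atlasLabels(am$atlas)

  base <- array(0, spec$shape)
  lobeOf <- c("FL", "TL", "PL", "OL", "FL", "TL", "PL", "OL")
  for (lb in 1:8)
    base[labels == lb] <- spec$baseline[[lobeOf[lb]]]
  base[labels == 9L] <- spec$ponsBaseline

  ctr <- spec$lesionCenter
  if (is.null(ctr))
    ctr <- .defaultLesionCenter(g$semi, spec$side, spec$shellRadius)
  if (spec$shellRadius > 0 &&
      sum((ctr / g$semi)^2) > 1)
    stop("lesion outside brain: lesionCenter lies beyond the brain ",
         "ellipsoid", call. = FALSE)
  d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
  sphere <- d2 <= spec$shellRadius^2
  sideOk <- if (spec$side == "L") g$x < 0 else g$x > 0
  if (!all(g$brain[sphere]) || !all(sideOk[sphere]))
    stop("lesion outside brain or crossing the midline; move lesionCenter ",
         "or shrink shellRadius", call. = FALSE)
  if (any(g$pons[sphere]))
    stop("lesion overlaps the pons reference region", call. = FALSE)
  infarct <- d2 <= spec$infarctRadius^2
  shell <- sphere & !infarct

  v <- base
  v[shell] <- v[shell] * (1 - spec$f)
  v[infarct] <- v[infarct] * (1 - spec$fInfarct)
  if (spec$psfSigma > 0)
    v <- gaussianSmooth(v, spec$psfSigma, spec$voxelSize)
  if (spec$noiseSd > 0)
    v <- v + .withSeed(spec$seed,
                       array(stats::rnorm(length(v), 0, spec$noiseSd),
                             dim = spec$shape))

  voxMl <- prod(spec$voxelSize) / 1000
  list(volume = BrainVolume(v, spec$voxelSize, spec$mirrorAxis, "activity"),
       infarct = BrainMask(infarct, spec$voxelSize, spec$mirrorAxis),
       truth = list(
         infarct = BrainMask(infarct, spec$voxelSize, spec$mirrorAxis),
         shell = BrainMask(shell, spec$voxelSize, spec$mirrorAxis),
         f = spec$f,
         shellVolumeMl = sum(shell) * voxMl,
         burden = sum(shell) * voxMl * spec$f),
       atlas = am$atlas, pons = am$pons, spec = spec)
}

#' Specification of a simulated cohort
#'
#' Per-subject lesion parameters are drawn uniformly from the stated ranges;
#' clinical scores are generated from the hypometabolic burden
#' (true shell volume x f) through a noisy monotone link:
#' `NIHSS = round(nihssSlope * burden + e)` clipped to 0..42 and
#' `mRS = round(mrsSlope * burden + e')` clipped to 0..6, with zero-mean
#' Gaussian `e`, `e'`.
#'
#' @param n number of subjects (>= 2); default 70
#' @param fRange range of the shell reduction fraction (default 0.12..0.4)
#' @param shellRadiusRange,infarctRadiusRange lesion radii ranges, mm
#' @param nihssSlope,mrsSlope positive link slopes (score per mL of burden)
#' @param nihssNoiseSd,mrsNoiseSd link noise standard deviations
#' @param psfSigma,noiseSd imaging degradation applied to every subject
#' @param shape,voxelSize,baseline,ponsBaseline,fInfarct,mirrorAxis
#'   forwarded to [phantomSpec()]
#' @param seed integer master seed; required
#' @return a validated `cohortSpec` list
#' @export
cohortSpec <- function(n = 70L, fRange = c(0.12, 0.4),
                       shellRadiusRange = c(9, 15),
                       infarctRadiusRange = c(3.5, 6),
                       nihssSlope = 2.5, mrsSlope = 1.0,
                       nihssNoiseSd = 1.5, mrsNoiseSd = 0.5,
                       psfSigma = 3, noiseSd = 0.2,
                       shape = c(48L, 56L, 48L), voxelSize = c(3, 3, 3),
                       baseline = c(FL = 10, TL = 9.5, PL = 10.5, OL = 9),
                       ponsBaseline = 8, fInfarct = 0.8,
                       mirrorAxis = 1L, seed) {
  if (missing(seed)) stop("cohortSpec requires a seed", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (nihssSlope <= 0 || mrsSlope <= 0)
    stop("link slopes must be positive", call. = FALSE)
  stopifnot(diff(fRange) >= 0, diff(shellRadiusRange) >= 0,
            min(shellRadiusRange) >= max(infarctRadiusRange))
  structure(list(n = as.integer(n), fRange = fRange,
                 shellRadiusRange = shellRadiusRange,
                 infarctRadiusRange = infarctRadiusRange,
                 nihssSlope = nihssSlope, mrsSlope = mrsSlope,
                 nihssNoiseSd = nihssNoiseSd, mrsNoiseSd = mrsNoiseSd,
                 psfSigma = psfSigma, noiseSd = noiseSd,
                 shape = as.integer(shape), voxelSize = as.numeric(voxelSize),
                 baseline = baseline, ponsBaseline = ponsBaseline,
                 fInfarct = fInfarct, mirrorAxis = as.integer(mirrorAxis),
                 seed = as.integer(seed)),
            class = "cohortSpec")
}

## link burden -> clipped integer scores; returns data.frame(nihss, mrs)
.linkScores <- function(spec, burden) {
  n <- length(burden)
  nihss <- round(spec$nihssSlope * burden +
                   stats::rnorm(n, 0, spec$nihssNoiseSd))
  mrs <- round(spec$mrsSlope * burden + stats::rnorm(n, 0, spec$mrsNoiseSd))
  data.frame(nihss = as.integer(pmin(pmax(nihss, 0), 42)),
             mrs = as.integer(pmin(pmax(mrs, 0), 6)))
}

#' Simulate a cohort of lesioned phantoms with linked clinical scores
#'
#' A pure function of (`spec`, `spec$seed`): lesion draws, subject seeds and
#' score noise are all derived from the master seed.
#'
#' @param spec a [cohortSpec()]
#' @return an object of class `aiCohort`: a list with `spec`, `atlas`,
#'   `pons`, `subjects` (per-subject lists as from [makeSubject()]) and
#'   `records` (clinical table, timepoint `"pre"`)
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  n <- spec$n
  draws <- .withSeed(spec$seed, {
    d <- data.frame(
      f = stats::runif(n, spec$fRange[1], spec$fRange[2]),
      shellR = stats::runif(n, spec$shellRadiusRange[1],
                            spec$shellRadiusRange[2]),
      infR = stats::runif(n, spec$infarctRadiusRange[1],
                          spec$infarctRadiusRange[2]),
      side = sample(c("L", "R"), n, replace = TRUE),
      jAP = stats::runif(n, -5, 5),
      jSI = stats::runif(n, -5, 5),
      subSeed = sample.int(.Machine$integer.max - 1L, n))
    d
  })
  am <- makeAtlas(spec$shape, spec$voxelSize, spec$mirrorAxis)
  g <- .phantomGeometry(spec$shape, spec$voxelSize, spec$mirrorAxis)
  subjects <- vector("list", n)
  ids <- sprintf("s%03d", seq_len(n))
  for (i in seq_len(n)) {
    ctr <- .defaultLesionCenter(g$semi, draws$side[i], draws$shellR[i])
    ctr[2] <- ctr[2] + draws$jAP[i]
    ctr[3] <- ctr[3] + draws$jSI[i]
    ps <- phantomSpec(shape = spec$shape, voxelSize = spec$voxelSize,
                      baseline = spec$baseline,
                      ponsBaseline = spec$ponsBaseline,
                      lesionCenter = ctr,
                      infarctRadius = draws$infR[i],
                      shellRadius = draws$shellR[i],
                      f = draws$f[i], fInfarct = spec$fInfarct,
                      side = draws$side[i],
                      psfSigma = spec$psfSigma, noiseSd = spec$noiseSd,
                      seed = draws$subSeed[i], mirrorAxis = spec$mirrorAxis)
    subjects[[i]] <- makeSubject(ps)
    subjects[[i]]$subject_id <- ids[i]
  }
  burden <- vapply(subjects, function(s) s$truth$burden, numeric(1))
  scores <- .withSeed(spec$seed + 1L, .linkScores(spec, burden))
  if (length(unique(scores$nihss)) == 1L && length(unique(scores$mrs)) == 1L)
    warning("degenerate score link: all scores clipped to a single value")
  records <- validateClinicalTable(data.frame(
    subject_id = ids,
    affected_side = draws$side,
    nihss = scores$nihss, mrs = scores$mrs,
    timepoint = "pre", stringsAsFactors = FALSE))
  structure(list(spec = spec, atlas = am$atlas, pons = am$pons,
                 subjects = subjects, records = records, draws = draws),
            class = "aiCohort")
}

#' Simulate a paired follow-up of an existing cohort
#'
#' Regenerates every subject at a post timepoint with the shell reduction
#' scaled to `f_post = (1 - g) * f_pre` (same lesion geometry, fresh noise)
#' and re-links the clinical scores to the new burden. `g > 0` models
#' metabolic improvement; `g < 0` deterioration; `g = 1` full recovery.
#'
#' @param cohort an `aiCohort` from [simulateCohort()]
#' @param g improvement fraction, scalar or per-subject vector, each in
#'   (-1, 1]
#' @param seed integer seed for the post-timepoint noise and score draws
#' @return a list with `pre` (the input cohort) and `post` (an `aiCohort`
#'   whose `records` carry timepoint `"post"`), paired by `subject_id`
#' @export
simulateFollowup <- function(cohort, g, seed) {
  stopifnot(inherits(cohort, "aiCohort"))
  if (missing(seed)) stop("simulateFollowup requires a seed", call. = FALSE)
  n <- length(cohort$subjects)
  g <- rep_len(g, n)
  if (any(g <= -1 | g > 1))
    stop("g must lie in (-1, 1]", call. = FALSE)
  spec <- cohort$spec
  subSeeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    preSpec <- cohort$subjects[[i]]$spec
    fPost <- (1 - g[i]) * preSpec$f
    if (fPost >= 1) stop("post-timepoint f would reach 1", call. = FALSE)
    ps <- preSpec
    ps$f <- fPost
    ps$seed <- subSeeds[i]
    class(ps) <- "phantomSpec"
    subjects[[i]] <- makeSubject(ps)
    subjects[[i]]$subject_id <- cohort$subjects[[i]]$subject_id
  }
  burden <- vapply(subjects, function(s) s$truth$burden, numeric(1))
  scores <- .withSeed(seed + 1L, .linkScores(spec, burden))
  records <- validateClinicalTable(data.frame(
    subject_id = cohort$records$subject_id,
    affected_side = cohort$records$affected_side,
    nihss = scores$nihss, mrs = scores$mrs,
    timepoint = "post", stringsAsFactors = FALSE))
  post <- structure(list(spec = spec, atlas = cohort$atlas,
                         pons = cohort$pons, subjects = subjects,
                         records = records, draws = cohort$draws),
                    class = "aiCohort")
  list(pre = cohort, post = post, g = g)
}
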