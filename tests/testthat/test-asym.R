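test_that("exclusion is the union of the infarct with its mirror image", {
  d <- c(4L, 4L, 4L)
  empty <- BrainMask(array(FALSE, d), c(2, 2, 2))
  expect_equal(sum(maskData(exclusionMask(empty))), 0)

  one <- array(FALSE, d); one[2, 3, 1] <- TRUE
  ex <- maskData(exclusionMask(BrainMask(one, c(2, 2, 2))))
  expect_equal(sum(ex), 2)
  expect_true(ex[2, 3, 1] && ex[3, 3, 1])

  sym <- array(FALSE, d); sym[2, 1, 1] <- TRUE; sym[3, 1, 1] <- TRUE
  m <- BrainMask(sym, c(2, 2, 2))
  expect_identical(maskData(exclusionMask(m)), sym)
})

test_that("AI values match direct substitution into the two formulas", {
  # affected (L) voxel 0.9, mirror partner 1.0
  v <- BrainVolume(array(c(0.9, 1.0), c(2, 1, 1)), c(2, 2, 2))
  expect_equal(aiValues(aiMap(v, "L", "AI1"))[1, 1, 1], 10)
  expect_equal(aiValues(aiMap(v, "L", "AI2"))[1, 1, 1],
               100 * 2 * 0.1 / 1.9)
  # symmetric pair gives 0 under both methods
  u <- BrainVolume(array(c(1, 1), c(2, 1, 1)), c(2, 2, 2))
  expect_equal(aiValues(aiMap(u, "L", "AI1"))[1, 1, 1], 0)
  expect_equal(aiValues(aiMap(u, "L", "AI2"))[1, 1, 1], 0)
  # zero contralateral denominator invalidates the voxel
  w <- BrainVolume(array(c(0.5, 0), c(2, 1, 1)), c(2, 2, 2))
  expect_false(aiValid(aiMap(w, "L", "AI1"))[1, 1, 1])
  # only affected-side voxels are valid
  m1 <- aiMap(v, "L", "AI1")
  expect_false(aiValid(m1)[2, 1, 1])
})

test_that("the closed-form AI1 -> AI2 identity holds voxel-wise", {
  expect_equal(ai2OfAi1(0), 0)
  expect_equal(ai2OfAi1(0.10), 2 * 0.10 / 1.9)
  # numerically solve 2a/(2-a) = 0.10
  root <- uniroot(function(a) ai2OfAi1(a) - 0.10, c(0, 0.5),
                  tol = 1e-12)$root
  expect_equal(root, 0.2 / 2.1, tolerance = 1e-9)
  expect_error(ai2OfAi1(2), "must be < 2")

  set.seed(42)
  contra <- runif(2000, 0.2, 3)
  ipsi <- runif(2000, 0.01, 3)
  a1 <- (contra - ipsi) / contra
  a2 <- 2 * (contra - ipsi) / (contra + ipsi)
  expect_equal(ai2OfAi1(a1), a2, tolerance = 1e-12)
})

test_that("AI2 dominates AI1 and the maps are scale-invariant", {
  s <- makeSubject(smallSpec(seed = 12, f = 0.25, psfSigma = 6,
                             noiseSd = 0.15))
  suvr <- suvrNormalize(s$volume, s$pons)
  excl <- exclusionMask(s$infarct)
  m1 <- aiMap(suvr, "L", "AI1", excl)
  m2 <- aiMap(suvr, "L", "AI2", excl)
  both <- aiValid(m1) & aiValid(m2)
  expect_gt(sum(both), 0)
  expect_true(all(aiValues(m2)[both] >= aiValues(m1)[both] - 1e-9))
  nz <- both & abs(aiValues(m1)) > 1e-6 & aiValues(m1) < 200
  expect_true(all(aiValues(m2)[nz] > aiValues(m1)[nz]))

  # hypometabolic mask nesting follows wherever both methods are defined
  h1 <- maskData(hypometabolicMask(m1, 10))
  h2 <- maskData(hypometabolicMask(m2, 10))
  expect_true(all(h2[h1 & aiValid(m2)]))

  # global scaling leaves both maps unchanged
  scaled <- initialize(s$volume, values = volumeData(s$volume) * 11.3)
  m1s <- aiMap(scaled, "L", "AI1", excl)
  expect_equal(aiValues(m1s)[aiValid(m1s)], aiValues(m1)[aiValid(m1)],
               tolerance = 1e-10)
})

test_that("an AI2 threshold t equals an AI1 threshold 2t/(2+t)", {
  set.seed(7)
  contra <- runif(20000, 0.05, 3)
  ipsi <- runif(20000, 0.05, 3)
  a1 <- 100 * (contra - ipsi) / contra
  a2 <- 100 * 2 * (contra - ipsi) / (contra + ipsi)
  for (t in c(5, 10, 25)) {
    tEquiv <- 100 * (2 * (t / 100)) / (2 + t / 100)
    expect_identical(a2 > t, a1 > tEquiv)
  }
  expect_equal(100 * 2 * 0.10 / 2.10, 9.523810, tolerance = 1e-6)
})

test_that("threshold volumetry is strict and recovers the phantom shell", {
  # all-zero AI map -> empty mask; boundary value excluded
  flat <- BrainVolume(array(1, c(4, 4, 4)), c(2, 2, 2))
  expect_equal(sum(maskData(hypometabolicMask(aiMap(flat, "L", "AI1")))), 0)

  # one pair exactly at AI1 = 10%: excluded by the strict rule
  v <- array(1, c(4, 1, 1)); v[1] <- 0.9
  vb <- BrainVolume(v, c(2, 2, 2))
  m <- aiMap(vb, "L", "AI1")
  expect_equal(aiValues(m)[1, 1, 1], 10)
  expect_false(maskData(hypometabolicMask(m, 10))[1, 1, 1])
  expect_true(maskData(hypometabolicMask(m, 9.9))[1, 1, 1])

  # noise-free phantom with f = 0.2 (AI1 = 20% in the shell):
  # mask equals shell minus exclusion, voxel for voxel
  s <- makeSubject(smallSpec(seed = 13, f = 0.2))
  suvr <- suvrNormalize(s$volume, s$pons)
  excl <- exclusionMask(s$infarct)
  h <- maskData(hypometabolicMask(aiMap(suvr, "L", "AI1", excl), 10))
  want <- maskData(s$truth$shell) & !maskData(excl)
  expect_identical(h, want)
})

test_that("regional quantification counts membership exactly", {
  s <- makeSubject(smallSpec(seed = 14, f = 0.2))
  suvr <- suvrNormalize(s$volume, s$pons)
  excl <- exclusionMask(s$infarct)
  m <- aiMap(suvr, "L", "AI1", excl)
  h <- hypometabolicMask(m, 10)
  rq <- regionalQuantify(h, s$atlas, m)
  expect_setequal(rq$region, c("FL", "TL", "PL", "OL", "hemisphere"))

  # brute-force oracle: direct membership count per region
  lb <- atlasLabels(s$atlas)
  lut <- atlasLut(s$atlas)
  voxMl <- voxelVolumeMl(s$atlas)
  for (rg in c("FL", "TL", "PL", "OL")) {
    lab <- lut$label[lut$lobe == rg & lut$hemisphere == "L"]
    evaluable <- (lb == lab) & aiValid(m)
    expect_equal(rq$volume_ml[rq$region == rg],
                 sum(maskData(h) & evaluable) * voxMl)
    expect_equal(rq$percentage[rq$region == rg],
                 100 * sum(maskData(h) & evaluable) / sum(evaluable))
  }
  # hemisphere equals the truth volume net of exclusion
  want <- sum(maskData(s$truth$shell) & !maskData(excl)) * voxMl
  expect_equal(rq$volume_ml[rq$region == "hemisphere"], want)
  # invariants of the measure
  expect_true(all(rq$volume_ml <= rq$evaluable_ml))
  expect_true(all(rq$percentage >= 0 & rq$percentage <= 100))
  expect_equal(rq$percentage, 100 * rq$volume_ml / rq$evaluable_ml)
})

test_that("a symmetric phantom yields zero AI and zero volumes", {
  s <- makeSubject(smallSpec(seed = 15, f = 0, fInfarct = 0.5,
                             infarctRadius = 0))
  suvr <- suvrNormalize(s$volume, s$pons)
  for (mt in c("AI1", "AI2")) {
    m <- aiMap(suvr, "R", mt)
    expect_true(all(abs(aiValues(m)[aiValid(m)]) < 1e-9))
    rq <- regionalQuantify(hypometabolicMask(m, 10), s$atlas, m)
    expect_true(all(rq$volume_ml == 0))
    expect_true(all(rq$percentage == 0))
  }
})

test_that("volume recovery improves monotonically as noise falls", {
  errs <- vapply(c(0.1, 0.05, 0.01), function(sd) {
    s <- makeSubject(smallSpec(seed = 16, f = 0.2, noiseSd = sd * 10))
    suvr <- suvrNormalize(s$volume, s$pons)
    excl <- exclusionMask(s$infarct)
    m <- aiMap(suvr, "L", "AI1", excl)
    rq <- regionalQuantify(hypometabolicMask(m, 10), s$atlas, m)
    truth <- sum(maskData(s$truth$shell) & !maskData(excl)) *
      voxelVolumeMl(s$volume)
    abs(rq$volume_ml[rq$region == "hemisphere"] - truth)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[3], errs[1])
})
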