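# Brute-force oracles coded independently of the implementations

oraclePairedT <- function(x, y) {
  d <- x - y
  n <- length(d)
  s <- sqrt(sum((d - sum(d) / n)^2) / (n - 1))
  t <- (sum(d) / n) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}

oracleRank <- function(v) {
  # midranks by definition: 1 + number smaller + half the number tied
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
}

oracleSpearmanRho <- function(x, y) {
  rx <- oracleRank(x); ry <- oracleRank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

test_that("paired t matches hand computation and the degenerate contract", {
  # d = (1, 2, 3): mean 2, sd 1, t = 2 / (1 / sqrt(3))
  r <- pairedT(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)

  same <- pairedT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$meanDiff, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  shifted <- pairedT(c(2, 3, 4), c(1, 2, 3))
  expect_equal(shifted$p, 0)
  expect_true(shifted$degenerate)

  expect_error(pairedT(1, 2), "n >= 2")
})

test_that("paired t and Bland-Altman agree with oracles on random data", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 3 == 0) y <- round(y)   # induce tied differences sometimes
    r <- pairedT(x, y)
    o <- oraclePairedT(x, y)
    expect_equal(r$t, o$t, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)

    ba <- blandAltman(x, y)
    expect_equal(ba$bias, mean(x - y), tolerance = 1e-12)
    expect_equal(ba$loaHigh - ba$bias, 1.96 * sd(x - y), tolerance = 1e-10)
    expect_lte(ba$loaLow, ba$bias)
    expect_gte(ba$loaHigh, ba$bias)
  }
  # hand case: differences (-1, 1)
  ba <- blandAltman(c(0, 2), c(1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sdDiff, sqrt(2))
  expect_equal(ba$loaHigh, 1.96 * sqrt(2), tolerance = 1e-12)
})

test_that("Spearman rho matches the hand-rank oracle including ties", {
  r <- spearmanCor(c(1, 2, 2, 4), c(3, 1, 2, 4))
  expect_equal(r$rho, oracleSpearmanRho(c(1, 2, 2, 4), c(3, 1, 2, 4)),
               tolerance = 1e-12)
  # monotone data
  x <- c(0.3, 1.1, 2.2, 5.1, 9)
  expect_equal(spearmanCor(x, exp(x))$rho, 1)
  expect_equal(spearmanCor(x, -x)$rho, -1)
  # invariance under strictly monotone transforms
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(spearmanCor(a, b)$rho, spearmanCor(exp(a), b^3 + 2 * b)$rho,
                 tolerance = 1e-12)
  }
  # degenerate: constant vector
  dg <- spearmanCor(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$rho))
})

test_that("Spearman p matches reference routines on random vectors", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    if (i %% 4 == 0) { x <- round(x * 2) / 2 }  # ties
    r <- spearmanCor(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(r$rho, unname(ref$estimate), tolerance = 1e-10)
    # same t-approximation p as the textbook formula
    tt <- r$rho * sqrt((n - 2) / (1 - r$rho^2))
    expect_equal(r$p, 2 * pt(-abs(tt), n - 2), tolerance = 1e-10)
  }
})

test_that("exact permutation Spearman p equals full enumeration", {
  enumerateP <- function(x, y) {
    n <- length(x)
    rx <- oracleRank(x); ry <- oracleRank(y)
    obs <- oracleSpearmanRho(x, y)
    perms <- NULL
    permute <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        out <- c(out, lapply(permute(v[-i]), function(p) c(v[i], p)))
      out
    }
    rhos <- vapply(permute(seq_len(n)), function(pm) {
      ryp <- ry[pm]
      sum((rx - mean(rx)) * (ryp - mean(ryp))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ryp - mean(ryp))^2))
    }, numeric(1))
    mean(abs(rhos) >= abs(obs) - 1e-12)
  }
  set.seed(303)
  for (n in c(4, 5, 6, 7)) {
    x <- rnorm(n); y <- rnorm(n)
    r <- spearmanCor(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p, enumerateP(x, y), tolerance = 1e-12)
  }
  expect_error(spearmanCor(c(1, 1, 2, 3), c(1, 2, 3, 4), exact = TRUE),
               "ties")
})

test_that("follow-up change matches construction and flags mismatches", {
  meas <- function(ids, vol, pct, method = "AI1") {
    do.call(rbind, lapply(seq_along(ids), function(i)
      data.frame(subject_id = ids[i], region = "hemisphere",
                 method = method, volume_ml = vol[i], percentage = pct[i],
                 stringsAsFactors = FALSE)))
  }
  rec <- function(ids, nihss, mrs, tp) {
    validateClinicalTable(data.frame(
      subject_id = ids, affected_side = "L", nihss = nihss, mrs = mrs,
      timepoint = tp, stringsAsFactors = FALSE))
  }
  ids <- c("a", "b", "c")
  pre <- meas(ids, c(10, 20, 30), c(5, 10, 15))
  preR <- rec(ids, c(5, 8, 10), c(2, 3, 4), "pre")

  # post = pre: all changes zero, degenerate p = 1
  fc <- followupChange(pre, pre, preR, rec(ids, c(5, 8, 10),
                                           c(2, 3, 4), "post"))
  expect_true(all(fc$changes$volume_change == 0))
  expect_equal(fc$continuous$p, rep(1, 2))

  post <- meas(ids, c(8, 15, 29), c(4, 8, 15))
  postR <- rec(ids, c(2, 4, 9), c(1, 2, 4), "post")
  fc2 <- followupChange(pre, post, preR, postR)
  expect_equal(fc2$changes$volume_change, c(2, 5, 1))
  vol <- fc2$continuous[fc2$continuous$measure == "volume_ml", ]
  expect_equal(vol$change_mean, mean(c(2, 5, 1)))
  expect_equal(vol$change_mean, vol$pre_mean - vol$post_mean,
               tolerance = 1e-12)
  expect_equal(fc2$scores$change_median[fc2$scores$score == "nihss"],
               median(c(3, 4, 1)))
  expect_equal(fc2$partition$n_improved, 3L)

  # unmatched ids are dropped with a warning
  post2 <- meas(c("a", "b", "zzz"), c(8, 15, 1), c(4, 8, 1))
  expect_warning(
    fc3 <- followupChange(pre, post2, preR,
                          rec(c("a", "b", "zzz"), c(1, 1, 1),
                              c(1, 1, 1), "post")),
    "unmatched")
  expect_setequal(unique(fc3$changes$subject_id), c("a", "b"))
})

test_that("cohort report tables carry the forced method ordering", {
  set.seed(77)
  ids <- sprintf("s%02d", 1:12)
  base <- runif(12, 20, 60)
  bump <- runif(12, 0.5, 2)     # AI2 always larger, per the voxel ordering
  m1 <- data.frame(subject_id = ids, region = "hemisphere", method = "AI1",
                   volume_ml = base, percentage = base / 6,
                   stringsAsFactors = FALSE)
  m2 <- m1; m2$method <- "AI2"; m2$volume_ml <- base + bump
  m2$percentage <- (base + bump) / 6
  meas <- rbind(m1, m2)
  recs <- validateClinicalTable(data.frame(
    subject_id = ids, affected_side = "L",
    nihss = pmin(round(base / 3), 42), mrs = pmin(round(base / 12), 6),
    timepoint = "pre", stringsAsFactors = FALSE))
  rep <- cohortReport(meas, recs)
  expect_true(all(rep$comparison$diff_mean > 0))
  expect_true(all(rep$agreement$bias < 0))   # AI1 - AI2 < 0
  expect_true(all(rep$correlations$rho > 0)) # monotone score link
  expect_true(all(c("comparison", "correlations", "agreement") %in%
                    names(rep)))
  # identical methods injected: all-zero differences
  m2z <- m1; m2z$method <- "AI2"
  repz <- cohortReport(rbind(m1, m2z), recs)
  expect_true(all(repz$comparison$diff_mean == 0))
  expect_warning(cohortReport(meas, NULL), "skipped")
  expect_error(cohortReport(meas[meas$subject_id %in% ids[1:2], ], recs),
               "3 subjects")
})
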