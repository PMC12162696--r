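## Cohort-level statistics: paired t comparison of the two AI methods,
## Bland-Altman agreement, Spearman correlation with clinical scores, and
## paired follow-up change. The estimators are written out from their
## defining formulas because the degenerate-case contracts (zero-variance
## differences, exact-permutation Spearman p) are part of the interface.

#' Paired t-test from its defining formula
#'
#' For paired vectors computes \eqn{d = x - y},
#' \eqn{t = \bar d / (s_d / \sqrt n)} with the \eqn{n-1} denominator in
#' \eqn{s_d}, and a two-sided p-value from the t distribution with
#' \eqn{n - 1} degrees of freedom. When every difference is identical
#' (\eqn{s_d = 0}) the test is flagged degenerate: p = 1 if the common
#' difference is 0, else p = 0.
#'
#' @param x,y numeric vectors of equal length `n >= 2`
#' @return a list of class `pairedComparison`: `n`, `meanDiff`, `sdDiff`,
#'   `t`, `df`, `p`, `degenerate`
#' @export
pairedT <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("paired test needs n >= 2", call. = FALSE)
  d <- x - y
  if (any(!is.finite(d))) stop("non-finite differences", call. = FALSE)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    out <- list(n = n, meanDiff = m, sdDiff = 0,
                t = if (m == 0) NA_real_ else sign(m) * Inf,
                df = n - 1L, p = if (m == 0) 1 else 0, degenerate = TRUE)
  } else {
    tt <- m / (s / sqrt(n))
    out <- list(n = n, meanDiff = m, sdDiff = s, t = tt, df = n - 1L,
                p = 2 * stats::pt(-abs(tt), df = n - 1), degenerate = FALSE)
  }
  structure(out, class = "pairedComparison")
}

#' @export
print.pairedComparison <- function(x, ...) {
  cat(sprintf(
    "Paired t: n=%d, mean diff=%.4g (sd %.4g), t=%.4g, df=%d, p=%.3g%s\n",
    x$n, x$meanDiff, x$sdDiff, x$t, x$df, x$p,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' Bias is the mean of the paired differences `x - y`; the limits of
#' agreement are `bias +/- 1.96 * sd` of the differences (n-1 denominator).
#'
#' @param x,y numeric vectors of equal length `n >= 2`
#' @return a list of class `agreementStats`: `n`, `bias`, `sdDiff`,
#'   `loaLow`, `loaHigh`
#' @export
blandAltman <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("Bland-Altman needs n >= 2", call. = FALSE)
  d <- x - y
  if (any(!is.finite(d))) stop("non-finite differences", call. = FALSE)
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(n = n, bias = bias, sdDiff = s,
                 loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s),
            class = "agreementStats")
}

#' @export
print.agreementStats <- function(x, ...) {
  cat(sprintf("Bland-Altman: n=%d, bias=%.4g, LoA [%.4g, %.4g]\n",
              x$n, x$bias, x$loaLow, x$loaHigh))
  invisible(x)
}

## all permutations of 1..n as an n! x n matrix (n <= 9)
.allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (pos in seq_len(n)) {
    block <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[block, pos] <- n
    out[block, setdiff(seq_len(n), pos)] <- sub
  }
  out
}

#' Spearman rank correlation with exact small-sample p
#'
#' Ranks use midranks for ties; rho is the Pearson correlation of the rank
#' vectors. The two-sided p-value uses full permutation enumeration when
#' `n <= 9` and neither vector is tied, and otherwise the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} with `n - 2` degrees of freedom.
#' If either rank vector has zero variance rho is undefined and flagged.
#'
#' @param x,y numeric vectors of equal length `n >= 3`
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact permutation
#'   p-value; default `NULL` chooses it for `n <= 9` without ties
#' @return a list of class `correlationResult`: `n`, `rho`, `p`, `method`
#'   (`"exact"` or `"t-approximation"`), `degenerate`
#' @export
spearmanCor <- function(x, y, exact = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("Spearman correlation needs n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(structure(list(n = n, rho = NA_real_, p = NA_real_,
                          method = "undefined", degenerate = TRUE),
                     class = "correlationResult"))
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (is.null(exact)) exact <- n <= 9 && !ties
  if (exact && ties)
    stop("exact permutation p is only defined without ties", call. = FALSE)
  if (exact) {
    perms <- .allPerms(n)
    ## no ties: rho = 1 - 6*sum(d^2) / (n (n^2-1))
    d2 <- rowSums((matrix(rx[perms], nrow(perms), n) -
                     matrix(ry, nrow(perms), n, byrow = TRUE))^2)
    rhoAll <- 1 - 6 * d2 / (n * (n^2 - 1))
    p <- mean(abs(rhoAll) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    method <- "t-approximation"
  }
  structure(list(n = n, rho = rho, p = p, method = method,
                 degenerate = FALSE),
            class = "correlationResult")
}

#' @export
print.correlationResult <- function(x, ...) {
  cat(sprintf("Spearman: n=%d, rho=%.4f, p=%.3g (%s)\n",
              x$n, x$rho, x$p, x$method))
  invisible(x)
}

## median (min, max) formatted summary used for score tables
.medRange <- function(v) {
  c(median = stats::median(v), min = min(v), max = max(v))
}

#' Paired pre/post follow-up change
#'
#' Matches subjects by `subject_id` across timepoints (unmatched ids are
#' dropped with a warning), computes per-subject change = pre - post for
#' the regional measures (positive = reduced hypometabolic burden) and the
#' clinical scores, and summarises: mean +/- sd and a paired t-test for the
#' continuous measures, median (range) for the scores. Subjects are also
#' partitioned by the sign of their affected-hemisphere volume change.
#'
#' @param preMeasures,postMeasures long measure tables (columns
#'   `subject_id`, `region`, `method`, `volume_ml`, `percentage`) as
#'   produced by [runCohort()]
#' @param preRecords,postRecords clinical tables for the two timepoints
#' @return a list of class `followupSummary`: `changes` (per subject,
#'   region, method), `continuous` (group summary + paired t per region,
#'   method, measure), `scores` (median-range summaries + paired t),
#'   `partition` (improved vs not, per method)
#' @export
followupChange <- function(preMeasures, postMeasures,
                           preRecords, postRecords) {
  ids <- intersect(unique(preMeasures$subject_id),
                   unique(postMeasures$subject_id))
  dropped <- setdiff(union(unique(preMeasures$subject_id),
                           unique(postMeasures$subject_id)), ids)
  if (length(dropped))
    warning("unmatched subject ids dropped: ",
            paste(dropped, collapse = ", "))
  if (length(ids) < 2)
    stop("need at least 2 matched subjects", call. = FALSE)
  pre <- preMeasures[preMeasures$subject_id %in% ids, ]
  post <- postMeasures[postMeasures$subject_id %in% ids, ]
  key <- function(d) paste(d$subject_id, d$region, d$method, sep = "\r")
  post <- post[match(key(pre), key(post)), ]
  stopifnot(!anyNA(post$subject_id))
  changes <- data.frame(subject_id = pre$subject_id, region = pre$region,
                        method = pre$method,
                        volume_change = pre$volume_ml - post$volume_ml,
                        percentage_change = pre$percentage - post$percentage,
                        stringsAsFactors = FALSE)

  cells <- unique(pre[c("region", "method")])
  continuous <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- pre$region == cells$region[i] & pre$method == cells$method[i]
    do.call(rbind, lapply(c("volume_ml", "percentage"), function(ms) {
      a <- pre[[ms]][sel]; b <- post[[ms]][sel]
      tt <- pairedT(a, b)
      data.frame(region = cells$region[i], method = cells$method[i],
                 measure = ms,
                 pre_mean = mean(a), pre_sd = stats::sd(a),
                 post_mean = mean(b), post_sd = stats::sd(b),
                 change_mean = tt$meanDiff, change_sd = tt$sdDiff,
                 t = tt$t, df = tt$df, p = tt$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(continuous) <- NULL

  pr <- preRecords[match(ids, preRecords$subject_id), ]
  po <- postRecords[match(ids, postRecords$subject_id), ]
  scores <- do.call(rbind, lapply(c("nihss", "mrs"), function(sc) {
    a <- pr[[sc]]; b <- po[[sc]]
    tt <- pairedT(as.numeric(a), as.numeric(b))
    data.frame(score = sc,
               pre_median = .medRange(a)[1], pre_min = min(a),
               pre_max = max(a),
               post_median = .medRange(b)[1], post_min = min(b),
               post_max = max(b),
               change_median = stats::median(a - b),
               change_min = min(a - b), change_max = max(a - b),
               p = tt$p, stringsAsFactors = FALSE)
  }))
  rownames(scores) <- NULL

  hemi <- changes[changes$region == "hemisphere", ]
  partition <- do.call(rbind, lapply(unique(hemi$method), function(mt) {
    v <- hemi$volume_change[hemi$method == mt]
    data.frame(method = mt, n_improved = sum(v > 0),
               n_not_improved = sum(v <= 0), stringsAsFactors = FALSE)
  }))

  structure(list(changes = changes, continuous = continuous,
                 scores = scores, partition = partition),
            class = "followupSummary")
}

#' Cohort-level report tables
#'
#' From per-subject regional measures under both AI methods and the
#' clinical table, builds (a) the per-region AI2-vs-AI1 paired comparison,
#' (b) Spearman correlations of hypometabolic volume and percentage with
#' NIHSS and mRS per region and method, and (c) Bland-Altman agreement
#' summaries between the methods.
#'
#' @param measures long measure table (columns `subject_id`, `region`,
#'   `method`, `volume_ml`, `percentage`) covering methods `AI1` and `AI2`
#' @param records clinical table (may be `NULL`: correlations are skipped
#'   with a warning)
#' @return a list of class `cohortReport` with data.frames `comparison`,
#'   `correlations` (possibly `NULL`) and `agreement`
#' @export
cohortReport <- function(measures, records = NULL) {
  ids <- unique(measures$subject_id)
  if (length(ids) < 3) stop("need at least 3 subjects", call. = FALSE)
  regions <- unique(measures$region)
  grab <- function(rg, mt, ms) {
    sel <- measures$region == rg & measures$method == mt
    d <- measures[sel, ]
    d[[ms]][match(ids, d$subject_id)]
  }
  comparison <- do.call(rbind, lapply(regions, function(rg) {
    do.call(rbind, lapply(c("volume_ml", "percentage"), function(ms) {
      a1 <- grab(rg, "AI1", ms); a2 <- grab(rg, "AI2", ms)
      tt <- pairedT(a2, a1)
      data.frame(region = rg, measure = ms,
                 ai1_mean = mean(a1), ai1_sd = stats::sd(a1),
                 ai2_mean = mean(a2), ai2_sd = stats::sd(a2),
                 diff_mean = tt$meanDiff, t = tt$t, df = tt$df, p = tt$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(comparison) <- NULL

  agreement <- do.call(rbind, lapply(regions, function(rg) {
    do.call(rbind, lapply(c("volume_ml", "percentage"), function(ms) {
      ba <- blandAltman(grab(rg, "AI1", ms), grab(rg, "AI2", ms))
      data.frame(region = rg, measure = ms, bias = ba$bias,
                 sd = ba$sdDiff, loa_low = ba$loaLow, loa_high = ba$loaHigh,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(agreement) <- NULL

  correlations <- NULL
  if (is.null(records)) {
    warning("no clinical records supplied; correlations skipped")
  } else {
    rec <- records[match(ids, records$subject_id), ]
    correlations <- do.call(rbind, lapply(regions, function(rg) {
      do.call(rbind, lapply(c("AI1", "AI2"), function(mt) {
        do.call(rbind, lapply(c("volume_ml", "percentage"), function(ms) {
          do.call(rbind, lapply(c("nihss", "mrs"), function(sc) {
            ct <- spearmanCor(grab(rg, mt, ms), as.numeric(rec[[sc]]))
            data.frame(region = rg, method = mt, measure = ms, score = sc,
                       rho = ct$rho, p = ct$p, n = ct$n,
                       stringsAsFactors = FALSE)
          }))
        }))
      }))
    }))
    rownames(correlations) <- NULL
  }
  structure(list(comparison = comparison, correlations = correlations,
                 agreement = agreement),
            class = "cohortReport")
}

#' Write a cohort report (and optional follow-up summary) as CSV files
#'
#' @param report a [cohortReport()] result
#' @param dir output directory (created if needed)
#' @param followup optional [followupChange()] result
#' @return the directory, invisibly
#' @export
writeCohortReport <- function(report, dir, followup = NULL) {
  stopifnot(inherits(report, "cohortReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$comparison, file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(report$agreement, file.path(dir, "agreement.csv"),
                   row.names = FALSE)
  if (!is.null(report$correlations))
    utils::write.csv(report$correlations,
                     file.path(dir, "correlations.csv"), row.names = FALSE)
  if (!is.null(followup)) {
    utils::write.csv(followup$continuous, file.path(dir, "followup.csv"),
                     row.names = FALSE)
    utils::write.csv(followup$changes,
                     file.path(dir, "followup_changes.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Printed follow-up group means of the affected hemisphere
#'
#' Loads the reference table of pre/post follow-up group means (mean and sd
#' of affected-hemisphere hypometabolic volume and percentage, and the
#' printed mean change) shipped with the package, used to check that the
#' change column is the difference of the group means.
#'
#' @return a data.frame with columns `method`, `measure`, `pre_mean`,
#'   `pre_sd`, `post_mean`, `post_sd`, `change_mean`, `change_sd`
#' @export
referenceFollowupTable <- function() {
  p <- system.file("extdata", "followup_reference.csv", package = "aindex",
                   mustWork = TRUE)
  utils::read.csv(p, stringsAsFactors = FALSE)
}
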