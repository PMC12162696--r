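## Orchestration: per-subject prep -> asymmetry -> volumetry, and the
## cohort driver that adds the statistical report and follow-up analysis.

#' Run the asymmetry pipeline for one subject
#'
#' Executes, in order: optional Van-Cittert partial-volume correction, SUVR
#' normalization against the reference mask, infarct-pair exclusion,
#' voxel-wise AI mapping for the requested methods, 10 percent threshold
#' volumetry and regional quantification.
#'
#' @param volume a [BrainVolume] (PET activity or precomputed SUVR)
#' @param atlas a [BrainAtlas] on the same grid
#' @param infarct a [BrainMask] of the infarct core
#' @param reference a [BrainMask] of the reference region (pons); ignored
#'   when `volume` already carries SUVR units and `normalize = FALSE`
#' @param affectedSide `"L"` or `"R"`
#' @param methods character subset of `c("AI1", "AI2")`
#' @param thresholdPct hypometabolism threshold, percent (default 10)
#' @param pvc optional [pvcParams()]; `NULL` skips partial-volume correction
#' @param normalize divide by the reference-region mean (default TRUE)
#' @return a data.frame of regional measures (columns `region`, `method`,
#'   `volume_ml`, `percentage`, `evaluable_ml`); attribute `"aiMaps"`
#'   carries the [AsymmetryMap] objects by method
#' @export
runSubject <- function(volume, atlas, infarct, reference = NULL,
                       affectedSide = c("L", "R"),
                       methods = c("AI1", "AI2"), thresholdPct = 10,
                       pvc = NULL, normalize = TRUE) {
  affectedSide <- match.arg(affectedSide)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(is(volume, "BrainVolume"), is(atlas, "BrainAtlas"),
            is(infarct, "BrainMask"), thresholdPct > 0)
  stopifnotSameGrid(volume, atlas, "volume and atlas")
  stopifnotSameGrid(volume, infarct, "volume and infarct mask")
  if (!is.null(pvc)) volume <- vanCittert(volume, pvc)
  if (normalize) {
    if (is.null(reference))
      stop("normalize = TRUE requires a reference mask", call. = FALSE)
    stopifnotSameGrid(volume, reference, "volume and reference mask")
    volume <- suvrNormalize(volume, reference)
  }
  excl <- exclusionMask(infarct)
  maps <- lapply(methods, function(mt)
    aiMap(volume, affectedSide, mt, exclusion = excl))
  names(maps) <- methods
  out <- do.call(rbind, lapply(methods, function(mt) {
    regionalQuantify(hypometabolicMask(maps[[mt]], thresholdPct),
                     atlas, maps[[mt]])
  }))
  rownames(out) <- NULL
  attr(out, "aiMaps") <- maps
  out
}

#' Run the pipeline over a simulated cohort
#'
#' Applies [runSubject()] to every subject of an `aiCohort` (see
#' [simulateCohort()]), then builds the [cohortReport()]. A failing subject
#' is quarantined with a warning rather than aborting the run. When a
#' paired follow-up cohort is supplied, the [followupChange()] analysis is
#' added.
#'
#' @param cohort an `aiCohort`
#' @param postCohort optional matched post-timepoint `aiCohort` (from
#'   [simulateFollowup()]`$post`)
#' @param thresholdPct threshold in percent (default 10)
#' @param pvc optional [pvcParams()] applied to every subject
#' @param outDir optional directory: report CSVs, the per-subject measure
#'   table and a JSON run manifest of all parameters are written there
#' @return a list of class `aiCohortResult`: `measures` (long per-subject
#'   table), `report` ([cohortReport()]), `followup` (or `NULL`),
#'   `postMeasures` (or `NULL`), `failed` (character subject ids)
#' @export
runCohort <- function(cohort, postCohort = NULL, thresholdPct = 10,
                      pvc = NULL, outDir = NULL) {
  stopifnot(inherits(cohort, "aiCohort"))
  quantifyAll <- function(ch) {
    rows <- list(); failed <- character()
    for (s in ch$subjects) {
      side <- ch$records$affected_side[
        match(s$subject_id, ch$records$subject_id)]
      m <- tryCatch(
        runSubject(s$volume, ch$atlas, s$infarct, ch$pons,
                   affectedSide = side, thresholdPct = thresholdPct,
                   pvc = pvc),
        error = function(e) {
          warning("subject ", s$subject_id, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(m)) failed <- c(failed, s$subject_id)
      else {
        m$subject_id <- s$subject_id
        attr(m, "aiMaps") <- NULL
        rows[[length(rows) + 1L]] <- m
      }
    }
    list(measures = do.call(rbind, rows), failed = failed)
  }
  qa <- quantifyAll(cohort)
  report <- cohortReport(qa$measures, cohort$records)
  followup <- NULL; postMeasures <- NULL
  if (!is.null(postCohort)) {
    stopifnot(inherits(postCohort, "aiCohort"))
    qpost <- quantifyAll(postCohort)
    postMeasures <- qpost$measures
    followup <- followupChange(qa$measures, postMeasures,
                               cohort$records, postCohort$records)
  }
  res <- structure(list(measures = qa$measures, report = report,
                        followup = followup, postMeasures = postMeasures,
                        failed = qa$failed),
                   class = "aiCohortResult")
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(qa$measures, file.path(outDir, "measures.csv"),
                     row.names = FALSE)
    writeCohortReport(report, outDir, followup = followup)
    manifest <- list(threshold_pct = thresholdPct,
                     pvc = if (is.null(pvc)) NULL else unclass(pvc),
                     mirror_axis = mirrorAxis(cohort$atlas),
                     voxel_size_mm = voxelSize(cohort$atlas),
                     n_subjects = length(cohort$subjects),
                     n_failed = length(qa$failed),
                     seed = cohort$spec$seed)
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}

#' Read a pipeline configuration from YAML
#'
#' The configuration names the input files (`suvr`, `atlas_labels`,
#' `atlas_lut`, `infarct`, `reference`, `clinical`), the `affected_side`,
#' and optional keys `threshold_pct`, `mirror_axis`, `normalize` and a
#' `pvc` block (`sigma_mm`, `iterations`, `relaxation`, `clamp`).
#'
#' @param path YAML file
#' @return a named list of class `pipelineConfig`
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- c("suvr", "atlas_labels", "atlas_lut", "infarct")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$threshold_pct)) cfg$threshold_pct <- 10
  if (cfg$threshold_pct <= 0)
    stop("threshold_pct must be > 0", call. = FALSE)
  if (is.null(cfg$mirror_axis)) cfg$mirror_axis <- 1L
  structure(cfg, class = "pipelineConfig")
}

#' Run one subject from a file-based configuration
#'
#' Thin file-based wrapper over [runSubject()]: reads the NIfTI volumes,
#' atlas and masks named in the configuration, runs the pipeline, and
#' writes the regional measure table (and a parameter manifest) to
#' `outDir` when given.
#'
#' @param config a [readPipelineConfig()] result or path to a YAML file
#' @param affectedSide override for the config's `affected_side`
#' @param outDir optional output directory for `measures.csv` and
#'   `run_manifest.json`
#' @return the regional measure data.frame, as from [runSubject()]
#' @export
runPipeline <- function(config, affectedSide = NULL, outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  ax <- as.integer(config$mirror_axis)
  volume <- readVolume(config$suvr, mirrorAxis = ax)
  atlas <- readAtlas(config$atlas_labels, config$atlas_lut, mirrorAxis = ax)
  infarct <- readMask(config$infarct, mirrorAxis = ax)
  reference <- if (!is.null(config$reference))
    readMask(config$reference, mirrorAxis = ax)
  normalize <- if (is.null(config$normalize)) !is.null(reference)
    else isTRUE(config$normalize)
  pvc <- if (!is.null(config$pvc))
    pvcParams(psfSigma = config$pvc$sigma_mm %||% 3,
              iterations = config$pvc$iterations %||% 10L,
              relaxation = config$pvc$relaxation %||% 1,
              clamp = config$pvc$clamp %||% TRUE)
  side <- affectedSide %||% config$affected_side
  if (is.null(side)) stop("affected_side is required", call. = FALSE)
  out <- runSubject(volume, atlas, infarct, reference,
                    affectedSide = side, thresholdPct = config$threshold_pct,
                    pvc = pvc, normalize = normalize)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    tab <- out; attr(tab, "aiMaps") <- NULL
    utils::write.csv(tab, file.path(outDir, "measures.csv"),
                     row.names = FALSE)
    manifest <- list(threshold_pct = config$threshold_pct,
                     mirror_axis = ax, affected_side = side,
                     normalize = normalize,
                     pvc = if (is.null(pvc)) NULL else unclass(pvc))
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
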