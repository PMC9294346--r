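#' Pipeline configuration
#'
#' Flat configuration for the end-to-end quantification run. Defaults follow
#' the standard operating point of the method: 416-px segments, 50% overlap
#' for label/training data but non-overlapping segments for counting
#' (overlap-mode counting with ellipse merging deviates more from
#' annotators and is kept available behind `overlapFrac > 0`), ground-truth
#' boxes at 0.9756% of the well width, IoU 0.1 for matching, a 0.05 F1
#' sweep grid, and 20% box shrink for the merge step. When
#' `detectionThreshold` is `NULL` it is chosen by the F1 sweep on the first
#' (validation) well; 0.25 is the documented fallback when no ground truth
#' is available to sweep against.
#'
#' @param segmentSizePx segment side (default 416).
#' @param overlapFrac counting overlap fraction (default 0, non-overlap).
#' @param boxFraction ground-truth box side as a fraction of well width.
#' @param iouThreshold IoU for matching (default 0.1).
#' @param sweepStep F1 sweep increment (default 0.05).
#' @param detectionThreshold confidence cut; `NULL` = choose by sweep.
#' @param shrinkFactor merge-step box shrink (default 0.2).
#' @param intensityThreshold reference-detector threshold.
#' @param minAreaPx,maxAreaPx reference-detector area filter; `NULL` =
#'   derived from the expected cell area implied by `boxFraction`.
#' @param exclusionPct optional Bland-Altman outlier bound (percent).
#' @param seed integer seed echoed into reports.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(segmentSizePx = 416L, overlapFrac = 0,
                           boxFraction = 0.009756, iouThreshold = 0.1,
                           sweepStep = 0.05, detectionThreshold = NULL,
                           shrinkFactor = 0.2, intensityThreshold = 0.6,
                           minAreaPx = NULL, maxAreaPx = NULL,
                           exclusionPct = NULL, seed = 1L) {
  cfg <- list(segmentSizePx = as.integer(segmentSizePx),
              overlapFrac = overlapFrac, boxFraction = boxFraction,
              iouThreshold = iouThreshold, sweepStep = sweepStep,
              detectionThreshold = detectionThreshold,
              shrinkFactor = shrinkFactor,
              intensityThreshold = intensityThreshold,
              minAreaPx = minAreaPx, maxAreaPx = maxAreaPx,
              exclusionPct = exclusionPct, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys are the arguments of [pipelineConfig()]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return A `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", toString(bad))
  do.call(pipelineConfig, vals)
}

# detector area bounds derived from the expected cell scale: the inscribed
# disc of the fixed-fraction ground-truth box, with generous head room
derivedAreaBounds <- function(cfg, wellWidthPx) {
  side <- boxSideFromWidth(wellWidthPx, cfg$boxFraction)
  discArea <- pi * (side / 2)^2
  list(minAreaPx = if (is.null(cfg$minAreaPx))
         max(20L, as.integer(round(0.15 * discArea))) else cfg$minAreaPx,
       maxAreaPx = if (is.null(cfg$maxAreaPx))
         as.integer(round(6 * discArea)) else cfg$maxAreaPx)
}

#' Reference detector configured for a given well width
#'
#' Builds the classical reference detector ([detectSegment()]) with area
#' bounds derived from the expected cell scale: 0.15x to 6x the area of
#' the disc inscribed in the fixed-fraction ground-truth box implied by
#' `cfg$boxFraction` (unless the config fixes explicit bounds).
#'
#' @param cfg a `PipelineConfig` from [pipelineConfig()].
#' @param wellWidthPx well-image width in pixels.
#' @return A detector function suitable for [runWell()].
#' @export
referenceDetectorFor <- function(cfg, wellWidthPx) {
  ab <- derivedAreaBounds(cfg, wellWidthPx)
  params <- detectorParams(intensityThreshold = cfg$intensityThreshold,
                           minAreaPx = ab$minAreaPx,
                           maxAreaPx = ab$maxAreaPx)
  function(raster) detectSegment(raster, params)
}

#' End-to-end quantification of a set of wells
#'
#' Runs the whole pipeline on ground-truthed wells: tile each well, detect
#' on every segment with the reference detector (or a supplied one), select
#' the detection threshold by F1 sweep on the first well when not fixed in
#' the config, filter, deduplicate with ellipse merging when segments
#' overlap, count per well, and compare against the annotated counts (RMSE,
#' Pearson, Bland-Altman when at least 3 wells are available). When
#' `outDir` is given, writes `counts.csv`, `metrics.json` (with a full
#' config echo so every run is reproducible from its report alone),
#' `sweep.csv`, and a run log.
#'
#' @param wells list of [SynthWell-class] objects (or any objects carrying
#'   `image` ([WellImage-class]), `marks` and `boxes` slots).
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @param detector optional detector function; default: reference detector
#'   with config-derived parameters.
#' @param outDir optional output directory.
#' @return List with `config`, `detectionThreshold`, `sweep`, `pairs`
#'   (per-well counts), `perExperiment` (RMSE by experiment), `agreement`
#'   (an [AgreementStats-class] or `NULL`), and `detections` (list of
#'   [WellDetections-class]).
#' @export
runQuantify <- function(wells, config = pipelineConfig(), detector = NULL,
                        outDir = NULL) {
  stopifnot(length(wells) >= 1)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("osteoquant quantify: %d wells, seed %d", length(wells), config$seed)
  w1 <- wells[[1]]@image
  if (is.null(detector)) detector <- referenceDetectorFor(config, imageWidth(w1))
  grids <- lapply(wells, function(wl)
    gridDims(imageWidth(wl@image), imageHeight(wl@image),
             config$segmentSizePx, config$overlapFrac))
  raw <- mapply(function(wl, g) runWell(wl@image, g, detector, 0),
                wells, grids, SIMPLIFY = FALSE)
  # operating point: fixed, or F1-optimal on the first (validation) well
  sweep <- NULL
  thr <- config$detectionThreshold
  if (is.null(thr)) {
    gt1 <- wells[[1]]@boxes
    if (nrow(gt1)) {
      sw <- sweepThresholds(detections(raw[[1]]), gt1,
                            iouThreshold = config$iouThreshold,
                            step = config$sweepStep)
      sweep <- sw$sweep
      thr <- sw$bestThreshold
      say("detection threshold from F1 sweep on '%s': %.2f",
          wellId(raw[[1]]), thr)
    } else {
      thr <- 0.25
      say("no ground truth to sweep; using fallback threshold 0.25")
    }
  }
  dets <- lapply(raw, function(wd) {
    keep <- wd@records[wd@records$confidence >= thr, , drop = FALSE]
    rownames(keep) <- NULL
    initialize(wd, records = keep)
  })
  truth <- data.frame(
    wellId = vapply(wells, wellId, character(1)),
    experimentId = vapply(wells, function(w) experimentId(w@image),
                          character(1)),
    count = vapply(wells, function(w) nrow(truthMarks(w)), integer(1)))
  pairs <- countWells(dets, truth, shrinkFactor = config$shrinkFactor)
  say("counted %d wells in %s mode", nrow(pairs), pairs$mode[1])
  agreement <- NULL
  usable <- sum(pairs$countA + pairs$countB > 0)
  if (usable >= 3)
    agreement <- blandAltman(pairs, exclusionPct = config$exclusionPct)
  perExp <- perExperimentRmse(pairs)
  res <- list(config = config, detectionThreshold = thr, sweep = sweep,
              pairs = pairs, perExperiment = perExp, agreement = agreement,
              detections = dets, log = log)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pairs, file.path(outDir, "counts.csv"),
                     row.names = FALSE)
    if (!is.null(sweep))
      utils::write.csv(sweep, file.path(outDir, "sweep.csv"),
                       row.names = FALSE)
    metrics <- list(config = unclass(config), detectionThreshold = thr,
                    perExperiment = perExp,
                    agreement = if (!is.null(agreement))
                      agreementAsList(agreement) else NULL)
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    writeLines(log, file.path(outDir, "run.log"))
  }
  res
}

#' Flatten AgreementStats for serialization
#'
#' @param stats an [AgreementStats-class].
#' @return Named list of the scalar statistics and the exclusion table.
#' @export
agreementAsList <- function(stats) {
  list(nPairs = stats@nPairs, rmse = stats@rmse, pearsonR = stats@pearsonR,
       biasPct = stats@biasPct, sdPct = stats@sdPct,
       loaLowPct = stats@loaLowPct, loaHighPct = stats@loaHighPct,
       ciBias = stats@ciBias, ciLoaLow = stats@ciLoaLow,
       ciLoaHigh = stats@ciLoaHigh, normalityP = stats@normalityP,
       excluded = stats@excluded)
}
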