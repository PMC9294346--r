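#' Accessors for osteoquant classes
#'
#' Small accessor generics for the package's S4 containers: image pixels and
#' dimensions, well/experiment identifiers, segment-lattice geometry,
#' detection records, and the scalar agreement statistics.
#'
#' @param object an osteoquant S4 object.
#' @return The corresponding slot value (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("wellId", function(object) standardGeneric("wellId"))
#' @rdname accessors
#' @export
setGeneric("experimentId", function(object) standardGeneric("experimentId"))
#' @rdname accessors
#' @export
setGeneric("imageWidth", function(object) standardGeneric("imageWidth"))
#' @rdname accessors
#' @export
setGeneric("imageHeight", function(object) standardGeneric("imageHeight"))
#' @rdname accessors
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setGeneric("segmentStride", function(object) standardGeneric("segmentStride"))
#' @rdname accessors
#' @export
setGeneric("detections", function(object) standardGeneric("detections"))
#' @rdname accessors
#' @export
setGeneric("countingMode", function(object) standardGeneric("countingMode"))
#' @rdname accessors
#' @export
setGeneric("averagePrecisionValue",
           function(object) standardGeneric("averagePrecisionValue"))
#' @rdname accessors
#' @export
setGeneric("truthMarks", function(object) standardGeneric("truthMarks"))
#' @rdname accessors
#' @export
setGeneric("truthBoxes", function(object) standardGeneric("truthBoxes"))

#' @rdname accessors
setMethod("pixels", "WellImage", function(object) object@pixels)
#' @rdname accessors
setMethod("wellId", "WellImage", function(object) object@wellId)
#' @rdname accessors
setMethod("experimentId", "WellImage", function(object) object@experimentId)
#' @rdname accessors
setMethod("imageWidth", "WellImage", function(object) dim(object@pixels)[2])
#' @rdname accessors
setMethod("imageHeight", "WellImage", function(object) dim(object@pixels)[1])

#' @rdname accessors
setMethod("imageWidth", "SegmentGrid", function(object) object@widthPx)
#' @rdname accessors
setMethod("imageHeight", "SegmentGrid", function(object) object@heightPx)
#' @rdname accessors
setMethod("nSegments", "SegmentGrid",
          function(object) as.integer(object@nCols) * as.integer(object@nRows))
#' @rdname accessors
setMethod("segmentStride", "SegmentGrid", function(object) object@stridePx)
#' @rdname accessors
setMethod("dim", "SegmentGrid", function(x) c(x@nRows, x@nCols))

#' @rdname accessors
setMethod("wellId", "WellDetections", function(object) object@wellId)
#' @rdname accessors
setMethod("detections", "WellDetections", function(object) object@records)
#' @rdname accessors
setMethod("countingMode", "WellDetections", function(object) object@mode)
#' @rdname accessors
setMethod("length", "WellDetections", function(x) nrow(x@records))

#' @rdname accessors
setMethod("averagePrecisionValue", "PRCurve", function(object) object@ap)

#' @rdname accessors
setMethod("wellId", "SynthWell", function(object) object@image@wellId)
#' @rdname accessors
setMethod("pixels", "SynthWell", function(object) object@image@pixels)
#' @rdname accessors
setMethod("truthMarks", "SynthWell", function(object) object@marks)
#' @rdname accessors
setMethod("truthBoxes", "SynthWell", function(object) object@boxes)

setMethod("show", "WellImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("WellImage '%s' (experiment '%s'): %d x %d px, %s\n",
              object@wellId, object@experimentId, d[2], d[1],
              if (length(d) == 3L) sprintf("%d channels", d[3])
              else "grayscale"))
})

setMethod("show", "SegmentGrid", function(object) {
  cat(sprintf(paste0("SegmentGrid over %d x %d px: %d x %d segments of ",
                     "%d px (overlap %.0f%%, stride %d) = %d total\n"),
              object@widthPx, object@heightPx, object@nCols, object@nRows,
              object@segmentSizePx, 100 * object@overlapFrac,
              object@stridePx, nSegments(object)))
})

setMethod("show", "WellDetections", function(object) {
  cat(sprintf("WellDetections '%s': %d records, %s mode, canvas %d x %d px\n",
              object@wellId, nrow(object@records), object@mode,
              object@widthPx, object@heightPx))
})

setMethod("show", "DetectorParams", function(object) {
  cat(sprintf(paste0("DetectorParams: threshold %.2f, area [%d, %d] px, ",
                     "confidence '%s'\n"),
              object@intensityThreshold, object@minAreaPx, object@maxAreaPx,
              object@confidenceRule))
})

setMethod("show", "MatchTable", function(object) {
  cat(sprintf("MatchTable: %d detections vs %d ground truth @ IoU %.2f; %d TP, %d FP\n",
              nrow(object@table), object@nGroundTruth, object@iouThreshold,
              sum(object@table$tp), sum(!object@table$tp)))
})

setMethod("show", "PRCurve", function(object) {
  cat(sprintf("PRCurve: AP = %.4f over %d ground-truth boxes (%d ranks)\n",
              object@ap, object@nGroundTruth, nrow(object@curve)))
})

setMethod("show", "AgreementStats", function(object) {
  cat(sprintf("AgreementStats on %d pairs (%d excluded)\n", object@nPairs,
              nrow(object@excluded)))
  cat(sprintf("  RMSE %.2f, Pearson r %.3f\n", object@rmse, object@pearsonR))
  cat(sprintf("  bias %.2f%% [%.2f, %.2f], SD %.2f%%\n", object@biasPct,
              object@ciBias[1], object@ciBias[2], object@sdPct))
  cat(sprintf("  LoA [%.2f%%, %.2f%%]; normality p = %.3f\n",
              object@loaLowPct, object@loaHighPct, object@normalityP))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0("SynthConfig: %d x %d px, %d cells (width %.1f px, ",
                     "CV %.2f), background %.2f, darkness %.2f, seed %d\n"),
              object@widthPx, object@heightPx, object@nCells,
              object@cellWidthMeanPx, object@cellWidthCv,
              object@backgroundLevel, object@darknessFactor, object@seed))
})

setMethod("show", "SynthWell", function(object) {
  cat(sprintf("SynthWell '%s': %d cells, %d x %d px\n",
              object@image@wellId, nrow(object@marks),
              imageWidth(object@image), imageHeight(object@image)))
})
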