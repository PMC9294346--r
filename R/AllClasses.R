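#' @import methods
NULL

#' Whole-well microscopy image
#'
#' Container for one tiled, merged well image. Pixels are stored as a numeric
#' array in `[0, 1]` with dimensions `height x width` (grayscale) or
#' `height x width x 3` (RGB). Pixel coordinates throughout the package are
#' 0-based with the origin at the top-left corner, x increasing rightward
#' (columns) and y increasing downward (rows); pixel `(x, y)` covers the unit
#' square `[x, x+1) x [y, y+1)` so its center sits at `(x + 0.5, y + 0.5)`.
#'
#' @slot pixels numeric array, `[0, 1]` intensities.
#' @slot wellId character scalar identifying the well.
#' @slot experimentId character scalar identifying the experiment.
#'
#' @seealso [wellImage()], [readWellImage()], [gridDims()]
#' @exportClass WellImage
setClass("WellImage",
  representation(pixels = "array", wellId = "character",
                 experimentId = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (is.null(d) || !(length(d) %in% c(2L, 3L)))
      return("pixels must be a 2D (grayscale) or 3D (multichannel) array")
    if (d[1] < 1L || d[2] < 1L)
      return("image must be at least 1 x 1 pixels")
    if (length(d) == 3L && !(d[3] %in% c(1L, 3L)))
      return("only 1- or 3-channel images are supported")
    v <- range(object@pixels)
    if (is.na(v[1]) || v[1] < 0 || v[2] > 1)
      return("pixel intensities must lie in [0, 1] with no NAs")
    if (length(object@wellId) != 1L || length(object@experimentId) != 1L)
      return("wellId and experimentId must be single strings")
    TRUE
  })

#' Overlapping segment lattice over a well image
#'
#' Describes the decomposition of a well image into fixed-size square
#' segments whose origins lie at integer multiples of the stride,
#' `stride = segmentSize * (1 - overlapFrac)`. Segments in the last row or
#' column may extend past the image edge; [extractSegment()] pads them.
#'
#' @slot widthPx,heightPx integer, dimensions of the underlying well image.
#' @slot segmentSizePx integer, side length of each square segment.
#' @slot overlapFrac numeric in `[0, 1)`, fraction of overlap between
#'   neighbouring segments.
#' @slot stridePx integer, spacing between adjacent segment origins.
#' @slot nCols,nRows integer, lattice dimensions
#'   (`ceiling(width / stride)` and `ceiling(height / stride)`).
#'
#' @seealso [gridDims()], [nSegments()], [segmentOrigin()]
#' @exportClass SegmentGrid
setClass("SegmentGrid",
  representation(widthPx = "integer", heightPx = "integer",
                 segmentSizePx = "integer", overlapFrac = "numeric",
                 stridePx = "integer", nCols = "integer", nRows = "integer"),
  validity = function(object) {
    if (object@stridePx < 1L) return("stride must be >= 1 pixel")
    if (object@overlapFrac < 0 || object@overlapFrac >= 1)
      return("overlapFrac must lie in [0, 1)")
    if (object@nCols != ceiling(object@widthPx / object@stridePx) ||
        object@nRows != ceiling(object@heightPx / object@stridePx))
      return("lattice dimensions inconsistent with the ceiling rule")
    TRUE
  })

#' Per-well detection set
#'
#' All detections for one well in well-frame coordinates, together with the
#' counting mode implied by the segment grid they came from (`"overlap"` when
#' segments overlapped, `"nonoverlap"` otherwise). `records` is a data.frame
#' with columns `cx, cy, w, h, confidence` plus the originating segment
#' `row, col` (NA for imported well-frame detections).
#'
#' @slot wellId character scalar.
#' @slot mode character, `"overlap"` or `"nonoverlap"`.
#' @slot widthPx,heightPx integer, well canvas dimensions (the merge canvas).
#' @slot records data.frame of detections.
#'
#' @seealso [runWell()], [mergeDetections()], [countWells()]
#' @exportClass WellDetections
setClass("WellDetections",
  representation(wellId = "character", mode = "character",
                 widthPx = "integer", heightPx = "integer",
                 records = "data.frame"),
  validity = function(object) {
    if (!object@mode %in% c("overlap", "nonoverlap"))
      return("mode must be 'overlap' or 'nonoverlap'")
    need <- c("cx", "cy", "w", "h", "confidence")
    if (!all(need %in% names(object@records)))
      return(paste("records must have columns", paste(need, collapse = ", ")))
    if (nrow(object@records) > 0) {
      conf <- object@records$confidence
      if (any(conf < 0 | conf > 1)) return("confidence must lie in [0, 1]")
      if (any(object@records$w <= 0 | object@records$h <= 0))
        return("detection boxes must have positive width and height")
    }
    TRUE
  })

#' Reference detector parameters
#'
#' Parameters of the deterministic classical detector shipped with the
#' package: grayscale conversion, global intensity threshold, 8-connected
#' component extraction and an area filter. Confidence is assigned by
#' `confidenceRule`: `"area_scaled"` (component area / maxAreaPx, capped at
#' 1) or `"contrast_scaled"` (relative darkness of the component below the
#' threshold).
#'
#' @slot intensityThreshold numeric in `[0, 1]`, fraction of the dynamic
#'   range; pixels strictly darker than this are foreground.
#' @slot minAreaPx,maxAreaPx integer area filter bounds (inclusive).
#' @slot confidenceRule character, `"area_scaled"` or `"contrast_scaled"`.
#'
#' @seealso [detectorParams()], [detectSegment()]
#' @exportClass DetectorParams
setClass("DetectorParams",
  representation(intensityThreshold = "numeric", minAreaPx = "integer",
                 maxAreaPx = "integer", confidenceRule = "character"),
  validity = function(object) {
    if (object@intensityThreshold < 0 || object@intensityThreshold > 1)
      return("intensityThreshold must lie in [0, 1]")
    if (!(object@minAreaPx > 0L && object@minAreaPx < object@maxAreaPx))
      return("need 0 < minAreaPx < maxAreaPx")
    if (!object@confidenceRule %in% c("area_scaled", "contrast_scaled"))
      return("confidenceRule must be 'area_scaled' or 'contrast_scaled'")
    TRUE
  })

#' Ranked true/false-positive assignment of detections to ground truth
#'
#' Result of greedy IoU matching of a detection set against ground-truth
#' boxes. `table` holds one row per detection in match order (confidence
#' descending, ties by lower cx then cy) with its best IoU, the index of the
#' consumed ground-truth box (NA for false positives) and the TP flag.
#'
#' @slot table data.frame with columns
#'   `rank, cx, cy, w, h, confidence, iou, gtIndex, tp`.
#' @slot nGroundTruth integer, number of ground-truth boxes.
#' @slot iouThreshold numeric, IoU required for a true positive.
#'
#' @seealso [matchDetections()], [averagePrecision()]
#' @exportClass MatchTable
setClass("MatchTable",
  representation(table = "data.frame", nGroundTruth = "integer",
                 iouThreshold = "numeric"),
  validity = function(object) {
    tp <- sum(object@table$tp)
    if (tp > object@nGroundTruth)
      return("more true positives than ground-truth boxes")
    gi <- object@table$gtIndex[object@table$tp]
    if (anyDuplicated(gi)) return("a ground-truth box was matched twice")
    TRUE
  })

#' Precision-recall curve and VOC2010 average precision
#'
#' Rank-indexed precision/recall values, the monotonically non-increasing
#' interpolated precision envelope, and the average precision (area under
#' the envelope over recall). With a single object class, mAP equals AP.
#'
#' @slot curve data.frame with columns `rank, recall, precision, envelope`.
#' @slot ap numeric in `[0, 1]`.
#' @slot nGroundTruth integer.
#'
#' @seealso [averagePrecision()]
#' @exportClass PRCurve
setClass("PRCurve",
  representation(curve = "data.frame", ap = "numeric",
                 nGroundTruth = "integer"),
  validity = function(object) {
    if (object@ap < -1e-12 || object@ap > 1 + 1e-12)
      return("AP must lie in [0, 1]")
    r <- object@curve$recall
    if (length(r) > 1 && any(diff(r) < -1e-12))
      return("recall must be non-decreasing with rank")
    TRUE
  })

#' Paired-count agreement statistics
#'
#' Bland-Altman analysis of paired per-well counts: differences expressed as
#' a percentage of the pair mean, mean difference (bias), limits of
#' agreement `bias +/- 1.96 SD`, t-based confidence intervals for the bias
#' and each limit, an omnibus skewness-kurtosis normality p-value for the
#' differences, and the companion raw-count RMSE and Pearson correlation.
#'
#' @slot nPairs integer, usable pairs after exclusions.
#' @slot rmse,pearsonR numeric, computed on the raw counts of usable pairs.
#' @slot biasPct,sdPct,loaLowPct,loaHighPct numeric, percent-of-mean scale.
#' @slot ciBias,ciLoaLow,ciLoaHigh numeric length-2 intervals.
#' @slot normalityP numeric p-value.
#' @slot excluded data.frame of excluded pairs with a `reason` column.
#' @slot pairs data.frame of usable pairs with their `meanCount, diffPct`.
#'
#' @seealso [blandAltman()], [pctDiff()], [plotBlandAltman()]
#' @exportClass AgreementStats
setClass("AgreementStats",
  representation(nPairs = "integer", rmse = "numeric", pearsonR = "numeric",
                 biasPct = "numeric", sdPct = "numeric",
                 loaLowPct = "numeric", loaHighPct = "numeric",
                 ciBias = "numeric", ciLoaLow = "numeric",
                 ciLoaHigh = "numeric", normalityP = "numeric",
                 excluded = "data.frame", pairs = "data.frame"),
  validity = function(object) {
    if (object@rmse < 0) return("rmse must be non-negative")
    if (!is.na(object@pearsonR) &&
        (object@pearsonR < -1 - 1e-12 || object@pearsonR > 1 + 1e-12))
      return("pearsonR must lie in [-1, 1]")
    if (abs(object@loaLowPct - (object@biasPct - 1.96 * object@sdPct)) > 1e-8)
      return("loaLowPct must equal bias - 1.96 * SD")
    if (abs(object@loaHighPct - (object@biasPct + 1.96 * object@sdPct)) > 1e-8)
      return("loaHighPct must equal bias + 1.96 * SD")
    TRUE
  })

#' Synthetic well generator configuration
#'
#' Parameters of the seeded synthetic well-image generator. Defaults emulate
#' the imaging conditions the pipeline targets: large light-background
#' brightfield wells carrying dark elliptical multinucleated-cell bodies
#' whose typical width is about 1% of the well width, per-well counts in the
#' 0-1,500 range, small mononuclear clutter specks, and an optional global
#' dimming factor reproducing a dark imaging condition.
#'
#' @slot widthPx,heightPx integer canvas size.
#' @slot nCells integer, number of cells to place.
#' @slot cellWidthMeanPx numeric, mean cell width (major axis), pixels.
#' @slot cellWidthCv numeric, coefficient of variation of cell width.
#' @slot eccRange numeric length-2, ellipse eccentricity range.
#' @slot backgroundLevel numeric in `[0, 1]`, background gray level.
#' @slot darknessFactor numeric in `(0, 1]`, global intensity multiplier.
#' @slot clutterDensity numeric, expected clutter specks per pixel.
#' @slot seed integer, fixes the full output.
#'
#' @seealso [synthConfig()], [generateWell()], [generateExperiment()]
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(widthPx = "integer", heightPx = "integer",
                 nCells = "integer", cellWidthMeanPx = "numeric",
                 cellWidthCv = "numeric", eccRange = "numeric",
                 backgroundLevel = "numeric", darknessFactor = "numeric",
                 clutterDensity = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@widthPx < 32L || object@heightPx < 32L)
      return("canvas must be at least 32 x 32 pixels")
    if (object@nCells < 0L) return("nCells must be non-negative")
    if (object@cellWidthMeanPx <= 2) return("cells must be wider than 2 px")
    if (object@darknessFactor <= 0 || object@darknessFactor > 1)
      return("darknessFactor must lie in (0, 1]")
    if (length(object@eccRange) != 2L ||
        any(object@eccRange < 0) || any(object@eccRange >= 1))
      return("eccRange must be two values in [0, 1)")
    TRUE
  })

#' Synthetic well with ground truth
#'
#' A rendered [WellImage] together with its ground truth: one point mark at
#' each cell centroid and the axis-aligned bounding box of each cell body.
#'
#' @slot image a [WellImage].
#' @slot marks data.frame with columns `x, y` (well frame, pixels).
#' @slot boxes data.frame with columns `cx, cy, w, h` (well frame, pixels).
#' @slot config the generating [SynthConfig].
#'
#' @seealso [generateWell()]
#' @exportClass SynthWell
setClass("SynthWell",
  representation(image = "WellImage", marks = "data.frame",
                 boxes = "data.frame", config = "SynthConfig"),
  validity = function(object) {
    if (nrow(object@marks) != nrow(object@boxes))
      return("one mark per ground-truth box is required")
    TRUE
  })
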