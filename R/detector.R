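#' Grayscale conversion with standard luma weights
#'
#' @param raster numeric array `h x w` or `h x w x 3` in `[0, 1]`.
#' @return Numeric matrix `h x w`. RGB is collapsed with the Rec.601 luma
#'   weights (0.299, 0.587, 0.114); grayscale input is returned as is.
#' @export
toGrayscale <- function(raster) {
  d <- dim(raster)
  if (length(d) == 2L) return(raster)
  if (length(d) == 3L && d[3] == 1L) return(array(raster[, , 1L], d[1:2]))
  if (length(d) == 3L && d[3] == 3L)
    return(0.299 * raster[, , 1L] + 0.587 * raster[, , 2L] +
           0.114 * raster[, , 3L])
  stop("raster must be h x w or h x w x 3")
}

# 8-connected component labeling of a logical matrix. EBImage::bwlabel is
# 4-connected, so labels touching only diagonally are merged afterwards with
# a union-find pass over the (few) diagonal label adjacencies.
labelComponents <- function(mask) {
  storage.mode(mask) <- "double"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  s1 <- a1 > 0L & b1 > 0L & a1 != b1
  s2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2]))
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  remap <- c(0L, dense)
  matrix(remap[lab + 1L], nr, nc)
}

#' Construct reference-detector parameters
#'
#' @param intensityThreshold global threshold as a fraction of the dynamic
#'   range; pixels with luma strictly below it are foreground (stained cell
#'   bodies are darker than the brightfield background).
#' @param minAreaPx,maxAreaPx inclusive component-area bounds in pixels.
#' @param confidenceRule `"area_scaled"` (default) or `"contrast_scaled"`.
#' @return A [DetectorParams-class].
#' @export
detectorParams <- function(intensityThreshold = 0.6, minAreaPx = 60L,
                           maxAreaPx = 2000L,
                           confidenceRule = "area_scaled") {
  new("DetectorParams", intensityThreshold = intensityThreshold,
      minAreaPx = as.integer(minAreaPx), maxAreaPx = as.integer(maxAreaPx),
      confidenceRule = confidenceRule)
}

#' Detect cell-like objects in one segment raster
#'
#' Deterministic classical reference detector filling the per-segment
#' detection contract: grayscale conversion, global intensity threshold,
#' 8-connected component labeling, an area filter, and one tight bounding
#' box per surviving component. Confidence is `area / maxAreaPx` capped at 1
#' under `"area_scaled"` (monotone in component area), or the component's
#' mean relative darkness below the threshold under `"contrast_scaled"`.
#' The same raster and parameters always produce identical output.
#'
#' Any function with this signature (raster in, data.frame of
#' `cx, cy, w, h, confidence` out) can stand in for the reference detector
#' in [runWell()]; externally produced detections can be imported with
#' [readDetections()].
#'
#' @param raster numeric array (segment pixels in `[0, 1]`).
#' @param params a [DetectorParams-class].
#' @return data.frame with columns `cx, cy, w, h, confidence` in
#'   segment-frame pixels.
#' @export
detectSegment <- function(raster, params = detectorParams()) {
  if (length(raster) == 0) stop("empty raster")
  gray <- toGrayscale(raster)
  lab <- labelComponents(gray < params@intensityThreshold)
  nlab <- max(lab)
  empty <- data.frame(cx = numeric(0), cy = numeric(0), w = numeric(0),
                      h = numeric(0), confidence = numeric(0))
  if (nlab == 0L) return(empty)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  areas <- tabulate(labs, nbins = nlab)
  keep <- which(areas >= params@minAreaPx & areas <= params@maxAreaPx)
  if (!length(keep)) return(empty)
  rows0 <- (idx - 1L) %% nrow(lab)        # 0-based y
  cols0 <- (idx - 1L) %/% nrow(lab)       # 0-based x
  out <- lapply(keep, function(k) {
    sel <- labs == k
    x0 <- min(cols0[sel]); x1 <- max(cols0[sel])
    y0 <- min(rows0[sel]); y1 <- max(rows0[sel])
    conf <- if (params@confidenceRule == "area_scaled") {
      min(1, areas[k] / params@maxAreaPx)
    } else {
      g <- gray[idx[sel]]
      thr <- max(params@intensityThreshold, 1e-9)
      min(1, max(0, mean(thr - g) / thr))
    }
    data.frame(cx = (x0 + x1 + 1) / 2, cy = (y0 + y1 + 1) / 2,
               w = x1 - x0 + 1, h = y1 - y0 + 1, confidence = conf)
  })
  do.call(rbind, out)
}

#' Run a detector over every segment of a well
#'
#' Applies `detector` to each segment raster, drops detections with
#' confidence below `detectionThreshold`, maps the surviving boxes to the
#' well frame via the segment origin, and clips them to the well bounds. The
#' counting mode is recorded from the grid: `"overlap"` when segments
#' overlap (downstream counting should deduplicate with
#' [mergeDetections()]), `"nonoverlap"` otherwise (detections are counted
#' as-is; a cell straddling a segment border can be detected in two
#' segments, an accepted error source of border clipping).
#'
#' @param well a [WellImage-class].
#' @param grid a [SegmentGrid-class].
#' @param detector function(raster) -> data.frame `cx, cy, w, h, confidence`
#'   (segment frame). Defaults to the reference detector with default
#'   parameters.
#' @param detectionThreshold minimum confidence kept, in `[0, 1]`.
#' @return A [WellDetections-class].
#' @export
runWell <- function(well, grid, detector = NULL, detectionThreshold = 0) {
  stopifnot(is(well, "WellImage"), is(grid, "SegmentGrid"))
  if (detectionThreshold < 0 || detectionThreshold > 1)
    stop("detectionThreshold must lie in [0, 1]")
  if (is.null(detector)) detector <- function(r) detectSegment(r)
  recs <- list()
  for (r in seq_len(grid@nRows) - 1L)
    for (co in seq_len(grid@nCols) - 1L) {
      seg <- extractSegment(well, grid, r, co)
      d <- tryCatch(detector(seg), error = function(e)
        stop(sprintf("detector failed on segment (row %d, col %d): %s",
                     r, co, conditionMessage(e))))
      if (!nrow(d)) next
      d <- d[d$confidence >= detectionThreshold, , drop = FALSE]
      if (!nrow(d)) next
      org <- segmentOrigin(grid, r, co)
      d$cx <- d$cx + org[["x"]]; d$cy <- d$cy + org[["y"]]
      d$row <- r; d$col <- co
      recs[[length(recs) + 1L]] <- d
    }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(cx = numeric(0), cy = numeric(0), w = numeric(0),
               h = numeric(0), confidence = numeric(0), row = integer(0),
               col = integer(0))
  if (nrow(records)) {
    # clip to well bounds
    x1 <- pmax(0, records$cx - records$w / 2)
    x2 <- pmin(grid@widthPx, records$cx + records$w / 2)
    y1 <- pmax(0, records$cy - records$h / 2)
    y2 <- pmin(grid@heightPx, records$cy + records$h / 2)
    records$cx <- (x1 + x2) / 2; records$w <- x2 - x1
    records$cy <- (y1 + y2) / 2; records$h <- y2 - y1
    records <- records[records$w > 0 & records$h > 0, , drop = FALSE]
    rownames(records) <- NULL
  }
  new("WellDetections", wellId = well@wellId,
      mode = if (grid@overlapFrac > 0) "overlap" else "nonoverlap",
      widthPx = grid@widthPx, heightPx = grid@heightPx, records = records)
}
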