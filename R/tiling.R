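#' Construct a WellImage
#'
#' @param pixels numeric array in `[0, 1]`, `height x width` or
#'   `height x width x 3`.
#' @param wellId,experimentId identifying strings.
#' @return A [WellImage-class] object.
#' @examples
#' img <- wellImage(matrix(0.8, 64, 96), "w1", "expA")
#' imageWidth(img)
#' @export
wellImage <- function(pixels, wellId = "well", experimentId = "exp") {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = dim(pixels))
  new("WellImage", pixels = pixels, wellId = as.character(wellId),
      experimentId = as.character(experimentId))
}

#' Segment lattice dimensions for a well image
#'
#' Computes the overlapping-tile decomposition of a `width x height` well
#' image into square segments of `segmentSizePx` whose origins advance by
#' `stride = segmentSizePx * (1 - overlapFrac)`. The lattice has
#' `ceiling(width / stride)` columns and `ceiling(height / stride)` rows, so
#' every pixel is covered by at least one segment; edge segments may overrun
#' the image and are padded on extraction. At the defaults (416 px, 50%
#' overlap) a 10,248 x 9,122 well yields 50 x 44 = 2,200 segments.
#'
#' @param widthPx,heightPx well-image dimensions in pixels.
#' @param segmentSizePx segment side length (default 416).
#' @param overlapFrac overlap fraction in `[0, 1)` (default 0.5). The implied
#'   stride must be a whole number of pixels; other values are rejected
#'   rather than silently rounded.
#' @return A [SegmentGrid-class] object.
#' @examples
#' nSegments(gridDims(10248, 9122))            # 2200
#' nSegments(gridDims(10248, 9122, overlapFrac = 0)) # 550
#' @export
gridDims <- function(widthPx, heightPx, segmentSizePx = 416L,
                     overlapFrac = 0.5) {
  if (widthPx < 1 || heightPx < 1 || segmentSizePx < 1)
    stop("image and segment dimensions must be positive")
  if (overlapFrac < 0 || overlapFrac >= 1)
    stop("overlapFrac must lie in [0, 1)")
  stride <- segmentSizePx * (1 - overlapFrac)
  if (abs(stride - round(stride)) > 1e-9)
    stop(sprintf(
      "overlap %.4f gives a non-integer stride (%.3f px) for %d-px segments",
      overlapFrac, stride, as.integer(segmentSizePx)))
  stride <- as.integer(round(stride))
  if (stride < 1L) stop("stride must be at least 1 pixel")
  new("SegmentGrid",
      widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      segmentSizePx = as.integer(segmentSizePx),
      overlapFrac = as.numeric(overlapFrac), stridePx = stride,
      nCols = as.integer(ceiling(widthPx / stride)),
      nRows = as.integer(ceiling(heightPx / stride)))
}

#' Segment origin in the well frame
#'
#' @param grid a [SegmentGrid-class].
#' @param row,col 0-based segment indices (`row` in `[0, nRows)`,
#'   `col` in `[0, nCols)`).
#' @return Named numeric vector `c(x, y)` of the segment's top-left corner.
#' @export
segmentOrigin <- function(grid, row, col) {
  stopifnot(is(grid, "SegmentGrid"))
  if (any(row < 0 | row >= grid@nRows) || any(col < 0 | col >= grid@nCols))
    stop(sprintf("segment (row %s, col %s) outside the %d x %d lattice",
                 toString(row), toString(col), grid@nRows, grid@nCols))
  c(x = as.numeric(col) * grid@stridePx, y = as.numeric(row) * grid@stridePx)
}

#' Extract one padded segment raster
#'
#' Copies the pixels of segment `(row, col)` out of the well image. Windows
#' overrunning the right or bottom edge are filled with `padValue`, so the
#' output is always exactly `segmentSizePx` square (with the well's channel
#' count).
#'
#' @param well a [WellImage-class].
#' @param grid a [SegmentGrid-class] for the same image.
#' @param row,col 0-based segment indices.
#' @param padValue intensity used outside the image (default 0).
#' @return Numeric array `segmentSizePx x segmentSizePx[ x channels]`.
#' @export
extractSegment <- function(well, grid, row, col, padValue = 0) {
  stopifnot(is(well, "WellImage"), is(grid, "SegmentGrid"))
  if (imageWidth(well) != grid@widthPx || imageHeight(well) != grid@heightPx)
    stop("grid was built for different image dimensions")
  org <- segmentOrigin(grid, row, col)
  s <- grid@segmentSizePx
  d <- dim(well@pixels)
  nc <- if (length(d) == 3L) d[3] else 1L
  out <- array(padValue, dim = c(s, s, nc))
  ys <- (org["y"] + 1):min(org["y"] + s, d[1])   # 1-based matrix rows
  xs <- (org["x"] + 1):min(org["x"] + s, d[2])
  src <- if (length(d) == 3L) well@pixels[ys, xs, , drop = FALSE] else
    array(well@pixels[ys, xs], dim = c(length(ys), length(xs), 1L))
  out[seq_along(ys), seq_along(xs), ] <- src
  if (nc == 1L) array(out[, , 1L], dim = c(s, s)) else out
}

#' Map coordinates between segment frame and well frame
#'
#' `toGlobal()` adds the segment origin to segment-frame coordinates;
#' `toLocal()` subtracts it. They are exact inverses.
#'
#' @param grid a [SegmentGrid-class].
#' @param row,col 0-based segment indices.
#' @param x,y coordinates (vectors allowed) in the source frame.
#' @return data.frame with columns `x, y` in the target frame.
#' @export
toGlobal <- function(grid, row, col, x, y) {
  org <- segmentOrigin(grid, row, col)
  data.frame(x = x + org[["x"]], y = y + org[["y"]])
}

#' @rdname toGlobal
#' @export
toLocal <- function(grid, row, col, x, y) {
  org <- segmentOrigin(grid, row, col)
  data.frame(x = x - org[["x"]], y = y - org[["y"]])
}

#' Ground-truth box side from the well width
#'
#' Most osteoclasts fit inside a square whose side is a fixed small fraction
#' of the whole well-image width (about 0.98%); the synthesized box side is
#' that fraction of the width, rounded half away from zero. A 10,248-px well
#' gives 100-px boxes; an 8,320-px well gives 81-px boxes.
#'
#' @param wellWidthPx well-image width in pixels.
#' @param fraction box side as a fraction of the width (default 0.009756).
#' @return Integer box side in pixels.
#' @examples
#' boxSideFromWidth(10248)  # 100
#' boxSideFromWidth(8320)   # 81
#' @export
boxSideFromWidth <- function(wellWidthPx, fraction = 0.009756) {
  if (wellWidthPx < 1 || fraction <= 0)
    stop("wellWidthPx must be >= 1 and fraction positive")
  x <- fraction * wellWidthPx
  side <- as.integer(sign(x) * floor(abs(x) + 0.5))  # half away from zero
  if (side < 1L)
    stop(sprintf("box side rounds to %d px; the box degenerates", side))
  side
}

#' Synthesize per-segment ground-truth boxes from point marks
#'
#' Each point mark generates one square box of side `boxSidePx`, centered on
#' the mark, in every segment whose half-open window
#' `[origin, origin + segmentSize)` contains the mark (with 50% overlap an
#' interior mark falls in up to 4 segments). Boxes are clipped to the segment
#' window; because the mark itself lies inside the window, clipped boxes
#' always retain positive area, and partial boxes are kept.
#'
#' @param marks data.frame with columns `x, y` (well frame, pixels).
#' @param grid a [SegmentGrid-class].
#' @param boxSidePx box side in pixels (see [boxSideFromWidth()]).
#' @return data.frame with one row per (mark, segment) pair: `row, col`
#'   (segment indices), `cx, cy, w, h` (segment frame, clipped), `mark`
#'   (index into `marks`).
#' @export
assignLabels <- function(marks, grid, boxSidePx) {
  stopifnot(is(grid, "SegmentGrid"), all(c("x", "y") %in% names(marks)))
  bad <- which(marks$x < 0 | marks$x >= grid@widthPx |
               marks$y < 0 | marks$y >= grid@heightPx)
  if (length(bad))
    stop("marks outside the well image: rows ", toString(bad))
  stride <- grid@stridePx; s <- grid@segmentSizePx; half <- boxSidePx / 2
  out <- vector("list", nrow(marks))
  for (i in seq_len(nrow(marks))) {
    x <- marks$x[i]; y <- marks$y[i]
    cols <- max(0L, as.integer(floor((x - s) / stride)) + 1L):
      min(grid@nCols - 1L, as.integer(floor(x / stride)))
    rows <- max(0L, as.integer(floor((y - s) / stride)) + 1L):
      min(grid@nRows - 1L, as.integer(floor(y / stride)))
    grid2 <- expand.grid(col = cols, row = rows)
    lx <- x - grid2$col * stride; ly <- y - grid2$row * stride
    x1 <- pmax(0, lx - half); x2 <- pmin(s, lx + half)
    y1 <- pmax(0, ly - half); y2 <- pmin(s, ly + half)
    out[[i]] <- data.frame(row = grid2$row, col = grid2$col,
                           cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                           w = x2 - x1, h = y2 - y1, mark = i)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(row = integer(), col = integer(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric(),
                      mark = integer())
  res
}

#' Epoch/iteration bookkeeping for minibatch training
#'
#' Converts between epochs (full passes over the training segments) and
#' optimizer iterations at a given batch size:
#' `iterations = ceiling(epochs * nSamples / batchSize)`. Two epochs over a
#' 354,320-segment training set at batch 64 is 11,073 iterations.
#'
#' @param nSamples number of training samples (segments).
#' @param epochs number of full passes.
#' @param batchSize minibatch size (default 64).
#' @return Integer iteration count.
#' @examples
#' trainingIterations(354320, 2)  # 11073
#' @export
trainingIterations <- function(nSamples, epochs, batchSize = 64L) {
  if (nSamples < 1 || epochs <= 0 || batchSize < 1)
    stop("nSamples, epochs and batchSize must be positive")
  as.integer(ceiling(epochs * nSamples / batchSize))
}

#' @rdname trainingIterations
#' @param iterations optimizer iteration count.
#' @return `iterationsToEpochs()`: fractional epochs.
#' @export
iterationsToEpochs <- function(iterations, nSamples, batchSize = 64L) {
  if (iterations < 1 || nSamples < 1 || batchSize < 1)
    stop("iterations, nSamples and batchSize must be positive")
  iterations * batchSize / nSamples
}
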