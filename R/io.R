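#' Read a well image from a TIF or PNG file
#'
#' Reads the raster, drops any alpha channel, and returns a [WellImage-class]
#' with intensities in `[0, 1]`.
#'
#' @param path image file (.tif/.tiff/.png).
#' @param wellId,experimentId identifiers; default `wellId` is the file stem.
#' @return A [WellImage-class].
#' @export
readWellImage <- function(path, wellId = NULL, experimentId = "exp") {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use TIF or PNG)"))
  if (length(dim(px)) == 3L && dim(px)[3] == 4L)
    px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (length(dim(px)) == 3L && dim(px)[3] == 2L)
    px <- px[, , 1L]                 # gray + alpha
  if (is.null(wellId)) wellId <- tools::file_path_sans_ext(basename(path))
  wellImage(px, wellId = wellId, experimentId = experimentId)
}

#' Write a well image (or segment raster) to PNG
#'
#' @param pixels a [WellImage-class] or a numeric array in `[0, 1]`.
#' @param path output .png path.
#' @return `path`, invisibly.
#' @export
writeWellImage <- function(pixels, path) {
  if (is(pixels, "WellImage")) pixels <- pixels@pixels
  png::writePNG(pixels, target = path)
  invisible(path)
}

#' Write all segments of a well as PNG files
#'
#' Files are named `{wellId}_r{row}_c{col}.png` with 0-based indices.
#'
#' @param well a [WellImage-class].
#' @param grid a [SegmentGrid-class].
#' @param dir output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
writeSegments <- function(well, grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (r in seq_len(grid@nRows) - 1L)
    for (co in seq_len(grid@nCols) - 1L) {
      p <- file.path(dir, sprintf("%s_r%d_c%d.png", well@wellId, r, co))
      png::writePNG(extractSegment(well, grid, r, co), target = p)
      paths <- c(paths, p)
    }
  invisible(paths)
}

#' Read Fiji multi-point marks from CSV
#'
#' Reads human click annotations exported from Fiji's multi-point tool as a
#' CSV of pixel coordinates. Dialect: comma-separated; an optional header row
#' is detected (any non-numeric first row); columns named `x`/`y` (any case)
#' are used when present, otherwise the first two columns; extra columns are
#' ignored. An empty file yields zero marks, since a well may genuinely
#' contain no osteoclasts.
#'
#' @param path CSV file of marks.
#' @return data.frame with numeric columns `x, y` (well frame, pixels).
#' @export
readFijiMarks <- function(path) {
  if (!file.exists(path)) stop("no such marks file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(x = numeric(0), y = numeric(0))
  if (!length(lines)) return(empty)
  first <- strsplit(lines[1], ",")[[1]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(first))))
  tab <- utils::read.csv(text = paste(lines, collapse = "\n"),
                         header = hasHeader,
                         stringsAsFactors = FALSE, strip.white = TRUE)
  if (!nrow(tab)) return(empty)
  nm <- tolower(names(tab))
  xi <- match("x", nm); yi <- match("y", nm)
  if (is.na(xi) || is.na(yi)) { xi <- 1L; yi <- 2L }
  if (ncol(tab) < max(xi, yi)) stop("marks file needs two coordinate columns")
  x <- suppressWarnings(as.numeric(tab[[xi]]))
  y <- suppressWarnings(as.numeric(tab[[yi]]))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop("non-numeric coordinates in ", path, " at data line(s) ",
         toString(bad + hasHeader))
  data.frame(x = x, y = y)
}

#' @rdname readFijiMarks
#' @param marks data.frame with columns `x, y`.
#' @export
writeFijiMarks <- function(marks, path) {
  utils::write.csv(marks[, c("x", "y")], path, row.names = FALSE)
  invisible(path)
}

darknetNormalize <- function(boxes, segmentSizePx) {
  n <- data.frame(cx = boxes$cx / segmentSizePx, cy = boxes$cy / segmentSizePx,
                  w = boxes$w / segmentSizePx, h = boxes$h / segmentSizePx)
  lim <- cbind(n$cx - n$w / 2, n$cx + n$w / 2, n$cy - n$h / 2, n$cy + n$h / 2)
  bad <- which(lim[, 1] < -1e-9 | lim[, 2] > 1 + 1e-9 |
               lim[, 3] < -1e-9 | lim[, 4] > 1 + 1e-9)
  if (length(bad))
    stop("box(es) ", toString(bad), " fall outside the unit segment after ",
         "normalization; clip them to the segment first")
  n
}

#' Write and read Darknet-format label files
#'
#' One text file per segment, named `{wellId}_r{row}_c{col}.txt`. Each line
#' is `0 cx cy w h` — single class id 0 followed by the box center and size
#' normalized by the segment side, printed with 6 decimals (the Darknet
#' ecosystem convention). Segments with no boxes get an empty file so the
#' image/label pairing stays complete.
#'
#' @param labels data.frame as returned by [assignLabels()]
#'   (`row, col, cx, cy, w, h` in segment frame, already clipped).
#' @param grid a [SegmentGrid-class] (defines which files to create).
#' @param dir output directory.
#' @param wellId well identifier used in file names.
#' @return Character vector of written paths, invisibly.
#' @export
writeDarknetLabels <- function(labels, grid, dir, wellId = "well") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- grid@segmentSizePx
  paths <- character(0)
  for (r in seq_len(grid@nRows) - 1L)
    for (co in seq_len(grid@nCols) - 1L) {
      p <- file.path(dir, sprintf("%s_r%d_c%d.txt", wellId, r, co))
      sel <- labels[labels$row == r & labels$col == co, , drop = FALSE]
      if (nrow(sel)) {
        n <- darknetNormalize(sel, s)
        writeLines(sprintf("0 %.6f %.6f %.6f %.6f", n$cx, n$cy, n$w, n$h), p)
      } else writeLines(character(0), p)
      paths <- c(paths, p)
    }
  invisible(paths)
}

#' @rdname writeDarknetLabels
#' @param path one label .txt file.
#' @param segmentSizePx segment side used to denormalize.
#' @return `readDarknetLabels()`: data.frame `classId, cx, cy, w, h` in
#'   segment-frame pixels.
#' @export
readDarknetLabels <- function(path, segmentSizePx = 416L) {
  if (!file.exists(path)) stop("no such label file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(classId = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) != 5L))
    stop("malformed Darknet label line in ", path)
  m <- matrix(as.numeric(unlist(parts)), ncol = 5L, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric Darknet label value in ", path)
  if (any(m[, 2:5] < -1e-9 | m[, 2:5] > 1 + 1e-9))
    stop("normalized values outside [0, 1] in ", path)
  data.frame(classId = as.integer(m[, 1]), cx = m[, 2] * segmentSizePx,
             cy = m[, 3] * segmentSizePx, w = m[, 4] * segmentSizePx,
             h = m[, 5] * segmentSizePx)
}

#' Read PASCAL VOC XML bounding boxes
#'
#' Reads LabelImg-style VOC XML annotations. Corner convention: `xmin`/`ymin`
#' and `xmax`/`ymax` are 1-based pixel indices where the box spans
#' `[xmin - 1, xmax - 1)` in the package's 0-based half-open frame, so the
#' box width is `xmax - xmin` (the convention LabelImg/Darknet converters
#' use); `(1, 1, 101, 101)` is a 100-px square centered at `(50, 50)`.
#'
#' @param path VOC XML annotation file.
#' @return data.frame with columns `name, cx, cy, w, h` (0-based pixels).
#' @export
readVocXml <- function(path) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  doc <- xml2::read_xml(path)
  objs <- xml2::xml_find_all(doc, ".//object")
  num <- function(o, tag)
    as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0(".//", tag))))
  rows <- lapply(objs, function(o) {
    xmin <- num(o, "xmin"); xmax <- num(o, "xmax")
    ymin <- num(o, "ymin"); ymax <- num(o, "ymax")
    if (anyNA(c(xmin, xmax, ymin, ymax)))
      stop("missing bndbox coordinate in ", path)
    if (xmax <= xmin || ymax <= ymin)
      stop(sprintf("degenerate box (%g,%g,%g,%g) in %s",
                   xmin, ymin, xmax, ymax, path))
    data.frame(
      name = xml2::xml_text(xml2::xml_find_first(o, ".//name")),
      cx = (xmin + xmax) / 2 - 1, cy = (ymin + ymax) / 2 - 1,
      w = xmax - xmin, h = ymax - ymin)
  })
  if (!length(rows))
    return(data.frame(name = character(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  do.call(rbind, rows)
}

#' Read and write detection records as JSON lines
#'
#' Lossless import/export path for detections produced outside the package
#' (for example by an external Darknet run). One JSON object per line with
#' fields `frame` (`"well"` or `"segment"`), `row`, `col` (segment indices,
#' `NA` in the well frame), `cx, cy, w, h` (pixels) and `confidence`.
#'
#' @param path JSON-lines file.
#' @return `readDetections()`: data.frame of records.
#' @export
readDetections <- function(path) {
  if (!file.exists(path)) stop("no such detections file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(frame = character(0), row = integer(0),
                      col = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0), confidence = numeric(0))
  if (!length(lines)) return(empty)
  recs <- lapply(seq_along(lines), function(i) {
    r <- jsonlite::fromJSON(lines[i])
    need <- c("frame", "cx", "cy", "w", "h", "confidence")
    if (!all(need %in% names(r)))
      stop("detection record on line ", i, " is missing fields")
    data.frame(frame = r$frame,
               row = if (is.null(r$row) || is.na(r$row)) NA_integer_
                     else as.integer(r$row),
               col = if (is.null(r$col) || is.na(r$col)) NA_integer_
                     else as.integer(r$col),
               cx = r$cx, cy = r$cy, w = r$w, h = r$h,
               confidence = r$confidence)
  })
  out <- do.call(rbind, recs)
  if (any(out$confidence < 0 | out$confidence > 1))
    stop("confidence values must lie in [0, 1]")
  if (any(out$w <= 0 | out$h <= 0))
    stop("detection boxes must have positive width and height")
  out
}

#' @rdname readDetections
#' @param records data.frame with columns
#'   `frame, row, col, cx, cy, w, h, confidence` (`row`/`col` optional).
#' @export
writeDetections <- function(records, path) {
  if (any(records$confidence < 0 | records$confidence > 1))
    stop("confidence values must lie in [0, 1]")
  if (!"frame" %in% names(records)) records$frame <- "well"
  if (!"row" %in% names(records)) records$row <- NA_integer_
  if (!"col" %in% names(records)) records$col <- NA_integer_
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(list(
      frame = records$frame[i], row = records$row[i], col = records$col[i],
      cx = records$cx[i], cy = records$cy[i], w = records$w[i],
      h = records$h[i], confidence = records$confidence[i]),
      auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic detection ordering
#'
#' Orders detections by confidence (descending) with ties broken by lower
#' `cx` then lower `cy`, the ordering used for greedy matching and AP
#' ranking.
#'
#' @param records data.frame with `cx, cy, confidence`.
#' @return The reordered data.frame.
#' @export
orderDetections <- function(records) {
  records[order(-records$confidence, records$cx, records$cy), , drop = FALSE]
}
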