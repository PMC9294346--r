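#' Shrink a box about its center
#'
#' Reduces width and height by `factor` (20% by default) while keeping the
#' center fixed; the first step of the overlap-mode deduplication.
#'
#' @param boxes data.frame with `cx, cy, w, h`.
#' @param factor shrink fraction in `[0, 1)`.
#' @return The data.frame with scaled `w, h`.
#' @examples
#' shrinkBox(data.frame(cx = 50, cy = 50, w = 100, h = 100))  # w = h = 80
#' @export
shrinkBox <- function(boxes, factor = 0.2) {
  if (factor < 0 || factor >= 1) stop("factor must lie in [0, 1)")
  boxes$w <- boxes$w * (1 - factor)
  boxes$h <- boxes$h * (1 - factor)
  boxes
}

# Linear (column-major) indices into a heightPx x widthPx canvas covered by
# the ellipse inscribed in one box. Pixel-center inclusion rule; degenerate
# axes (< 0.5 px) floor to 0.5 px; boxes clipped at the canvas edges.
# Returns integer(0) for a box fully outside the canvas.
ellipsePixelIndices <- function(cx, cy, w, h, widthPx, heightPx) {
  a <- max(w / 2, 0.5); b <- max(h / 2, 0.5)
  x0 <- floor(cx - a); x1 <- ceiling(cx + a)
  y0 <- floor(cy - b); y1 <- ceiling(cy + b)
  if (x1 <= 0 || x0 >= widthPx || y1 <= 0 || y0 >= heightPx)
    return(integer(0))
  xs <- max(0, x0):min(widthPx - 1, x1)   # 0-based pixel columns
  ys <- max(0, y0):min(heightPx - 1, y1)
  inside <- outer(((ys + 0.5 - cy) / b)^2, ((xs + 0.5 - cx) / a)^2, `+`) <= 1
  if (!any(inside)) {
    # sub-pixel footprint: the single nearest in-canvas pixel
    px <- min(max(floor(cx), 0), widthPx - 1)
    py <- min(max(floor(cy), 0), heightPx - 1)
    return(as.integer(px * heightPx + py + 1))
  }
  ij <- which(inside, arr.ind = TRUE)
  as.integer(xs[ij[, 2]] * heightPx + ys[ij[, 1]] + 1L)
}

#' Rasterize inscribed ellipses of boxes onto a binary canvas
#'
#' Fills, for every box, the ellipse inscribed in it: pixel `(x, y)` (0-based)
#' is set iff its center satisfies
#' `((x + 0.5 - cx)/a)^2 + ((y + 0.5 - cy)/b)^2 <= 1` with semi-axes
#' `a = w/2`, `b = h/2`. Degenerate axes below 0.5 px fill the single
#' nearest pixel so every in-canvas box leaves a footprint. Boxes partly
#' outside the canvas are clipped; boxes fully outside are skipped with a
#' warning.
#'
#' @param boxes data.frame with `cx, cy, w, h` (well frame; pass the output
#'   of [shrinkBox()] for the deduplication pipeline).
#' @param widthPx,heightPx canvas dimensions.
#' @return Logical matrix `heightPx x widthPx`.
#' @export
rasterizeEllipses <- function(boxes, widthPx, heightPx) {
  mask <- matrix(FALSE, heightPx, widthPx)
  for (i in seq_len(nrow(boxes))) {
    idx <- ellipsePixelIndices(boxes$cx[i], boxes$cy[i], boxes$w[i],
                               boxes$h[i], widthPx, heightPx)
    if (!length(idx)) {
      warning(sprintf("box %d lies fully outside the %d x %d canvas; skipped",
                      i, widthPx, heightPx))
      next
    }
    mask[idx] <- TRUE
  }
  mask
}

#' Fuse overlapping-tile detections of the same cell
#'
#' Deduplication used in overlap mode: every detected box is shrunk by
#' `shrinkFactor` in width and height, its inscribed ellipse is rasterized
#' onto a well-sized binary canvas, connected ellipse regions
#' (8-connectivity) are fused, and one output region with its tight bounding
#' box is emitted per fused component — reducing multiple detections of one
#' compact cell to a single count. Output boxes are the tight boxes of the
#' merged ellipse regions (they are used for counting, not display, and are
#' not re-inflated).
#'
#' @param records data.frame of detections with `cx, cy, w, h` (well frame),
#'   or a [WellDetections-class].
#' @param widthPx,heightPx canvas dimensions (taken from the object when a
#'   [WellDetections-class] is given).
#' @param shrinkFactor box shrink fraction before rasterization (default
#'   0.2).
#' @return data.frame with one row per merged region: `region` (id),
#'   `pixelCount`, `cx, cy, w, h` (tight box), and a list column `members`
#'   of contributing input row indices. At most `nrow(records)` rows.
#' @export
mergeDetections <- function(records, widthPx = NULL, heightPx = NULL,
                            shrinkFactor = 0.2) {
  if (is(records, "WellDetections")) {
    if (is.null(widthPx)) widthPx <- records@widthPx
    if (is.null(heightPx)) heightPx <- records@heightPx
    records <- records@records
  }
  if (is.null(widthPx) || is.null(heightPx))
    stop("canvas dimensions are required for plain data.frame input")
  empty <- data.frame(region = integer(0), pixelCount = integer(0),
                      cx = numeric(0), cy = numeric(0), w = numeric(0),
                      h = numeric(0))
  empty$members <- list()
  if (!nrow(records)) return(empty)
  shrunk <- shrinkBox(records, shrinkFactor)
  footprints <- lapply(seq_len(nrow(shrunk)), function(i)
    ellipsePixelIndices(shrunk$cx[i], shrunk$cy[i], shrunk$w[i],
                        shrunk$h[i], widthPx, heightPx))
  if (any(!lengths(footprints)))
    warning("detection box(es) ", toString(which(!lengths(footprints))),
            " lie fully outside the canvas; skipped")
  mask <- matrix(FALSE, heightPx, widthPx)
  mask[unlist(footprints)] <- TRUE
  lab <- labelComponents(mask)
  nlab <- max(lab)
  if (nlab == 0L) return(empty)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows0 <- (idx - 1L) %% heightPx
  cols0 <- (idx - 1L) %/% heightPx
  regions <- lapply(seq_len(nlab), function(k) {
    sel <- labs == k
    x0 <- min(cols0[sel]); x1 <- max(cols0[sel])
    y0 <- min(rows0[sel]); y1 <- max(rows0[sel])
    data.frame(region = k, pixelCount = sum(sel),
               cx = (x0 + x1 + 1) / 2, cy = (y0 + y1 + 1) / 2,
               w = x1 - x0 + 1, h = y1 - y0 + 1)
  })
  out <- do.call(rbind, regions)
  members <- rep(list(integer(0)), nlab)
  for (i in seq_along(footprints)) {
    hit <- unique(lab[footprints[[i]]])
    for (k in hit[hit > 0L]) members[[k]] <- c(members[[k]], i)
  }
  out$members <- members
  out
}
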