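#' Construct a synthetic-well configuration
#'
#' Defaults render a light brightfield background (level 0.85) carrying dark
#' elliptical stained-cell bodies with bright nucleus dots. The mean cell
#' width defaults to 1% of the well width — the scale the fixed-fraction
#' ground-truth boxes assume — with 15% width CV and moderate
#' eccentricities. `darknessFactor < 1` dims the whole rendered image,
#' emulating a dark imaging condition; `clutterDensity` adds small dark
#' mononuclear-cell-like specks well below the osteoclast area range. The
#' default 2,080 x 1,664 canvas is 10 x 8 strides at the standard 416-px
#' half-overlapping segmentation, so full pipelines run in seconds;
#' full-scale wells are supported by the same code.
#'
#' @param widthPx,heightPx canvas size in pixels.
#' @param nCells number of cells to place (well counts of 0-1,500 are the
#'   realistic range).
#' @param cellWidthMeanPx mean cell width; default `0.01 * widthPx`.
#' @param cellWidthCv coefficient of variation of cell widths.
#' @param eccRange eccentricity range of the elliptical bodies.
#' @param backgroundLevel background gray level in `[0, 1]`.
#' @param darknessFactor global multiplier in `(0, 1]`.
#' @param clutterDensity expected clutter specks per pixel.
#' @param seed integer seed fixing the full output.
#' @return A [SynthConfig-class].
#' @export
synthConfig <- function(widthPx = 2080L, heightPx = 1664L, nCells = 100L,
                        cellWidthMeanPx = NULL, cellWidthCv = 0.15,
                        eccRange = c(0, 0.6), backgroundLevel = 0.85,
                        darknessFactor = 1, clutterDensity = 2e-5,
                        seed = 1L) {
  if (is.null(cellWidthMeanPx)) cellWidthMeanPx <- 0.01 * widthPx
  new("SynthConfig", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx), nCells = as.integer(nCells),
      cellWidthMeanPx = as.numeric(cellWidthMeanPx),
      cellWidthCv = as.numeric(cellWidthCv), eccRange = as.numeric(eccRange),
      backgroundLevel = as.numeric(backgroundLevel),
      darknessFactor = as.numeric(darknessFactor),
      clutterDensity = as.numeric(clutterDensity), seed = as.integer(seed))
}

# linear indices (into an H x W matrix) of the TRUE entries of `inside`,
# a window at 0-based pixel columns xs / rows ys
windowIndices <- function(xs, ys, inside, heightPx) {
  ij <- which(inside, arr.ind = TRUE)
  as.integer(xs[ij[, 2]] * heightPx + ys[ij[, 1]] + 1L)
}

#' Generate one synthetic well with ground truth
#'
#' Renders `nCells` rotated elliptical cell bodies (dark, stain-like, each
#' with 3+ bright nucleus dots) over a noisy light background, plus small
#' dark clutter specks. Cell centroids are rejection-sampled to be at least
#' `0.6 * cellWidthMeanPx` apart, so nearby cells can touch but rarely
#' coincide. Ground truth records the centroid mark and the axis-aligned
#' bounding box of every cell body. Output is bit-identical for equal
#' configurations (the RNG state is saved and restored around the call).
#'
#' @param config a [SynthConfig-class].
#' @param wellId,experimentId identifiers for the rendered [WellImage-class].
#' @return A [SynthWell-class].
#' @export
generateWell <- function(config, wellId = "synth1", experimentId = "synth") {
  stopifnot(is(config, "SynthConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)
  W <- config@widthPx; H <- config@heightPx
  n <- config@nCells
  cw <- config@cellWidthMeanPx
  # textured background with a faint vignette-like shading
  bg <- config@backgroundLevel +
    matrix(stats::rnorm(W * H, 0, 0.012), H, W) +
    0.01 * outer(sin(seq(0, pi, length.out = H) + stats::runif(1, 0, pi)),
                 cos(seq(0, pi, length.out = W) + stats::runif(1, 0, pi)))
  # per-channel matrices so painting happens in place; assembled at the end
  chR <- bg; chG <- bg * 0.975; chB <- bg * 0.955
  paint <- function(idx, color) {
    chR[idx] <<- color[1]; chG[idx] <<- color[2]; chB[idx] <<- color[3]
  }
  # centroid placement with minimum spacing
  margin <- cw
  if (n > 0 && (W - 2 * margin < 1 || H - 2 * margin < 1))
    stop("canvas too small for the configured cell width")
  minDist <- 0.6 * cw
  cxs <- numeric(0); cys <- numeric(0)
  tries <- 0L; maxTries <- max(1000L, 300L * n)
  while (length(cxs) < n) {
    if (tries >= maxTries)
      stop(sprintf(paste0("could not place %d cells at width %.0f px in a %d",
                          " x %d canvas; lower nCells or the cell width"),
                   n, cw, W, H))
    tries <- tries + 1L
    x <- stats::runif(1, margin, W - margin)
    y <- stats::runif(1, margin, H - margin)
    if (!length(cxs) || min((cxs - x)^2 + (cys - y)^2) >= minDist^2) {
      cxs <- c(cxs, x); cys <- c(cys, y)
    }
  }
  boxes <- data.frame(cx = numeric(0), cy = numeric(0), w = numeric(0),
                      h = numeric(0))
  for (i in seq_len(n)) {
    width <- stats::rnorm(1, cw, config@cellWidthCv * cw)
    width <- min(max(width, 0.5 * cw), 1.8 * cw)
    a <- width / 2
    ecc <- stats::runif(1, config@eccRange[1], config@eccRange[2])
    b <- a * sqrt(1 - ecc^2)
    theta <- stats::runif(1, 0, pi)
    ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
    ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
    xs <- max(0, floor(cxs[i] - ex - 1)):min(W - 1, ceiling(cxs[i] + ex + 1))
    ys <- max(0, floor(cys[i] - ey - 1)):min(H - 1, ceiling(cys[i] + ey + 1))
    dx <- xs + 0.5 - cxs[i]; dy <- ys + 0.5 - cys[i]
    U <- outer(dy * sin(theta), dx * cos(theta), `+`)
    V <- outer(dy * cos(theta), -dx * sin(theta), `+`)
    inside <- (U / a)^2 + (V / b)^2 <= 1
    body <- c(0.52, 0.36, 0.50) + stats::rnorm(3, 0, 0.02)
    paint(windowIndices(xs, ys, inside, H), body)
    # bright nucleus dots (>= 3, Hoechst-like), kept inside the body
    for (k in seq_len(3L + stats::rpois(1, 2))) {
      ang <- stats::runif(1, 0, 2 * pi); rad <- sqrt(stats::runif(1)) * 0.6
      nu <- rad * a * cos(ang); nv <- rad * b * sin(ang)
      nx <- cxs[i] + nu * cos(theta) - nv * sin(theta)
      ny <- cys[i] + nu * sin(theta) + nv * cos(theta)
      nr <- max(1, a / 6)
      nxs <- max(0, floor(nx - nr)):min(W - 1, ceiling(nx + nr))
      nys <- max(0, floor(ny - nr)):min(H - 1, ceiling(ny + nr))
      nin <- outer((nys + 0.5 - ny)^2, (nxs + 0.5 - nx)^2, `+`) <= nr^2
      paint(windowIndices(nxs, nys, nin, H),
            c(0.70, 0.69, 0.80) + stats::rnorm(3, 0, 0.015))
    }
    boxes <- rbind(boxes, data.frame(cx = cxs[i], cy = cys[i],
                                     w = 2 * ex, h = 2 * ey))
  }
  # mononuclear clutter specks, well below the osteoclast area range
  nClutter <- stats::rpois(1, config@clutterDensity * W * H)
  for (j in seq_len(nClutter)) {
    x <- stats::runif(1, 0, W); y <- stats::runif(1, 0, H)
    r <- stats::runif(1, 0.8, 2.2)
    xs <- max(0, floor(x - r)):min(W - 1, ceiling(x + r))
    ys <- max(0, floor(y - r)):min(H - 1, ceiling(y + r))
    cin <- outer((ys + 0.5 - y)^2, (xs + 0.5 - x)^2, `+`) <= r^2
    paint(windowIndices(xs, ys, cin, H), c(0.50, 0.42, 0.48))
  }
  img <- array(c(chR, chG, chB), dim = c(H, W, 3))
  img <- pmin(pmax(img * config@darknessFactor, 0), 1)
  new("SynthWell",
      image = wellImage(img, wellId = wellId, experimentId = experimentId),
      marks = data.frame(x = cxs, y = cys), boxes = boxes, config = config)
}

#' Generate a multi-well synthetic experiment
#'
#' Draws a per-well cell count uniformly from `countRange`, renders each
#' well with a seed derived from `seed`, and (optionally) writes the full
#' annotation bundle per well: a PNG image, a Fiji-style marks CSV, and
#' Darknet label files synthesized through the standard tiling path
#' ([gridDims()], [assignLabels()], [writeDarknetLabels()]).
#'
#' @param nWells number of wells.
#' @param config template [SynthConfig-class]; `nCells` and `seed` are
#'   overridden per well.
#' @param countRange integer range the per-well counts are sampled from.
#' @param outDir optional output directory.
#' @param seed experiment-level seed (default: the template's).
#' @param experimentId experiment label.
#' @param segmentSizePx,overlapFrac tiling used for written label files.
#' @return List with `wells` (list of [SynthWell-class]) and `counts`
#'   (data.frame `wellId, experimentId, count`).
#' @export
generateExperiment <- function(nWells, config = synthConfig(),
                               countRange = c(50L, 400L), outDir = NULL,
                               seed = NULL, experimentId = "synthExp",
                               segmentSizePx = 416L, overlapFrac = 0.5) {
  stopifnot(nWells >= 1)
  if (is.null(seed)) seed <- config@seed
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  counts <- sample(countRange[1]:countRange[2], nWells, replace = TRUE)
  wellSeeds <- (seed %% 10000019L) * 100L + seq_len(nWells)
  wells <- vector("list", nWells)
  for (i in seq_len(nWells)) {
    cfg <- config
    cfg@nCells <- counts[i]
    cfg@seed <- wellSeeds[i]
    wells[[i]] <- generateWell(cfg, wellId = sprintf("synth%02d", i),
                               experimentId = experimentId)
  }
  tab <- data.frame(wellId = vapply(wells, wellId, character(1)),
                    experimentId = experimentId, count = counts)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (wl in wells) {
      id <- wellId(wl)
      writeWellImage(wl@image, file.path(outDir, paste0(id, ".png")))
      writeFijiMarks(wl@marks, file.path(outDir, paste0(id, "_marks.csv")))
      grid <- gridDims(imageWidth(wl@image), imageHeight(wl@image),
                       segmentSizePx, overlapFrac)
      side <- boxSideFromWidth(imageWidth(wl@image))
      labels <- assignLabels(wl@marks, grid, side)
      writeDarknetLabels(labels, grid, file.path(outDir, paste0(id, "_labels")),
                         wellId = id)
    }
    utils::write.csv(tab, file.path(outDir, "counts.csv"), row.names = FALSE)
  }
  list(wells = wells, counts = tab)
}
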