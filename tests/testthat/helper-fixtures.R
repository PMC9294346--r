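# shared fixtures: all synthetic, built in code at test time

# small flat grayscale well with a few dark square blobs at known centers
blockWell <- function(width = 200, height = 150, centers = NULL, side = 10,
                      bg = 0.9, fg = 0.2) {
  px <- matrix(bg, height, width)
  if (!is.null(centers))
    for (i in seq_len(nrow(centers))) {
      xs <- (centers$x[i] - side / 2):(centers$x[i] + side / 2 - 1)
      ys <- (centers$y[i] - side / 2):(centers$y[i] + side / 2 - 1)
      px[ys + 1, xs + 1] <- fg
    }
  wellImage(px, wellId = "block", experimentId = "fix")
}

# random center-format boxes inside a canvas
randomBoxes <- function(n, width = 100, height = 100, wmin = 5, wmax = 20) {
  w <- runif(n, wmin, wmax); h <- runif(n, wmin, wmax)
  data.frame(cx = runif(n, w / 2, width - w / 2),
             cy = runif(n, h / 2, height - h / 2), w = w, h = h)
}

# independent AP oracle: exact per-TP form. Each true positive adds
# (1 / nGT) * envelope precision at its own rank; equals the step-integral
# of the interpolated envelope because every TP raises recall by 1/nGT.
apOracle <- function(tpFlags, nGT) {
  n <- length(tpFlags)
  if (n == 0 || nGT == 0) return(0)
  prec <- cumsum(tpFlags) / seq_len(n)
  env <- rev(cummax(rev(prec)))
  sum(env[tpFlags]) / nGT
}

# coarse numeric-grid integration of the envelope over recall, for a
# second, cruder cross-check of the same quantity
apGridOracle <- function(tpFlags, nGT, grid = 20000) {
  n <- length(tpFlags)
  if (n == 0 || nGT == 0) return(0)
  prec <- cumsum(tpFlags) / seq_len(n)
  rec <- cumsum(tpFlags) / nGT
  env <- rev(cummax(rev(prec)))
  rs <- seq(0, max(rec), length.out = grid)
  # envelope precision at recall r: max precision among ranks with rec >= r
  vals <- vapply(rs, function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(env[ok]) else 0
  }, numeric(1))
  mean(vals) * max(rec)
}

# greedy matcher written independently (index arithmetic, corner boxes)
matchOracle <- function(dets, gts, thr) {
  ord <- order(-dets$confidence, dets$cx, dets$cy)
  dets <- dets[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(dets))
  rectIoU <- function(d, g) {
    ax1 <- d$cx - d$w / 2; ax2 <- d$cx + d$w / 2
    ay1 <- d$cy - d$h / 2; ay2 <- d$cy + d$h / 2
    bx1 <- g$cx - g$w / 2; bx2 <- g$cx + g$w / 2
    by1 <- g$cy - g$h / 2; by2 <- g$cy + g$h / 2
    iw <- max(0, min(ax2, bx2) - max(ax1, bx1))
    ih <- max(0, min(ay2, by2) - max(ay1, by1))
    inter <- iw * ih
    inter / ((ax2 - ax1) * (ay2 - ay1) + (bx2 - bx1) * (by2 - by1) - inter)
  }
  for (i in seq_len(nrow(dets))) {
    best <- -1; bestJ <- NA
    for (j in seq_len(nrow(gts))) {
      if (used[j]) next
      v <- rectIoU(dets[i, ], gts[j, ])
      if (v > best) { best <- v; bestJ <- j }
    }
    if (!is.na(bestJ) && best >= thr) { tp[i] <- TRUE; used[bestJ] <- TRUE }
  }
  tp
}

# duplicate-style merge instance: well-separated cells, each detected 1-4
# times with small jitter — the geometry overlap-mode deduplication targets
dupInstance <- function(k = 15, width = 800, height = 500, boxw = 60) {
  cx <- runif(k, 60, width - 60); cy <- runif(k, 60, height - 60)
  keep <- rep(TRUE, k)
  for (i in seq_len(k)[-1])
    if (min(sqrt((cx[1:(i - 1)] - cx[i])^2 +
                 (cy[1:(i - 1)] - cy[i])^2)) < 1.4 * boxw) keep[i] <- FALSE
  cx <- cx[keep]; cy <- cy[keep]
  recs <- NULL
  for (i in seq_along(cx)) {
    nd <- sample(1:4, 1)
    recs <- rbind(recs, data.frame(
      cx = cx[i] + runif(nd, -6, 6), cy = cy[i] + runif(nd, -6, 6),
      w = boxw * runif(nd, 0.9, 1.1), h = boxw * runif(nd, 0.9, 1.1),
      confidence = runif(nd)))
  }
  list(recs = recs, k = length(cx))
}

# small synthetic config used across tests (fast: 832 x 624 px); cells are
# 16 px so their bodies stay well resolved at this miniature scale
testSynthConfig <- function(nCells = 40L, seed = 7L, ...) {
  synthConfig(widthPx = 832L, heightPx = 624L, nCells = nCells,
              cellWidthMeanPx = 16, seed = seed, ...)
}

# reference detector with area bounds scaled to the 16-px fixture cells
testDetector <- function(widthPx = 832L, cellWidthPx = 16) {
  referenceDetectorFor(
    pipelineConfig(boxFraction = cellWidthPx / widthPx), widthPx)
}
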