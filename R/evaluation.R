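#' Intersection over union of boxes
#'
#' Continuous box geometry on center/size boxes; returns values in `[0, 1]`.
#' `a` may contain several boxes; `b` is recycled row-wise against it when
#' it has one row, otherwise both must have equal rows.
#'
#' @param a,b data.frames with `cx, cy, w, h`.
#' @return Numeric vector of IoU values.
#' @export
boxIoU <- function(a, b) {
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  if (any(a$w <= 0 | a$h <= 0 | b$w <= 0 | b$h <= 0))
    stop("IoU requires positive-area boxes")
  ix <- pmax(0, pmin(a$cx + a$w / 2, b$cx + b$w / 2) -
                pmax(a$cx - a$w / 2, b$cx - b$w / 2))
  iy <- pmax(0, pmin(a$cy + a$h / 2, b$cy + b$h / 2) -
                pmax(a$cy - a$h / 2, b$cy - b$h / 2))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Greedy IoU matching of detections against ground truth
#'
#' Detections are processed in confidence-descending order (ties broken by
#' lower `cx`, then lower `cy`). Each detection is a true positive if its
#' highest-IoU *unmatched* ground-truth box reaches `iouThreshold`; that box
#' is then consumed, so any subsequent detection of the same ground truth is
#' a false positive. The permissive default threshold of 0.1 accommodates
#' click marks that are not centered on the cells and the fixed synthesized
#' box size.
#'
#' @param dets data.frame of detections (`cx, cy, w, h, confidence`).
#' @param gts data.frame of ground-truth boxes (`cx, cy, w, h`), same frame.
#' @param iouThreshold minimum IoU for a true positive (default 0.1).
#' @return A [MatchTable-class].
#' @export
matchDetections <- function(dets, gts, iouThreshold = 0.1) {
  dets <- orderDetections(as.data.frame(dets))
  gts <- as.data.frame(gts)
  n <- nrow(dets)
  tab <- data.frame(rank = seq_len(n), cx = dets$cx, cy = dets$cy,
                    w = dets$w, h = dets$h, confidence = dets$confidence,
                    iou = numeric(n), gtIndex = rep(NA_integer_, n),
                    tp = logical(n))
  matched <- logical(nrow(gts))
  for (i in seq_len(n)) {
    if (!nrow(gts)) break
    ious <- boxIoU(gts, dets[i, c("cx", "cy", "w", "h")])
    ious[matched] <- -1
    best <- which.max(ious)
    if (length(best) && ious[best] >= iouThreshold) {
      tab$tp[i] <- TRUE
      tab$gtIndex[i] <- best
      tab$iou[i] <- ious[best]
      matched[best] <- TRUE
    } else {
      tab$iou[i] <- max(0, if (length(ious)) max(ious) else 0)
    }
  }
  new("MatchTable", table = tab, nGroundTruth = nrow(gts),
      iouThreshold = iouThreshold)
}

#' VOC2010 average precision from a match table
#'
#' Computes precision and recall at every rank of the confidence-ordered
#' match table, forms the monotonically non-increasing interpolated
#' precision envelope `p~(r) = max over recalls >= r of p`, and integrates
#' it across the distinct recall steps: `AP = sum(delta_r * p~)`. With a
#' single object class, mAP equals AP.
#'
#' @param match a [MatchTable-class]; its `nGroundTruth` must be positive
#'   (recall is undefined for zero ground truth).
#' @return A [PRCurve-class].
#' @export
averagePrecision <- function(match) {
  stopifnot(is(match, "MatchTable"))
  nGT <- match@nGroundTruth
  if (nGT < 1L) stop("average precision undefined with zero ground truth")
  tab <- match@table
  n <- nrow(tab)
  if (n == 0L) {
    curve <- data.frame(rank = integer(0), recall = numeric(0),
                        precision = numeric(0), envelope = numeric(0))
    return(new("PRCurve", curve = curve, ap = 0, nGroundTruth = nGT))
  }
  cumTP <- cumsum(tab$tp)
  precision <- cumTP / seq_len(n)
  recall <- cumTP / nGT
  envelope <- rev(cummax(rev(precision)))
  dr <- diff(c(0, recall))
  ap <- sum(dr * envelope)
  curve <- data.frame(rank = seq_len(n), recall = recall,
                      precision = precision, envelope = envelope)
  new("PRCurve", curve = curve, ap = ap, nGroundTruth = nGT)
}

#' Precision/recall/F1 sweep over detection thresholds
#'
#' Filters the detections at every threshold on a regular grid (0 to 1 in
#' steps of `step`, both endpoints included), matches the survivors against
#' the ground truth, and reports precision, recall and
#' `F1 = 2PR / (P + R)` per threshold. Conventions: precision is 0 when no
#' detections survive, and F1 is 0 when `P + R = 0`. The returned
#' `bestThreshold` maximizes F1, with ties resolved toward the lowest
#' threshold; it is the operating point used for counting new wells.
#'
#' @param dets data.frame of detections (`cx, cy, w, h, confidence`).
#' @param gts data.frame of ground-truth boxes.
#' @param iouThreshold IoU for matching (default 0.1).
#' @param step threshold increment (default 0.05).
#' @return List with `sweep` (data.frame
#'   `threshold, precision, recall, f1, nDetections, ties`) and
#'   `bestThreshold`. `ties` flags thresholds at which distinct detections
#'   share a confidence value (their relative order is fixed by the
#'   documented tie-break, but other implementations may rank them
#'   differently).
#' @export
sweepThresholds <- function(dets, gts, iouThreshold = 0.1, step = 0.05) {
  if (step <= 0 || step > 1) stop("step must lie in (0, 1]")
  thresholds <- unique(c(seq(0, 1, by = step), 1))
  rows <- lapply(thresholds, function(th) {
    keep <- dets[dets$confidence >= th, , drop = FALSE]
    nTP <- if (nrow(keep))
      sum(matchDetections(keep, gts, iouThreshold)@table$tp) else 0L
    p <- if (nrow(keep)) nTP / nrow(keep) else 0
    r <- if (nrow(gts)) nTP / nrow(gts) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(threshold = th, precision = p, recall = r, f1 = f1,
               nDetections = nrow(keep),
               ties = anyDuplicated(keep$confidence) > 0)
  })
  sweep <- do.call(rbind, rows)
  list(sweep = sweep, bestThreshold = sweep$threshold[which.max(sweep$f1)])
}
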