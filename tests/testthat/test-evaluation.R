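test_that("IoU matches closed-form cases", {
  a <- data.frame(cx = 50, cy = 50, w = 100, h = 100)
  expect_equal(boxIoU(a, a), 1)
  b <- data.frame(cx = 500, cy = 50, w = 100, h = 100)
  expect_equal(boxIoU(a, b), 0)
  # corner-form (0,0,100,100) vs (50,0,150,100): intersection 50x100
  c1 <- data.frame(cx = 100, cy = 50, w = 100, h = 100)
  expect_equal(boxIoU(a, c1), 1 / 3)
  expect_error(boxIoU(a, data.frame(cx = 1, cy = 1, w = 0, h = 5)),
               "positive")
})

test_that("greedy matching consumes each ground truth once", {
  gt <- data.frame(cx = 50, cy = 50, w = 100, h = 100)
  d1 <- data.frame(cx = 60, cy = 50, w = 100, h = 100, confidence = 0.9)
  m <- matchDetections(d1, gt, 0.1)
  expect_true(m@table$tp)
  # second detection of the same cell is a false positive
  d2 <- rbind(d1, data.frame(cx = 45, cy = 55, w = 100, h = 100,
                             confidence = 0.5))
  m2 <- matchDetections(d2, gt, 0.1)
  expect_identical(m2@table$tp, c(TRUE, FALSE))
  expect_identical(m2@table$confidence, c(0.9, 0.5))
})

test_that("matching agrees with an independent greedy oracle", {
  set.seed(51)
  for (rep in 1:40) {
    nd <- sample(1:6, 1); ng <- sample(1:4, 1)
    dets <- cbind(randomBoxes(nd, 120, 120, 8, 30),
                  data.frame(confidence = round(runif(nd), 2)))
    gts <- randomBoxes(ng, 120, 120, 8, 30)
    thr <- sample(c(0.1, 0.3, 0.5), 1)
    m <- matchDetections(dets, gts, thr)
    expect_identical(m@table$tp, matchOracle(dets, gts, thr))
  }
})

test_that("VOC2010 AP reproduces hand-computed envelope areas", {
  gt2 <- data.frame(cx = c(10, 200), cy = 10, w = 10, h = 10)
  # flags TP, FP, TP with 2 GT: AP = 0.5 * 1 + 0.5 * 2/3 = 5/6
  dets <- data.frame(cx = c(10, 100, 200), cy = 10, w = 10, h = 10,
                     confidence = c(0.9, 0.8, 0.7))
  pr <- averagePrecision(matchDetections(dets, gt2, 0.1))
  expect_equal(averagePrecisionValue(pr), 5 / 6)
  expect_equal(pr@curve$precision, c(1, 1 / 2, 2 / 3))
  expect_equal(pr@curve$recall, c(0.5, 0.5, 1))
  # perfect detector
  prPerfect <- averagePrecision(matchDetections(
    cbind(gt2, data.frame(confidence = 1)), gt2, 0.5))
  expect_equal(averagePrecisionValue(prPerfect), 1)
  # a single miss
  prMiss <- averagePrecision(matchDetections(
    data.frame(cx = 500, cy = 500, w = 10, h = 10, confidence = 1),
    gt2[1, ], 0.1))
  expect_equal(averagePrecisionValue(prMiss), 0)
  # zero ground truth is undefined
  empty <- matchDetections(dets, gt2[0, ], 0.1)
  expect_error(averagePrecision(empty), "zero ground truth")
})

test_that("AP equals independent per-TP and grid oracles on random instances", {
  set.seed(53)
  for (rep in 1:60) {
    nd <- sample(1:10, 1); ng <- sample(1:5, 1)
    dets <- cbind(randomBoxes(nd, 150, 150, 10, 40),
                  data.frame(confidence = runif(nd)))
    gts <- randomBoxes(ng, 150, 150, 10, 40)
    m <- matchDetections(dets, gts, 0.1)
    ap <- averagePrecisionValue(averagePrecision(m))
    expect_equal(ap, apOracle(m@table$tp, ng), tolerance = 1e-12)
    expect_equal(ap, apGridOracle(m@table$tp, ng), tolerance = 0.01)
  }
})

test_that("inserting a false positive never increases AP", {
  set.seed(55)
  for (rep in 1:20) {
    nd <- sample(2:8, 1); ng <- sample(1:4, 1)
    dets <- cbind(randomBoxes(nd, 150, 150, 10, 40),
                  data.frame(confidence = runif(nd)))
    gts <- randomBoxes(ng, 150, 150, 10, 40)
    ap <- averagePrecisionValue(averagePrecision(matchDetections(dets, gts,
                                                                 0.1)))
    # an FP far outside the canvas, inserted at an arbitrary rank
    fp <- data.frame(cx = 5000, cy = 5000, w = 10, h = 10,
                     confidence = runif(1))
    apFp <- averagePrecisionValue(averagePrecision(matchDetections(
      rbind(dets, fp), gts, 0.1)))
    expect_lte(apFp, ap + 1e-12)
  }
})

test_that("stricter IoU thresholds cannot raise AP", {
  set.seed(57)
  for (rep in 1:30) {
    nd <- sample(1:10, 1); ng <- sample(1:5, 1)
    dets <- cbind(randomBoxes(nd, 150, 150, 10, 40),
                  data.frame(confidence = runif(nd)))
    gts <- randomBoxes(ng, 150, 150, 10, 40)
    ap01 <- averagePrecisionValue(averagePrecision(matchDetections(dets, gts, 0.1)))
    ap05 <- averagePrecisionValue(averagePrecision(matchDetections(dets, gts, 0.5)))
    expect_lte(ap05, ap01 + 1e-12)
  }
})

test_that("F1 sweep finds the separating threshold and handles edge cases", {
  gts <- randomBoxes(6, 300, 300, 20, 30)
  # correct detections confident (>= 0.6), spurious ones weak (<= 0.4)
  good <- cbind(gts, data.frame(confidence = seq(0.6, 0.95, length.out = 6)))
  bad <- data.frame(cx = seq(20, 120, 20), cy = 280, w = 4, h = 4,
                    confidence = seq(0.1, 0.4, length.out = 6))
  sw <- sweepThresholds(rbind(good, bad), gts, 0.1, 0.05)
  expect_gt(sw$bestThreshold, 0.4)
  expect_lte(sw$bestThreshold, 0.6)
  expect_equal(max(sw$sweep$f1), 1)
  # perfect detector: F1 = 1 everywhere reachable, ties resolve low
  swP <- sweepThresholds(cbind(gts, data.frame(confidence = 1)), gts, 0.1)
  expect_equal(swP$bestThreshold, 0)
  expect_true(all(swP$sweep$f1 == 1))
  # no detections at all: P = R = F1 = 0 by convention
  swE <- sweepThresholds(good[0, ], gts, 0.1)
  expect_true(all(swE$sweep$f1 == 0))
  expect_true(all(swE$sweep$precision == 0))
  expect_identical(nrow(swE$sweep), 21L)
  expect_equal(range(swE$sweep$threshold), c(0, 1))
})
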