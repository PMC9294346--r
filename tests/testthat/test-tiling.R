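test_that("segment lattice reproduces the printed well decompositions", {
  g1 <- gridDims(10248, 9122, 416, 0.5)
  expect_identical(dim(g1), c(44L, 50L))
  expect_identical(nSegments(g1), 2200L)
  g2 <- gridDims(8320, 7760, 416, 0.5)
  expect_identical(dim(g2), c(38L, 40L))
  expect_identical(nSegments(g2), 1520L)
  g0 <- gridDims(10248, 9122, 416, 0)
  expect_identical(dim(g0), c(22L, 25L))
  expect_identical(nSegments(g0), 550L)
  # an image of exactly one segment: a single tile without overlap; with
  # 50% overlap the ceiling rule places a (padded) second row and column
  expect_identical(nSegments(gridDims(416, 416, 416, 0)), 1L)
  expect_identical(nSegments(gridDims(416, 416, 416, 0.5)), 4L)
  # half-overlap quadruples the non-overlap count when both sides >= 2 strides
  expect_identical(nSegments(g1), 4L * nSegments(g0))
})

test_that("invalid lattice requests are rejected with informative errors", {
  expect_error(gridDims(10248, 9122, 416, 0.3), "0.3")
  expect_error(gridDims(0, 100), "positive")
  expect_error(gridDims(100, 100, 416, 1), "\\[0, 1\\)")
})

test_that("every pixel is covered by at least one segment window", {
  for (ov in c(0, 0.5, 0.75)) {
    g <- gridDims(1000, 700, 416, ov)
    lastX <- (g@nCols - 1L) * segmentStride(g) + g@segmentSizePx
    lastY <- (g@nRows - 1L) * segmentStride(g) + g@segmentSizePx
    expect_gte(lastX, 1000)
    expect_gte(lastY, 700)
  }
})

test_that("segment extraction pads edge windows and partitions at overlap 0", {
  set.seed(11)
  px <- matrix(runif(120 * 90), 90, 120)
  well <- wellImage(px)
  # constant interior segment
  cw <- wellImage(matrix(0.5, 500, 600))
  g <- gridDims(600, 500, 416, 0.5)
  seg <- extractSegment(cw, g, 0, 0)
  expect_true(all(seg == 0.5))
  # bottom-right edge segment of the full-size lattice: 56 image columns
  gBig <- gridDims(10248, 9122, 416, 0.5)
  org <- segmentOrigin(gBig, 0, 49)
  expect_equal(org[["x"]], 10192)
  expect_equal(10248 - org[["x"]], 56)        # real columns
  expect_equal(org[["x"]] + 416 - 10248, 360) # padded columns
  # overlap-0 tiling reassembles the original image exactly
  g0 <- gridDims(120, 90, 30, 0)
  recon <- matrix(NA_real_, 90, 120)
  for (r in 0:(g0@nRows - 1)) for (co in 0:(g0@nCols - 1)) {
    s <- extractSegment(well, g0, r, co)
    recon[r * 30 + 1:30, co * 30 + 1:30] <- s
  }
  expect_identical(recon, px)
  expect_error(extractSegment(well, g0, 99, 0), "outside")
})

test_that("segment/well coordinate maps are exact inverses", {
  g <- gridDims(2080, 1664, 416, 0.5)
  expect_equal(unlist(toGlobal(g, 1, 1, 0, 0)), c(x = 208, y = 208))
  expect_equal(unlist(toLocal(g, 1, 2, 500, 300)), c(x = 84, y = 92))
  set.seed(3)
  x <- runif(1000, 0, 416); y <- runif(1000, 0, 416)
  gl <- toGlobal(g, 2, 3, x, y)
  back <- toLocal(g, 2, 3, gl$x, gl$y)
  expect_equal(back$x, x)
  expect_equal(back$y, y)
})

test_that("box side synthesis rounds half away from zero", {
  expect_identical(boxSideFromWidth(10248), 100L)
  expect_identical(boxSideFromWidth(8320), 81L)
  expect_identical(boxSideFromWidth(1025), 10L)
  expect_error(boxSideFromWidth(10), "degenerates")
})

test_that("marks fan out to every covering segment and clip correctly", {
  g <- gridDims(832, 832, 416, 0)       # 2 x 2 non-overlapping
  lab <- assignLabels(data.frame(x = 416, y = 416), g, 100)
  expect_identical(nrow(lab), 1L)       # boundary point: later segment only
  expect_identical(c(lab$row, lab$col), c(1L, 1L))
  gOv2 <- gridDims(2080, 1664, 416, 0.5)
  lab4 <- assignLabels(data.frame(x = 210, y = 210), gOv2, 100)
  expect_identical(nrow(lab4), 4L)
  expect_setequal(paste(lab4$row, lab4$col), c("0 0", "0 1", "1 0", "1 1"))
  # clip arithmetic: mark 2 px inside the left edge of segment (1, 1)
  labClip <- lab4[lab4$row == 1 & lab4$col == 1, ]
  expect_equal(labClip$w, 2 + 50)       # 2 px to the edge + half box
  g1 <- gridDims(416, 416, 416, 0)
  labE <- assignLabels(data.frame(x = 10, y = 200), g1, 100)
  expect_equal(labE$w, 60)              # 10 + 50
  expect_error(assignLabels(data.frame(x = -1, y = 0), g1, 100), "outside")
})

test_that("label synthesis conserves marks and keeps boxes inside segments", {
  set.seed(21)
  g <- gridDims(1040, 832, 208, 0)
  marks <- data.frame(x = runif(60, 0, 1039.9), y = runif(60, 0, 831.9))
  lab <- assignLabels(marks, g, 41)
  expect_identical(nrow(lab), 60L)      # exactly one box per mark
  expect_identical(sort(unique(lab$mark)), 1:60)
  gOv <- gridDims(1040, 832, 208, 0.5)
  labOv <- assignLabels(marks, gOv, 41)
  s <- gOv@segmentSizePx
  expect_true(all(labOv$cx - labOv$w / 2 >= -1e-9))
  expect_true(all(labOv$cx + labOv$w / 2 <= s + 1e-9))
  expect_true(all(labOv$cy - labOv$h / 2 >= -1e-9))
  expect_true(all(labOv$cy + labOv$h / 2 <= s + 1e-9))
  expect_true(all(labOv$w > 0 & labOv$h > 0))
})

test_that("training bookkeeping converts epochs to iterations", {
  expect_identical(trainingIterations(354320, 2), 11073L)
  expect_equal(iterationsToEpochs(11073, 354320), 2, tolerance = 1e-4)
  expect_identical(trainingIterations(64, 1, 64), 1L)
})
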