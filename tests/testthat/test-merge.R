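test_that("box shrinking keeps centers and scales sides", {
  b <- shrinkBox(data.frame(cx = 50, cy = 50, w = 100, h = 100), 0.2)
  expect_equal(unlist(b), c(cx = 50, cy = 50, w = 80, h = 80))
  b0 <- data.frame(cx = 1, cy = 2, w = 10, h = 4)
  expect_equal(shrinkBox(b0, 0), b0)
  expect_equal(shrinkBox(b0, 0.5)$w, 5)
  expect_error(shrinkBox(b0, 1), "factor")
})

test_that("ellipse rasterization fills the right area and unions", {
  # 80-px square box: disc of radius 40
  m <- rasterizeEllipses(data.frame(cx = 100, cy = 100, w = 80, h = 80),
                         200, 200)
  expect_lt(abs(sum(m) - pi * 40^2) / (pi * 40^2), 0.01)
  # no boxes: empty mask
  expect_identical(sum(rasterizeEllipses(data.frame(cx = numeric(0),
                                                    cy = numeric(0),
                                                    w = numeric(0),
                                                    h = numeric(0)),
                                         50, 50)), 0L)
  # duplicate boxes: idempotent union
  two <- data.frame(cx = c(100, 100), cy = c(100, 100), w = 80, h = 80)
  expect_identical(rasterizeEllipses(two, 200, 200), m)
  # sub-pixel box leaves exactly one pixel
  tiny <- rasterizeEllipses(data.frame(cx = 10.5, cy = 10.5, w = 0.2,
                                       h = 0.2), 50, 50)
  expect_identical(sum(tiny), 1L)
  # fully off-canvas box is skipped with a warning
  expect_warning(rasterizeEllipses(data.frame(cx = 500, cy = 500, w = 10,
                                              h = 10), 50, 50), "outside")
})

test_that("duplicate detections of one cell fuse to one region", {
  recs <- data.frame(cx = c(200, 205), cy = c(150, 150), w = 100, h = 100,
                     confidence = 0.9)
  merged <- mergeDetections(recs, 400, 300)
  expect_identical(nrow(merged), 1L)
  expect_setequal(merged$members[[1]], 1:2)
  far <- data.frame(cx = c(100, 600), cy = 100, w = 100, h = 100,
                    confidence = 0.9)
  expect_identical(nrow(mergeDetections(far, 800, 200)), 2L)
})

test_that("the fuse/no-fuse boundary of 100-px boxes sits between 79 and 81 px", {
  spaced <- function(d) {
    recs <- data.frame(cx = c(150, 150 + d), cy = 100, w = 100, h = 100,
                       confidence = 0.5)
    nrow(mergeDetections(recs, 450, 200))
  }
  expect_identical(spaced(79), 1L)  # shrunk ellipses overlap
  expect_identical(spaced(81), 2L)  # a background column separates them
})

test_that("merging never increases counts and deduplication is idempotent", {
  set.seed(41)
  # arbitrary overlapping boxes: counts can only shrink, members all appear
  for (rep in 1:5) {
    recs <- cbind(randomBoxes(25, 600, 400, wmin = 20, wmax = 80),
                  data.frame(confidence = runif(25)))
    merged <- mergeDetections(recs, 600, 400)
    expect_lte(nrow(merged), nrow(recs))
    # every input contributes somewhere
    expect_setequal(sort(unique(unlist(merged$members))), 1:25)
  }
  # duplicate-detection geometry (the algorithm's target case): the merged
  # count equals the number of distinct cells and re-merging is idempotent
  for (rep in 1:10) {
    inst <- dupInstance()
    merged <- mergeDetections(inst$recs, 800, 500)
    expect_identical(nrow(merged), inst$k)
    again <- mergeDetections(merged[, c("cx", "cy", "w", "h")], 800, 500)
    expect_identical(nrow(again), nrow(merged))
  }
  # disjoint shrunk ellipses: counts are conserved exactly
  grid <- expand.grid(cx = seq(50, 550, by = 100), cy = seq(50, 350, 100))
  recs <- cbind(grid, data.frame(w = 60, h = 60, confidence = 1))
  expect_identical(nrow(mergeDetections(recs, 600, 400)), nrow(recs))
})

test_that("merging is translation-equivariant for interior detections", {
  recs <- data.frame(cx = c(100, 140, 300), cy = c(100, 100, 200),
                     w = 60, h = 60, confidence = 1)
  a <- mergeDetections(recs, 600, 400)
  b <- mergeDetections(transform(recs, cx = cx + 50, cy = cy + 30), 600, 400)
  expect_identical(nrow(a), nrow(b))
  expect_equal(sort(b$cx), sort(a$cx) + 50)
  expect_equal(sort(b$cy), sort(a$cy) + 30)
})
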