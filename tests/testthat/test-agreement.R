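test_that("percentage-of-mean differences match the worked example", {
  d <- pctDiff(5, 1)
  expect_equal(d$meanCount, 3)
  expect_equal(d$diffPct, 133.3, tolerance = 1e-3)
  expect_equal(pctDiff(7, 7)$diffPct, 0)
  # antisymmetry
  expect_equal(pctDiff(1, 5)$diffPct, -pctDiff(5, 1)$diffPct)
  set.seed(61)
  a <- rpois(50, 100); b <- rpois(50, 100)
  expect_equal(pctDiff(a, b)$diffPct, -pctDiff(b, a)$diffPct)
  expect_error(pctDiff(0, 0), "undefined")
})

test_that("RMSE and Pearson agree with direct two-pass formulas", {
  a <- c(10, 20, 30); expect_equal(countRmse(a, a), 0)
  expect_equal(countPearson(a, 2 * a + 3), 1)
  set.seed(63)
  x <- rpois(40, 200); y <- x + rnorm(40, 0, 20)
  expect_equal(countRmse(x, y), sqrt(sum((x - y)^2) / 40), tolerance = 1e-12)
  mx <- mean(x); my <- mean(y)
  rOracle <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  expect_equal(countPearson(x, y), rOracle, tolerance = 1e-12)
  expect_error(countPearson(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(countPearson(1, 2), "at least 2")
})

test_that("omnibus normality statistic matches its reference values", {
  x <- c(1.2, -0.7, 3.4, 0.1, -2.2, 0.8, 1.9, -1.1, 0.4, 2.6,
         -0.3, 1.5, 0.9, -1.8, 2.1, 0.2, -0.6, 1.1, 3.9, -0.9,
         0.7, 1.3, -2.5, 0.5, 1.7)
  r <- dagostinoTest(x)
  expect_equal(r$statistic, 0.0015659608045862, tolerance = 1e-10)
  expect_equal(r$p.value, 0.99921732604688, tolerance = 1e-10)
  r2 <- dagostinoTest(c(x, x^3))   # strongly non-normal
  expect_equal(r2$statistic, 70.148805954796, tolerance = 1e-9)
  expect_lt(r2$p.value, 1e-10)
  expect_error(dagostinoTest(rnorm(5)), "at least 8")
})

test_that("Bland-Altman statistics follow the cited CI formulas", {
  set.seed(65)
  n <- 30
  diffs <- rnorm(n, 3, 8)
  pairs <- data.frame(countA = 100 + diffs / 2, countB = 100 - diffs / 2)
  st <- blandAltman(pairs)
  bias <- mean(diffs); sdd <- sd(diffs); tq <- qt(0.975, n - 1)
  expect_equal(st@biasPct, bias, tolerance = 1e-9)
  expect_equal(st@sdPct, sdd, tolerance = 1e-9)
  expect_equal(st@loaLowPct, bias - 1.96 * sdd, tolerance = 1e-9)
  expect_equal(st@loaHighPct, bias + 1.96 * sdd, tolerance = 1e-9)
  expect_equal(st@ciBias, bias + c(-1, 1) * tq * sdd / sqrt(n),
               tolerance = 1e-9)
  expect_equal(st@ciLoaLow,
               bias - 1.96 * sdd + c(-1, 1) * tq * sqrt(3 * sdd^2 / n),
               tolerance = 1e-9)
  expect_equal(st@ciLoaHigh,
               bias + 1.96 * sdd + c(-1, 1) * tq * sqrt(3 * sdd^2 / n),
               tolerance = 1e-9)
  # bias conserves the mean of the individual differences
  expect_equal(st@biasPct, mean(st@pairs$diffPct))
})

test_that("identical counts give zero bias with degenerate limits", {
  pairs <- data.frame(countA = c(10, 20, 30, 40), countB = c(10, 20, 30, 40))
  st <- blandAltman(pairs)
  expect_equal(st@biasPct, 0)
  expect_equal(c(st@loaLowPct, st@loaHighPct), c(0, 0))
  expect_equal(st@ciBias, c(0, 0))
  expect_equal(st@rmse, 0)
})

test_that("outliers are excluded only on request and always reported", {
  pairs <- data.frame(wellId = c("a", "b", "c", "d"),
                      countA = c(100, 210, 300, 5),
                      countB = c(105, 200, 310, 1))
  stAll <- blandAltman(pairs)
  expect_identical(stAll@nPairs, 4L)
  # the (5, 1) well: mean 3, diff 133.3% — dropped at a 100% bound
  st <- blandAltman(pairs, exclusionPct = 100)
  expect_identical(st@nPairs, 3L)
  expect_identical(st@excluded$wellId, "d")
  expect_equal(st@excluded$diffPct, 133.3, tolerance = 1e-3)
  # a (0, 0) well has no defined difference and is listed separately
  withZero <- rbind(pairs, data.frame(wellId = "e", countA = 0, countB = 0))
  stZ <- blandAltman(withZero)
  expect_identical(stZ@nPairs, 4L)
  expect_match(stZ@excluded$reason, "undefined")
  expect_error(blandAltman(pairs[1:2, ]), "at least 3")
})

test_that("recovered limits of agreement cover ~95% of normal differences", {
  set.seed(67)
  n <- 2000
  diffs <- rnorm(n, 2, 10)
  pairs <- data.frame(countA = 100 + diffs / 2, countB = 100 - diffs / 2)
  st <- blandAltman(pairs)
  inside <- mean(diffs >= st@loaLowPct & diffs <= st@loaHighPct) * 100
  expect_lt(abs(inside - 95), 1.5)
  expect_true(st@ciBias[1] <= 2 && 2 <= st@ciBias[2])
  expect_gt(st@normalityP, 0.01)
})

test_that("well counting pairs detections with annotations by id and mode", {
  recs <- data.frame(cx = c(100, 300, 100), cy = c(100, 100, 300),
                     w = 40, h = 40, confidence = 0.9)
  wdN <- new("WellDetections", wellId = "w1", mode = "nonoverlap",
             widthPx = 400L, heightPx = 400L, records = recs)
  # overlap mode with a duplicated detection: merged count drops to 3
  recsDup <- rbind(recs, transform(recs[1, ], cx = cx + 4))
  wdO <- new("WellDetections", wellId = "w1", mode = "overlap",
             widthPx = 400L, heightPx = 400L, records = recsDup)
  truth <- data.frame(wellId = "w1", experimentId = "e1", count = 3)
  pn <- countWells(list(wdN), truth)
  po <- countWells(list(wdO), truth)
  expect_identical(pn$countA, 3L)
  expect_identical(po$countA, 3L)
  expect_identical(pn$mode, "nonoverlap")
  expect_identical(po$mode, "overlap")
  # zero-detection, zero-mark wells pair as (0, 0)
  wd0 <- new("WellDetections", wellId = "w0", mode = "nonoverlap",
             widthPx = 400L, heightPx = 400L, records = recs[0, ])
  p0 <- countWells(list(wd0), data.frame(wellId = "w0", count = 0))
  expect_equal(c(p0$countA, p0$countB), c(0, 0))
  expect_error(countWells(list(wdN), data.frame(wellId = "zz", count = 1)),
               "no annotated count")
  # per-experiment RMSE equals the direct formula
  pairs <- data.frame(experimentId = c("a", "a", "b"),
                      countA = c(10, 20, 5), countB = c(12, 18, 5))
  pe <- perExperimentRmse(pairs)
  expect_equal(pe$rmse[pe$experimentId == "a"], sqrt(mean(c(4, 4))))
  expect_equal(pe$rmse[pe$experimentId == "b"], 0)
})
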