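#' Percentage-of-mean difference between paired counts
#'
#' The Bland-Altman difference scale for paired counts:
#' `mean = (a + b) / 2` and `diffPct = (a - b) / mean * 100`. A pair of 5
#' detected and 1 annotated cells has mean 3 and a difference of 133.3%.
#' Antisymmetric in its arguments; undefined (error) when both counts are
#' zero.
#'
#' @param countA,countB non-negative paired counts (vectors allowed).
#' @return data.frame with columns `meanCount, diffPct`.
#' @examples
#' pctDiff(5, 1)  # mean 3, diff 133.3
#' @export
pctDiff <- function(countA, countB) {
  if (any(countA < 0 | countB < 0)) stop("counts must be non-negative")
  m <- (countA + countB) / 2
  if (any(m == 0))
    stop("percentage difference undefined for pair(s) with both counts zero: ",
         toString(which(m == 0)))
  data.frame(meanCount = m, diffPct = (countA - countB) / m * 100)
}

#' RMSE and Pearson correlation of paired counts
#'
#' Standard definitions on the raw counts:
#' `rmse = sqrt(mean((a - b)^2))`; Pearson via [stats::cor()].
#'
#' @param countA,countB paired count vectors.
#' @return A single numeric value.
#' @export
countRmse <- function(countA, countB) {
  stopifnot(length(countA) == length(countB), length(countA) >= 1)
  sqrt(mean((countA - countB)^2))
}

#' @rdname countRmse
#' @export
countPearson <- function(countA, countB) {
  stopifnot(length(countA) == length(countB))
  if (length(countA) < 2) stop("Pearson correlation needs at least 2 pairs")
  if (stats::sd(countA) == 0 || stats::sd(countB) == 0)
    stop("Pearson correlation undefined for a zero-variance series")
  stats::cor(countA, countB)
}

#' Omnibus skewness-kurtosis normality test
#'
#' D'Agostino-Pearson K-squared test: combines the D'Agostino (1970)
#' transformed skewness statistic and the Anscombe-Glynn (1983) transformed
#' kurtosis statistic as `K2 = Z_skew^2 + Z_kurt^2`, referred to a
#' chi-squared distribution with 2 df. This is the omnibus test commonly
#' used to check Bland-Altman differences for normality.
#'
#' @param x numeric vector, `length(x) >= 20` recommended (a warning is
#'   issued below 20, where the kurtosis approximation is poor).
#' @return List with `statistic` (K2) and `p.value`.
#' @export
dagostinoTest <- function(x) {
  n <- length(x)
  if (n < 8) stop("omnibus normality test needs at least 8 observations")
  if (n < 20)
    warning("omnibus normality test is approximate for n < 20")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # transformed skewness (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1
  zSkew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # transformed kurtosis (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtB1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtB1 * (2 / sqrtB1 + sqrt(1 + 4 / sqrtB1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xx * sqrt(2 / (A - 4))
  term2 <- sign(denom) * (abs((1 - 2 / A) / denom))^(1 / 3)
  zKurt <- (term1 - term2) / sqrt(2 / (9 * A))
  k2 <- zSkew^2 + zKurt^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2,
                                               lower.tail = FALSE))
}

#' Bland-Altman agreement analysis of paired per-well counts
#'
#' Differences are expressed as a percentage of the pair mean ([pctDiff()]).
#' Reported quantities: bias (mean difference), SD of the differences,
#' limits of agreement `bias +/- 1.96 SD` (containing about 95% of
#' differences under normality), t-based confidence intervals — for the bias
#' `bias +/- t(0.975, n-1) * SD / sqrt(n)` and for each limit
#' `LoA +/- t(0.975, n-1) * sqrt(3 SD^2 / n)` (Giavarina's approximation) —
#' an omnibus skewness-kurtosis normality p-value for the differences
#' ([dagostinoTest()]), and RMSE/Pearson on the raw counts of the usable
#' pairs.
#'
#' Pairs whose difference is undefined (both counts zero) are excluded and
#' listed. Outliers are never dropped silently: only when `exclusionPct` is
#' given are pairs with `|diffPct| > exclusionPct` excluded, each listed
#' with its value (e.g. `exclusionPct = 100` removes a 133.3% outlier well).
#'
#' @param pairs data.frame with columns `countA, countB` and optionally
#'   `wellId, experimentId`.
#' @param exclusionPct optional absolute percentage bound; pairs beyond it
#'   are excluded and reported.
#' @return An [AgreementStats-class].
#' @export
blandAltman <- function(pairs, exclusionPct = NULL) {
  stopifnot(all(c("countA", "countB") %in% names(pairs)))
  if (!"wellId" %in% names(pairs))
    pairs$wellId <- sprintf("pair%d", seq_len(nrow(pairs)))
  excluded <- data.frame(wellId = character(0), diffPct = numeric(0),
                         reason = character(0))
  undef <- (pairs$countA + pairs$countB) == 0
  if (any(undef)) {
    excluded <- rbind(excluded, data.frame(
      wellId = pairs$wellId[undef], diffPct = NA_real_,
      reason = "difference undefined (both counts zero)"))
    pairs <- pairs[!undef, , drop = FALSE]
  }
  d <- pctDiff(pairs$countA, pairs$countB)
  if (!is.null(exclusionPct)) {
    out <- abs(d$diffPct) > exclusionPct
    if (any(out)) {
      excluded <- rbind(excluded, data.frame(
        wellId = pairs$wellId[out], diffPct = d$diffPct[out],
        reason = sprintf("|diff| exceeds %g%%", exclusionPct)))
      pairs <- pairs[!out, , drop = FALSE]
      d <- d[!out, , drop = FALSE]
    }
  }
  n <- nrow(pairs)
  if (n < 3) stop("Bland-Altman analysis needs at least 3 usable pairs")
  bias <- mean(d$diffPct)
  sdd <- stats::sd(d$diffPct)
  loaLow <- bias - 1.96 * sdd
  loaHigh <- bias + 1.96 * sdd
  tq <- stats::qt(0.975, df = n - 1)
  seBias <- sdd / sqrt(n)
  seLoa <- sqrt(3 * sdd^2 / n)
  normP <- if (n >= 8) dagostinoTest(d$diffPct)$p.value else NA_real_
  r <- if (n >= 2 && stats::sd(pairs$countA) > 0 &&
           stats::sd(pairs$countB) > 0)
    countPearson(pairs$countA, pairs$countB) else NA_real_
  usable <- cbind(pairs, d)
  rownames(usable) <- NULL
  new("AgreementStats", nPairs = as.integer(n),
      rmse = countRmse(pairs$countA, pairs$countB), pearsonR = r,
      biasPct = bias, sdPct = sdd, loaLowPct = loaLow, loaHighPct = loaHigh,
      ciBias = c(bias - tq * seBias, bias + tq * seBias),
      ciLoaLow = c(loaLow - tq * seLoa, loaLow + tq * seLoa),
      ciLoaHigh = c(loaHigh - tq * seLoa, loaHigh + tq * seLoa),
      normalityP = normP, excluded = excluded, pairs = usable)
}

#' Per-well counts paired against annotator truth
#'
#' Counts the detections of each well — merged regions ([mergeDetections()])
#' in overlap mode, raw filtered detections in nonoverlap mode — and pairs
#' them with the annotated count for the same well id.
#'
#' @param detectionsByWell list of [WellDetections-class].
#' @param truthCounts data.frame with columns `wellId, count` and optionally
#'   `experimentId` (one row per well).
#' @param shrinkFactor passed to [mergeDetections()] in overlap mode.
#' @return data.frame with columns
#'   `wellId, experimentId, mode, countA` (detected), `countB` (annotated).
#' @export
countWells <- function(detectionsByWell, truthCounts, shrinkFactor = 0.2) {
  if (!"experimentId" %in% names(truthCounts))
    truthCounts$experimentId <- "exp"
  rows <- lapply(detectionsByWell, function(wd) {
    stopifnot(is(wd, "WellDetections"))
    i <- match(wd@wellId, truthCounts$wellId)
    if (is.na(i))
      stop("no annotated count for well id '", wd@wellId, "'")
    detected <- if (wd@mode == "overlap")
      nrow(mergeDetections(wd, shrinkFactor = shrinkFactor))
    else nrow(wd@records)
    data.frame(wellId = wd@wellId,
               experimentId = truthCounts$experimentId[i], mode = wd@mode,
               countA = detected, countB = truthCounts$count[i])
  })
  do.call(rbind, rows)
}

#' Per-experiment RMSE of paired counts
#'
#' @param pairs data.frame with `experimentId, countA, countB`.
#' @return data.frame with columns `experimentId, nWells, rmse`.
#' @export
perExperimentRmse <- function(pairs) {
  sp <- split(pairs, pairs$experimentId)
  out <- lapply(names(sp), function(e)
    data.frame(experimentId = e, nWells = nrow(sp[[e]]),
               rmse = countRmse(sp[[e]]$countA, sp[[e]]$countB)))
  do.call(rbind, out)
}

#' Bland-Altman plot
#'
#' Difference (% of pair mean) against pair mean, with the bias and limits
#' of agreement as dashed lines and their confidence intervals shaded.
#'
#' @param stats an [AgreementStats-class].
#' @param path optional PNG output path; when given, the plot is written
#'   there instead of the active device.
#' @return `stats`, invisibly.
#' @export
plotBlandAltman <- function(stats, path = NULL) {
  stopifnot(is(stats, "AgreementStats"))
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 620)
    on.exit(grDevices::dev.off())
  }
  p <- stats@pairs
  ylim <- range(p$diffPct, stats@ciLoaLow, stats@ciLoaHigh)
  plot(p$meanCount, p$diffPct, pch = 19, col = "grey25",
       xlab = "Mean of paired counts",
       ylab = "Difference (% of mean)",
       ylim = ylim + c(-2, 2), main = "Bland-Altman agreement")
  shade <- function(ci) graphics::rect(graphics::par("usr")[1], ci[1],
                                       graphics::par("usr")[2], ci[2],
                                       col = grDevices::adjustcolor("grey60", 0.3),
                                       border = NA)
  shade(stats@ciBias); shade(stats@ciLoaLow); shade(stats@ciLoaHigh)
  graphics::abline(h = stats@biasPct, lty = 2, col = "black")
  graphics::abline(h = c(stats@loaLowPct, stats@loaHighPct), lty = 2,
                   col = "red")
  graphics::abline(h = 0, col = "grey70")
  invisible(stats)
}
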