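coverageFixture <- function(mean = 30, high = NULL) {
  win <- data.frame(chrom = rep(c("chr1", "chr2"), each = 100),
                    start = rep(seq(0, 99e4, 1e4), 2))
  win$end <- win$start + 1e4
  win$coverage <- rep(mean, nrow(win))
  if (!is.null(high))
    win$coverage[win$chrom == high$chrom &
                   win$start == high$window] <- high$value
  CoverageTrack(win, genomeMean = mean)
}

test_that("support filter applies the coverage-fraction threshold", {
  g <- tinyGenome()
  cov <- coverageFixture(mean = 30)
  calls <- newAdjacencies(adjDf("chr1", c(1e5, 2e5, 3e5), "tail",
                                "chr2", c(5e5, 5e5, 5e5), "head",
                                support = c(1, 2, NA)), g)
  res <- filterSupport(calls, cov)  # threshold 0.05 * 30 = 1.5
  expect_equal(res$removed$support, 1)
  expect_equal(nrow(res$kept), 2L)          # NA support passes through
  expect_equal(res$removed$filter_reason, "low_support")
  # frac 0 removes nothing
  expect_equal(nrow(filterSupport(calls, cov, frac = 0)$removed), 0L)
  badCov <- coverageFixture(mean = 30)
  badCov@genomeMean <- 0
  expect_error(filterSupport(calls, badCov), "mean coverage")
})

test_that("high-coverage filter removes calls with a breakend in a hot window", {
  g <- tinyGenome()
  cov <- coverageFixture(mean = 30, high = list(chrom = "chr1",
                                                window = 4e5, value = 100))
  calls <- newAdjacencies(adjDf("chr1", c(405000, 1e5), "tail",
                                "chr2", c(5e5, 5e5), "head",
                                support = 10), g)
  res <- filterHighCoverage(calls, cov)     # 100 > 3 * 30
  expect_equal(res$removed$pos1, 405000)
  expect_equal(nrow(res$kept), 1L)
  expect_equal(nrow(filterHighCoverage(calls, cov, factor = Inf)$removed),
               0L)
  outside <- newAdjacencies(adjDf("chr1", 1e5, "tail", "chr2", 999999,
                                  "head"), g)
  covShort <- CoverageTrack(data.frame(chrom = "chr1", start = 0,
                                       end = 1e6, coverage = 30),
                            genomeMean = 30)
  expect_error(filterHighCoverage(outside, covShort), "outside")
})

test_that("gap filter uses strict distance with inside counting as zero", {
  g <- tinyGenome(gaps = data.frame(chrom = "chr1", start = 1e5, end = 2e5))
  calls <- newAdjacencies(adjDf("chr1", c(195000, 209999, 210000), "tail",
                                "chr2", rep(5e5, 3), "head"), g)
  res <- filterNearGaps(calls, g)
  expect_setequal(res$removed$pos1, c(195000, 209999))
  expect_equal(res$kept$pos1, 210000)       # distance exactly 10 kb kept
})

test_that("segdup filter uses half-open interval overlap", {
  g <- tinyGenome(segdups = data.frame(chrom = "chr1", start = 500,
                                       end = 900))
  calls <- newAdjacencies(adjDf("chr1", c(600, 900), "tail",
                                "chr2", c(5e5, 5e5), "head"), g)
  res <- filterSegdup(calls, g)
  expect_equal(res$removed$pos1, 600)
  expect_equal(res$kept$pos1, 900)
  g0 <- tinyGenome()
  expect_equal(nrow(filterSegdup(calls, g0)$removed), 0L)
})

test_that("every filter partitions its input", {
  set.seed(11)
  g <- tinyGenome(gaps = data.frame(chrom = "chr1", start = 4e5, end = 5e5),
                  segdups = data.frame(chrom = "chr2", start = 1e5,
                                       end = 15e4))
  cov <- coverageFixture()
  calls <- newAdjacencies(adjDf("chr1", sample(1e6 - 1, 40), "tail",
                                "chr2", sample(1e6 - 1, 40), "head",
                                support = sample(0:20, 40, TRUE)), g)
  for (res in list(filterSupport(calls, cov),
                   filterHighCoverage(calls, cov),
                   filterNearGaps(calls, g),
                   filterSegdup(calls, g))) {
    expect_equal(nrow(res$kept) + nrow(res$removed), nrow(calls))
    expect_length(intersect(res$kept$id, res$removed$id), 0)
  }
})

test_that("filters commute as pure predicates on their keep sets", {
  set.seed(12)
  g <- tinyGenome(gaps = data.frame(chrom = "chr1", start = 4e5, end = 5e5),
                  segdups = data.frame(chrom = "chr2", start = 1e5, end = 15e4))
  cov <- coverageFixture()
  calls <- newAdjacencies(adjDf("chr1", sample(1e6 - 1, 60), "tail",
                                "chr2", sample(1e6 - 1, 60), "head",
                                support = sample(0:20, 60, TRUE)), g)
  ab <- filterNearGaps(filterSegdup(calls, g)$kept, g)$kept
  ba <- filterSegdup(filterNearGaps(calls, g)$kept, g)$kept
  expect_setequal(ab$id, ba$id)
  cd <- filterSupport(filterHighCoverage(calls, cov)$kept, cov)$kept
  dc <- filterHighCoverage(filterSupport(calls, cov)$kept, cov)$kept
  expect_setequal(cd$id, dc$id)
})

test_that("cohort filter removes clustered cross-sample calls only", {
  g <- tinyGenome()
  a <- newAdjacencies(adjDf("chr1", c(1e5, 3e5, 3.005e5), "tail",
                            "chr2", c(5e5, 7e5, 7.003e5), "head",
                            id = c("shared", "a_only1", "a_only2")), g)
  b <- newAdjacencies(adjDf("chr1", 1e5 + 300, "tail",
                            "chr2", 5e5 - 200, "head", id = "sharedB"), g)
  res <- filterCohort(list(A = a, B = b))
  # shared adjacency (within 1 kb on both ends) removed in both samples
  expect_equal(res$A$removed$id, "shared")
  expect_equal(res$B$removed$id, "sharedB")
  # two A-only calls 500 bp apart cluster together but stay single-sample
  expect_setequal(res$A$kept$id, c("a_only1", "a_only2"))
  expect_warning(filterCohort(list(A = a)), "2 samples")
})

test_that("technology merge prefers precise short-read calls", {
  g <- tinyGenome()
  long <- newAdjacencies(adjDf("chr1", c(1e5, 3e5, 6e5), "tail",
                               "chr2", c(5e5, 6e5, 9e5), "head",
                               caller = "longread",
                               id = c("L1", "L2", "L3")), g)
  short <- newAdjacencies(adjDf("chr1", c(1e5 + 40, 3e5 - 20, 8e5), "tail",
                                "chr2", c(5e5 + 10, 6e5 + 30, 9e5), "head",
                                caller = "shortread",
                                precise = c(TRUE, FALSE, TRUE),
                                id = c("S1", "S2", "S3")), g)
  merged <- mergeTechnologies(long, short, matchDist = 1000)
  expect_equal(nrow(merged), 4L)  # 2 matched + 1 long-only + 1 short-only
  m1 <- merged[merged$tech == "both" & merged$chrom1 == "chr1" &
                 abs(merged$pos1 - 1e5) <= 1000, ]
  expect_equal(m1$id, "S1")       # precise short call chosen
  expect_equal(m1$pos1, 1e5 + 40)
  m2 <- merged[merged$id %in% c("L2", "S2"), ]
  expect_equal(m2$id, "L2")       # imprecise short -> long-read coordinates
  expect_equal(merged$tech[merged$id == "L3"], "longread")
  expect_equal(merged$tech[merged$id == "S3"], "shortread")
})

test_that("large-scale selection is strict and keeps trans calls", {
  g <- tinyGenome()
  calls <- newAdjacencies(rbind(
    adjDf("chr1", 1e5, "tail", "chr2", 5e5, "head", id = "trans"),
    adjDf("chr1", 1e5, "tail", "chr1", 2e5, "head", id = "cis100k"),
    adjDf("chr1", 1e5, "tail", "chr1", 200001, "head", id = "cis100k1")), g)
  res <- selectLargeScale(calls)
  expect_setequal(res$large$id, c("trans", "cis100k1"))
  expect_equal(res$small$id, "cis100k")
})

test_that("small-scale calls attach at curated anchors within tolerance", {
  g <- tinyGenome()
  curated <- newAdjacencies(adjDf("chr1", 2e5, "tail", "chr2", 5e5, "head",
                                  id = "big", curated = TRUE), g)
  small <- newAdjacencies(rbind(
    adjDf("chr1", 2e5 + 20, "tail", "chr1", 2.1e5, "head", id = "near"),
    adjDf("chr1", 7e5, "tail", "chr1", 7.2e5, "head", id = "far"),
    adjDf("chr1", 2e5, "tail", "chr1", 2.05e5, "head", id = "exact")), g)
  aug <- attachSmallScale(curated, small, tol = 50)
  expect_setequal(aug$id, c("big", "near", "exact"))
  exactOnly <- attachSmallScale(curated, small, tol = 0)
  expect_setequal(exactOnly$id, c("big", "exact"))
})
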