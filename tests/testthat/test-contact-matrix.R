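test_that("COO round trip is the identity and the header is required", {
  set.seed(21)
  cm <- randomContactMatrix(10)
  f <- tempfile(fileext = ".coo")
  writeCoo(cm, f)
  back <- readCoo(f)
  expect_equal(contactEntries(back), contactEntries(cm))
  expect_equal(binSize(back), binSize(cm))
  expect_equal(chromTable(back), chromTable(cm))
  # missing header
  writeLines(c("0 1 3", "1 2 4"), f)
  expect_error(readCoo(f), "header")
})

test_that("lower-triangle entries are normalized, negative counts rejected", {
  ch <- data.frame(name = "c1", length = 2.5e5)
  expect_warning(cm <- ContactMatrix(ch, 25000,
                                     data.frame(i = 5, j = 2, count = 3)),
                 "normalized")
  ent <- contactEntries(cm)
  expect_equal(ent, data.frame(i = 2L, j = 5L, count = 3))
  expect_error(ContactMatrix(ch, 25000,
                             data.frame(i = 1, j = 2, count = -1)),
               "negative")
})

test_that("bin rounding: starts round up, ends round down, sub-bin flagged", {
  cm <- ContactMatrix(data.frame(name = "c1", length = 2.5e5), 25000)
  fb <- fragmentBins(cm, "c1", 30000, 120000)
  expect_equal(fb$startBin, 2L)   # covers 50-100 kb
  expect_equal(fb$endBin, 4L)
  expect_false(fb$subBin)
  fb0 <- fragmentBins(cm, "c1", 0, 25000)
  expect_equal(c(fb0$startBin, fb0$endBin), c(0L, 1L))
  expect_true(fragmentBins(cm, "c1", 30000, 40000)$subBin)
  expect_equal(binOf(cm, "c1", c(0, 24999, 25000)), c(0L, 0L, 1L))
})

test_that("tile extraction equals dense slicing with axis reversals", {
  set.seed(22)
  for (k in 1:20) {
    n <- sample(6:14, 1)
    cm <- randomContactMatrix(n)
    full <- denseContacts(cm)
    s1 <- sample(0:(n - 2), 1); e1 <- sample((s1 + 1):n, 1)
    s2 <- sample(0:(n - 2), 1); e2 <- sample((s2 + 1):n, 1)
    tile <- extractTile(cm, c(s1, e1), c(s2, e2))
    expect_identical(tile, full[(s1 + 1):e1, (s2 + 1):e2, drop = FALSE])
    inv <- extractTile(cm, c(s1, e1), c(s2, e2), TRUE, TRUE)
    expect_identical(inv[rev(seq_len(nrow(inv))), rev(seq_len(ncol(inv))),
                         drop = FALSE], tile)
  }
  cm0 <- ContactMatrix(data.frame(name = "c1", length = 2.5e5), 25000)
  expect_true(all(extractTile(cm0, c(0, 5), c(0, 5)) == 0))
  expect_error(extractTile(cm0, c(3, 3), c(0, 5)), "sub-bin")
})

test_that("decay fit recovers constant and power-law backgrounds", {
  n <- 10
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  cmC <- ContactMatrix(data.frame(name = "c1", length = n * 25000), 25000,
                       data.frame(i = ij[, 1] - 1, j = ij[, 2] - 1,
                                  count = 7))
  dec <- fitDecay(cmC)
  expect_true(all(abs(dec$expected - 7) < 1e-9))
  expect_equal(dec$trans, 0)   # trans-free matrix
  expect_true(all(diff(dec$expected) <= 1e-12))  # nonincreasing
  # planted 1/(1+d) decay, Poisson sampled at high depth
  set.seed(23)
  tr <- simulateRearrangement(simConfig(ctBreakpoints = 0L,
                                        hicDepth = 200), seed = 23)
  hic <- emitHic(tr)
  dec2 <- fitDecay(hic)
  d <- 0:50
  truth <- 200 * (1 + d)^-1
  expect_true(all(abs(dec2$expected[d + 1] - truth) / truth < 0.1))
  expect_error(fitDecay(ContactMatrix(data.frame(name = "c1",
                                                 length = 2.5e5), 25000)),
               "empty")
})

test_that("ectopic scoring flags strong trans tiles only", {
  # 2 chroms, constant cis signal, one hot trans block
  n <- 10
  ch <- data.frame(name = c("c1", "c2"), length = rep(n * 25000, 2))
  ij <- which(upper.tri(matrix(0, 2 * n, 2 * n), diag = TRUE), arr.ind = TRUE)
  cis <- (ij[, 1] <= n & ij[, 2] <= n) | (ij[, 1] > n & ij[, 2] > n)
  count <- ifelse(cis, 5, 0.2)
  hot <- ij[, 1] <= 5 & ij[, 2] > n & ij[, 2] <= n + 5
  count[hot] <- 10 * 0.2 * (n * n) / (0.2 * (n * n - 25) + 2 * 25) # ~10x mean
  cm <- ContactMatrix(ch, 25000, data.frame(i = ij[, 1] - 1,
                                            j = ij[, 2] - 1, count = count))
  dec <- fitDecay(cm)
  hotTile <- ectopicScore(cm, dec, c(0, 5), c(n, n + 5))
  expect_true(hotTile$flag)
  coldTile <- ectopicScore(cm, dec, c(5, n), c(n + 5, 2 * n))
  expect_false(coldTile$flag)
  expect_lt(coldTile$score, 1)
  # background cis tile is not flagged
  cisTile <- ectopicScore(cm, dec, c(0, 5), c(5, n))
  expect_false(cisTile$flag)
  # minimum nonzero-bin requirement
  tiny <- ectopicScore(cm, dec, c(0, 1), c(n, n + 1), minBins = 4L)
  expect_false(tiny$flag)
  empty <- ectopicScore(cm, dec, c(3, 3), c(0, 5))
  expect_equal(empty$score, 0)
  expect_false(empty$flag)
})

test_that("grid partition tiles every chromosome exactly", {
  cm <- ContactMatrix(data.frame(name = c("c1", "c2"),
                                 length = c(2.5e5, 1.25e5)), 25000)
  grid <- gridPartition(cm, data.frame(chrom = "c1", pos = c(60000, 130000)))
  c1 <- grid[grid$chrom == "c1", ]
  expect_equal(c1$startBin, c(0L, 3L, 6L))
  expect_equal(c1$endBin, c(3L, 6L, 10L))
  expect_equal(sum(grid$endBin - grid$startBin), 15L)
})

test_that("control subtraction scales to half the off-diagonal signal", {
  set.seed(24)
  cm <- randomContactMatrix(10, density = 0.8)
  res <- subtractControl(cm, cm)
  e0 <- contactEntries(cm); e1 <- contactEntries(res)
  off0 <- e0[e0$i != e0$j, ]; off1 <- e1[e1$i != e1$j, ]
  m <- merge(off0, off1, by = c("i", "j"))
  expect_true(all(abs(m$count.y - m$count.x / 2) < 1e-12))
  # control without off-diagonal signal -> error
  diagOnly <- ContactMatrix(chromTable(cm)[, c("name", "length")], 25000,
                            data.frame(i = 0:9, j = 0:9, count = 1))
  expect_error(subtractControl(cm, diagOnly), "off-diagonal")
  # the evaluation variant excludes the first subdiagonal too
  res2 <- subtractControl(cm, cm, exclude = "main_and_first")
  e2 <- contactEntries(res2)
  m2 <- merge(off0, e2, by = c("i", "j"))
  sub2 <- m2[m2$j - m2$i >= 2, ]
  expect_true(all(abs(sub2$count.y - sub2$count.x / 2) < 1e-12))
})

test_that("negative values after subtraction clip to zero", {
  ch <- data.frame(name = "c1", length = 1e5)
  s <- ContactMatrix(ch, 25000, data.frame(i = c(0, 0), j = c(1, 2),
                                           count = c(1, 10)))
  ctl <- ContactMatrix(ch, 25000, data.frame(i = c(0, 0), j = c(1, 2),
                                             count = c(10, 1)))
  res <- subtractControl(s, ctl)
  ent <- contactEntries(res)
  expect_true(all(ent$count >= 0))
})
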