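test_that("telomeric-end counting respects orientation", {
  g <- tinyGenome(c(chrA = 1e5))
  lyBoth <- list(fragments = data.frame(fragment = "f", chrom = "chrA",
                                        start = 0, end = 1e5,
                                        orientation = "forward"))
  expect_equal(scaffoldTelomericEnds(lyBoth, g), 2)
  lyOne <- list(fragments = data.frame(fragment = "f", chrom = "chrA",
                                       start = 0, end = 5e4,
                                       orientation = "forward"))
  expect_equal(scaffoldTelomericEnds(lyOne, g), 1)
  lyOneInv <- lyOne
  lyOneInv$fragments$orientation <- "inverted"
  expect_equal(scaffoldTelomericEnds(lyOneInv, g), 1)
  lyNone <- list(fragments = data.frame(fragment = "f", chrom = "chrA",
                                        start = 2e4, end = 5e4,
                                        orientation = "forward"))
  expect_equal(scaffoldTelomericEnds(lyNone, g), 0)
})

test_that("scaffold grouping links by flagged tiles with transitivity", {
  # six chromosomes so ectopic blocks stay a small share of the trans
  # area; scaffolds on c1..c3 with strong blocks linking s1-s2 and s2-s3
  n <- 8
  ch <- data.frame(name = paste0("c", 1:6), length = rep(n * 25000, 6))
  g <- GenomeModel(ch)
  N <- 6 * n
  ij <- which(upper.tri(matrix(0, N, N), diag = TRUE), arr.ind = TRUE)
  chromOf <- function(b) (b - 1) %/% n
  cis <- chromOf(ij[, 1]) == chromOf(ij[, 2])
  count <- ifelse(cis, 5, 0.1)
  hot12 <- ij[, 1] <= n & ij[, 2] > n & ij[, 2] <= 2 * n
  hot23 <- ij[, 1] > n & ij[, 1] <= 2 * n & ij[, 2] > 2 * n &
    ij[, 2] <= 3 * n
  count[hot12 | hot23] <- 8
  cm <- ContactMatrix(ch, 25000, data.frame(i = ij[, 1] - 1,
                                            j = ij[, 2] - 1,
                                            count = count))
  dec <- fitDecay(cm)
  mkScaffold <- function(nm, chrom) list(
    name = nm, fragments = data.frame(fragment = nm, chrom = chrom,
                                      start = 0, end = n * 25000,
                                      orientation = "forward"),
    completeness = "scaffold")
  sc <- list(mkScaffold("s1", "c1"), mkScaffold("s2", "c2"),
             mkScaffold("s3", "c3"))
  grp <- groupScaffolds(sc, cm, dec, g)
  expect_length(grp, 1L)              # chain s1-s2, s2-s3 unions all three
  expect_setequal(grp[[1]]$members, 1:3)
  expect_gt(nrow(grp[[1]]$evidence), 0L)
  # without flagged tiles every scaffold is its own group
  cold <- ContactMatrix(ch, 25000,
                        data.frame(i = ij[cis, 1] - 1, j = ij[cis, 2] - 1,
                                   count = 5))
  grp2 <- groupScaffolds(sc, cold, fitDecay(cold), g)
  expect_length(grp2, 3L)
  # a fragment shared by two scaffolds is an error
  scBad <- c(sc, list(mkScaffold("s1", "c1")))
  expect_error(groupScaffolds(scBad, cm, dec, g), "two scaffolds")
})

test_that("layout enumeration matches the closed form and fixes the ends", {
  sg <- simulateScaffoldGroup(nScaffolds = 4, seed = 81)
  sc <- sg$scaffolds
  mkGroup <- function(members) list(
    members = members, scaffolds = sc[members],
    telomericEnds = sum(vapply(sc[members], scaffoldTelomericEnds,
                               numeric(1), genome = sg$genome)))
  for (cfg in list(list(n = 2, expect = 1),
                   list(n = 4, expect = 8))) {
    # keep the two telomeric scaffolds (first and last) plus middles
    members <- c(1, seq_len(cfg$n - 2) + 1, length(sc))[seq_len(cfg$n)]
    members <- unique(c(1, head(2:(length(sc) - 1), cfg$n - 2),
                        length(sc)))
    cand <- enumerateLayouts(mkGroup(members), sg$genome)
    expect_length(cand, cfg$expect)
    keys <- vapply(cand, layoutKey, "")
    expect_equal(anyDuplicated(keys), 0L)
    # ends fixed, telomere outward
    first <- sc[[1]]$fragments$fragment[1]
    last <- sc[[length(sc)]]$fragments$fragment[1]
    for (cd in cand) {
      expect_equal(cd$fragments$fragment[1], first)
      expect_equal(cd$fragments$fragment[nrow(cd$fragments)], last)
    }
  }
  sg5 <- simulateScaffoldGroup(nScaffolds = 5, seed = 82)
  g5 <- list(members = 1:5, scaffolds = sg5$scaffolds,
             telomericEnds = 2)
  expect_length(enumerateLayouts(g5, sg5$genome), 48L)
  # one telomeric end only: refuse
  gBad <- list(members = 2:4, scaffolds = sg5$scaffolds[2:4],
               telomericEnds = 0)
  expect_error(enumerateLayouts(gBad, sg5$genome), "telomeric")
  gBig <- list(members = 1:5, scaffolds = sg5$scaffolds, telomericEnds = 2)
  expect_error(enumerateLayouts(gBig, sg5$genome, maxComponents = 4L),
               "limited")
})

test_that("tile subscore equals the dense double-loop oracle", {
  set.seed(83)
  for (k in 1:60) {
    n <- sample(6:16, 1)
    m <- matrix(runif(n * n, 0, 10), n)
    m <- m + t(m)
    s1 <- sample(1:(n - 1), 1); e1 <- sample(s1:n, 1)
    s2 <- sample(1:(n - 1), 1); e2 <- sample(s2:n, 1)
    w <- sample(1:6, 1)
    expect_equal(tileSubscore(m, s1, e1, s2, e2, w),
                 bruteSubscore(m, s1, e1, s2, e2, w), tolerance = 1e-9)
  }
  mz <- matrix(0, 8, 8)
  expect_equal(tileSubscore(mz, 1, 8, 1, 8), 0)
  # diagonal band: |i - j| weight kills same-bin signal
  md <- diag(5, 8)
  expect_equal(tileSubscore(md, 1, 4, 1, 4), 0)
  expect_error(tileSubscore(mz, 0, 4, 1, 4), "out of range")
})

test_that("layout score is invariant under whole-layout reversal", {
  set.seed(84)
  sg <- simulateScaffoldGroup(nScaffolds = 4, seed = 84)
  ly <- sg$truth$layouts[[1]]
  rev <- ly
  rev$fragments <- rev$fragments[rev(seq_len(nrow(rev$fragments))), ]
  rev$fragments$orientation <- ifelse(rev$fragments$orientation ==
                                        "forward", "inverted", "forward")
  expect_equal(layoutScore(sg$matrix, ly), layoutScore(sg$matrix, rev),
               tolerance = 1e-9)
  # single-fragment layout scores zero (no pairs)
  single <- sg$scaffolds[[1]]
  expect_equal(layoutScore(sg$matrix, single), 0)
})

test_that("identity order of a pure decay matrix scores lowest", {
  set.seed(85)
  tr <- simulateRearrangement(simConfig(
    chroms = data.frame(name = "chrA", length = 5e6),
    mode = "chromothripsis", ctChroms = 1L, ctBreakpoints = 0L,
    hicDepth = 20), seed = 85)
  hic <- emitHic(tr)   # wild-type decay only
  frags <- data.frame(fragment = paste0("f", 1:4), chrom = "chrA",
                      start = (0:3) * 1.25e6, end = (1:4) * 1.25e6,
                      orientation = "forward")
  identity <- list(name = "id", fragments = frags)
  sId <- layoutScore(hic, identity)
  perm <- identity
  perm$fragments <- frags[c(1, 3, 2, 4), ]
  expect_lt(sId, layoutScore(hic, perm))
  inv <- identity
  inv$fragments$orientation[2] <- "inverted"
  expect_lt(sId, layoutScore(hic, inv))
})

test_that("argmin selection returns the planted arrangement, ties reported", {
  sg <- simulateScaffoldGroup(nScaffolds = 5, seed = 86)
  grp <- list(members = 1:5, scaffolds = sg$scaffolds, telomericEnds = 2)
  cand <- enumerateLayouts(grp, sg$genome)
  # score the control-subtracted map: the wild-type half of the raw
  # overlay rewards the reference order instead of the rearranged one
  sel <- selectBest(cand, subtractControl(sg$matrix, sg$control))
  expect_equal(layoutKey(sel$best), layoutKey(sg$truth$layouts[[1]]))
  expect_false(sel$tied)
  expect_equal(nrow(sel$table), 48L)
  expect_equal(sel$table$score, sort(sel$table$score))
  # all-zero matrix: every candidate ties, first canonical returned
  zero <- ContactMatrix(chromTable(sg$matrix)[, c("name", "length")],
                        binSize(sg$matrix))
  expect_message(selZ <- selectBest(cand, zero), "tied")
  expect_true(selZ$tied)
})
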