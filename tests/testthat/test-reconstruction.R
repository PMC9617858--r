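test_that("breakpoint snapping groups by single linkage to the leftmost", {
  g <- tinyGenome(c(chrA = 1e5, chrB = 1e5))
  adj <- newAdjacencies(rbind(
    adjDf("chrA", 1000, "tail", "chrB", 5000, "head"),
    adjDf("chrA", 1030, "head", "chrB", 9000, "head")), g)
  sb <- simplifyBreakpoints(adj)
  expect_equal(sort(sb$breakpoints$pos[sb$breakpoints$chrom == "chrA"]),
               1000)
  expect_equal(sb$adjacencies$pos1, c(1000, 1000))
  # distance >= 50 bp stays put
  adj2 <- newAdjacencies(rbind(
    adjDf("chrA", 1000, "tail", "chrB", 5000, "head"),
    adjDf("chrA", 1060, "head", "chrB", 9000, "head")), g)
  sb2 <- simplifyBreakpoints(adj2)
  expect_setequal(sb2$breakpoints$pos[sb2$breakpoints$chrom == "chrA"],
                  c(1000, 1060))
  # chain 1000, 1040, 1080 merges transitively
  adj3 <- newAdjacencies(rbind(
    adjDf("chrA", 1000, "tail", "chrB", 5000, "head"),
    adjDf("chrA", 1040, "head", "chrB", 9000, "head"),
    adjDf("chrA", 1080, "tail", "chrB", 20000, "head")), g)
  sb3 <- simplifyBreakpoints(adj3)
  expect_equal(sb3$breakpoints$pos[sb3$breakpoints$chrom == "chrA"], 1000)
})

test_that("fragments tile chromosomes with telomere flags", {
  g <- tinyGenome(c(chrA = 10000))
  fr <- makeFragments(g, data.frame(chrom = "chrA", pos = c(3000, 7000)))
  expect_equal(fr$start, c(0, 3000, 7000))
  expect_equal(fr$end, c(3000, 7000, 10000))
  expect_equal(fr$tel5, c(TRUE, FALSE, FALSE))
  expect_equal(fr$tel3, c(FALSE, FALSE, TRUE))
  fr0 <- makeFragments(g, data.frame(chrom = character(), pos = numeric()))
  expect_equal(nrow(fr0), 1L)
  expect_true(fr0$tel5 && fr0$tel3)
  expect_warning(frD <- makeFragments(g, data.frame(chrom = "chrA",
                                                    pos = c(0, 3000))),
                 "degenerate")
  expect_equal(nrow(frD), 2L)
})

test_that("graph construction maps breakend sides to fragment nodes", {
  g <- tinyGenome(c(chrA = 10000, chrB = 10000))
  adj <- newAdjacencies(adjDf("chrA", 3000, "tail", "chrB", 5000, "head"),
                        g)
  fr <- makeFragments(g, data.frame(chrom = c("chrA", "chrB"),
                                    pos = c(3000, 5000)))
  gr <- buildGraph(fr, adj)
  expect_equal(gr$edges$node1, "chrA:0-3000.3p")
  expect_equal(gr$edges$node2, "chrB:5000-10000.5p")
  expect_equal(nrow(gr$conflicts), 0L)
  # two adjacencies on one node -> conflict report with both ids
  adj2 <- newAdjacencies(rbind(
    adjDf("chrA", 3000, "tail", "chrB", 5000, "head", id = "x1"),
    adjDf("chrA", 3000, "tail", "chrB", 5000, "tail", id = "x2")), g)
  gr2 <- buildGraph(fr, adj2)
  expect_equal(gr2$conflicts$node, "chrA:0-3000.3p")
  expect_match(gr2$conflicts$adjIds, "x1,x2")
  # breakend at a telomeric side has no node
  adjT <- newAdjacencies(adjDf("chrA", 0, "head", "chrB", 5000, "head"), g)
  expect_error(buildGraph(fr, adjT), "telomeric")
  # breakend matching no boundary
  adjX <- newAdjacencies(adjDf("chrA", 4444, "tail", "chrB", 5000, "head"),
                         g)
  expect_error(buildGraph(fr, adjX), "4444")
})

test_that("conflicts resolve by technology, strand concordance, Hi-C, override", {
  g <- tinyGenome(c(chrA = 10000, chrB = 10000, chrC = 10000))
  fr <- makeFragments(g, data.frame(chrom = c("chrA", "chrB", "chrC"),
                                    pos = c(3000, 5000, 4000)))
  adj <- newAdjacencies(rbind(
    adjDf("chrA", 3000, "tail", "chrB", 5000, "head", id = "both"),
    adjDf("chrA", 3000, "tail", "chrC", 4000, "head", id = "single")), g)
  gr <- buildGraph(fr, adj)
  ev <- data.frame(adjId = c("both", "single"),
                   bothTech = c(TRUE, FALSE),
                   strandConcordant = TRUE, hicScore = c(1, 99))
  res <- resolveConflicts(gr, ev)
  expect_equal(res$edges$adjId, "both")
  expect_equal(res$removed$adjId, "single")
  # equal technology: higher Hi-C score wins
  ev2 <- data.frame(adjId = c("both", "single"), bothTech = TRUE,
                    strandConcordant = TRUE, hicScore = c(1.2, 5.1))
  expect_equal(resolveConflicts(gr, ev2)$edges$adjId, "single")
  # pinned override beats the key
  ov <- c("chrA:0-3000.3p" = "both")
  expect_equal(resolveConflicts(gr, ev2, overrides = ov)$edges$adjId,
               "both")
  # exact tie demands an override
  evT <- data.frame(adjId = c("both", "both"), bothTech = TRUE,
                    strandConcordant = TRUE, hicScore = 1)
  grT <- gr
  grT$edges$adjId <- c("both", "both")
  expect_error(resolveConflicts(grT, evT), "tie")
})

test_that("traversal yields layouts with the documented orientation rule", {
  g <- tinyGenome(c(chrA = 10000))
  # WT: no adjacencies
  fr <- makeFragments(g, data.frame(chrom = character(), pos = numeric()))
  tv <- traverseGraph(buildGraph(fr, newAdjacencies(
    adjDf(character(0), numeric(0), character(0), character(0),
          numeric(0), character(0)))))
  expect_length(tv$layouts, 1L)
  expect_equal(tv$layouts[[1]]$completeness, "complete")
  expect_equal(tv$layouts[[1]]$fragments$orientation, "forward")
  # A[0,b).3p -- C[c,L).5p with B singleton
  fr2 <- makeFragments(g, data.frame(chrom = "chrA", pos = c(3000, 7000)))
  adj <- newAdjacencies(adjDf("chrA", 3000, "tail", "chrA", 7000, "head"),
                        g)
  tv2 <- traverseGraph(buildGraph(fr2, adj))
  expect_length(tv2$layouts, 1L)
  expect_equal(tv2$layouts[[1]]$fragments$fragment,
               c("chrA:0-3000", "chrA:7000-10000"))
  expect_equal(tv2$layouts[[1]]$fragments$orientation,
               c("forward", "forward"))
  expect_equal(tv2$layouts[[1]]$completeness, "complete")
  expect_equal(tv2$singletons$id, "chrA:3000-7000")
  # edge into the partner's 3p node: the partner enters inverted
  g2 <- tinyGenome(c(chrA = 10000, chrB = 10000))
  fr3 <- makeFragments(g2, data.frame(chrom = c("chrA", "chrB"),
                                      pos = c(3000, 5000)))
  adj3 <- newAdjacencies(adjDf("chrA", 3000, "tail", "chrB", 5000, "tail",
                               id = "inv"), g2)
  tv3 <- traverseGraph(buildGraph(fr3, adj3))
  ly <- tv3$layouts[[1]]
  expect_equal(ly$fragments$fragment, c("chrA:0-3000", "chrB:0-5000"))
  expect_equal(ly$fragments$orientation, c("forward", "inverted"))
  expect_equal(ly$completeness, "complete")  # both outer ends telomeric
})

test_that("traversal is independent of fragment input order", {
  set.seed(41)
  tr <- simulateRearrangement(simConfig(mode = "chromothripsis"), seed = 41)
  sb <- simplifyBreakpoints(tr$adjacencies)
  fr <- makeFragments(tr$genome, sb$breakpoints)
  tv1 <- traverseGraph(buildGraph(fr, sb$adjacencies))
  frShuf <- fr[sample(nrow(fr)), ]
  tv2 <- traverseGraph(buildGraph(frShuf, sb$adjacencies))
  expect_equal(vapply(tv1$layouts, layoutKey, ""),
               vapply(tv2$layouts, layoutKey, ""))
  expect_equal(tv1$singletons$id, tv2$singletons$id)
})

test_that("length is conserved across layouts and singletons", {
  for (s in 42:44) {
    tr <- simulateRearrangement(simConfig(
      mode = if (s %% 2) "chromothripsis" else "chromoplexy"), seed = s)
    sb <- simplifyBreakpoints(tr$adjacencies)
    tv <- traverseGraph(buildGraph(makeFragments(tr$genome,
                                                 sb$breakpoints),
                                   sb$adjacencies))
    tot <- sum(vapply(tv$layouts, function(l)
      sum(l$fragments$end - l$fragments$start), 0)) +
      sum(tv$singletons$end - tv$singletons$start)
    expect_equal(tot, sum(chromLengths(tr$genome)))
  }
})

test_that("withdrawing an internal fragment's junctions splits a layout", {
  g <- tinyGenome(c(chrA = 100000))
  bp <- data.frame(chrom = "chrA", pos = c(2e4, 4e4, 6e4, 8e4))
  fr <- makeFragments(g, bp)
  # derivative F1+, F3+, F2+, F4-, F5+ expressed as four junctions
  adj <- newAdjacencies(rbind(
    adjDf("chrA", 2e4, "tail", "chrA", 4e4, "head", id = "j1"),
    adjDf("chrA", 6e4, "tail", "chrA", 2e4, "head", id = "j2"),
    adjDf("chrA", 4e4, "tail", "chrA", 8e4, "tail", id = "j3"),
    adjDf("chrA", 6e4, "head", "chrA", 8e4, "head", id = "j4")), g)
  tvFull <- traverseGraph(buildGraph(fr, adj))
  expect_length(tvFull$layouts, 1L)
  expect_equal(nrow(tvFull$layouts[[1]]$fragments), 5L)
  expect_equal(tvFull$layouts[[1]]$completeness, "complete")
  # remove both junctions of the middle fragment F2 [2e4,4e4): j2 and j3
  tvCut <- traverseGraph(buildGraph(fr, adj[!(adj$id %in% c("j2", "j3")), ]))
  expect_length(tvCut$layouts, 2L)
  expect_setequal(vapply(tvCut$layouts, function(l) l$completeness, ""),
                  c("scaffold", "scaffold"))
  expect_equal(tvCut$singletons$id, "chrA:20000-40000")
})

test_that("singleton classification thresholds behave as documented", {
  sing <- data.frame(id = c("a", "b", "c", "d"))
  cls <- classifySingletons(sing, c(0.5, 1.0, 0.7, NA))
  expect_equal(cls, c("deleted", "retained_unplaced", "ambiguous",
                      "ambiguous"))
})

test_that("custom genome emission concatenates and reverse-complements", {
  set.seed(45)
  refs <- Biostrings::DNAStringSet(c(chrA = randSeq(1000),
                                     chrB = randSeq(1000)))
  ly <- list(name = "der1", fragments = data.frame(
    fragment = c("a", "b"), chrom = c("chrA", "chrB"),
    start = c(0, 600), end = c(400, 1000),
    orientation = c("forward", "inverted")), completeness = "complete")
  cg <- emitCustomGenome(refs, list(ly))
  expected <- paste0(
    as.character(Biostrings::subseq(refs[["chrA"]], 1, 400)),
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(refs[["chrB"]], 601, 1000))))
  expect_equal(as.character(cg$seqs[["der1"]]), expected)
  expect_equal(cg$junctions$pos, 400)  # prefix sum of fragment lengths
  lyBad <- ly; lyBad$fragments$end[2] <- 2000
  expect_error(emitCustomGenome(refs, list(lyBad)), "beyond")
})

test_that("junction support counts only contiguous spanning alignments", {
  junctions <- data.frame(derivative = "der1", junction = 1L, pos = 500)
  aln <- data.frame(
    id = c("spans", "endsShort", "split"),
    chrom = "der1",
    start = c(350, 200, 300),
    end = c(650, 490, 500),   # split read's first alignment stops at 500
    mapq = 60, flag = 0L)
  js <- junctionSupport(aln, junctions, window = 100)
  expect_equal(js$nSpanning, 1)
  # the same via a SAM file round trip (split read = two records)
  reads <- data.frame(id = c("spans", "endsShort", "split", "split"),
                      chrom = "der1", pos = c(350, 200, 300, 500),
                      mapq = 60,
                      cigar = c("300M", "290M", "200M200S", "200S200M"),
                      seq = c(strrep("A", 300), strrep("A", 290),
                              strrep("A", 400), strrep("A", 400)))
  f <- tempfile(fileext = ".sam")
  writeSam(reads, c(der1 = 2000), f)
  js2 <- junctionSupport(readSamAlignments(f), junctions, window = 100)
  expect_equal(js2$nSpanning, 1)
})
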