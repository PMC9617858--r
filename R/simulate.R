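#' Simulation configuration
#'
#' Defaults describe the desk-scale study conditions the package is tested
#' under: a five-chromosome 50 Mb genome with assembly gaps, segmental
#' duplications and high-coverage regions; a heterozygous rearrangement
#' (chromoplexy: few balanced inter-chromosomal exchanges; chromothripsis:
#' clustered shattering with fragment loss and random rejoining); Hi-C as a
#' 50/50 overlay of the wild-type and rearranged alleles with power-law
#' distance decay; junction-local sequence context with plantable
#' microhomology, untemplated insertion and reciprocal-offset InDels.
#' Breakpoints are placed on Hi-C bin boundaries (downstream map work
#' operates at bin resolution; base-pair uncertainty is modeled separately
#' as caller jitter).
#'
#' @param ... overrides of any default field
#' @return a \code{SimConfig} list
#' @export
simConfig <- function(...) {
  cfg <- list(
    chroms = data.frame(name = c("chrA", "chrB", "chrC", "chrD", "chrE"),
                        length = rep(1e7, 5)),
    mode = "chromothripsis",
    # rearrangement
    cpChroms = 5L,             # chromoplexy: chromosomes in the exchange cycle
    ctChroms = 2L,             # chromothripsis: shattered chromosomes
    ctBreakpoints = 24L,       # total breakpoints across shatter regions
    deletionProb = 0.2,        # per internal fragment (chromothripsis)
    shatterFrac = 0.35,        # fraction of the chromosome shattered
    minSpacing = 100000,       # minimum breakpoint spacing (bp)
    endMargin = 200000,        # keep-out from chromosome ends (bp)
    # reference annotation (per chromosome)
    gapLength = 1e5, segdupLength = 5e4,
    # caller noise
    jitterSd = 10, fnRate = 0, fpPerClass = 10L,
    preciseRate = 0.7,
    meanCoverage = 30, windowSize = 10000, highCovValue = 150,
    # Hi-C
    binSize = 25000, hicDepth = 10, alpha = 1.0,
    wtFraction = 0.5, transLevel = 0.02,
    # junctions
    homologyRange = 0:10, indelRange = -20:20, insertionRange = 0L,
    junctionDepth = 8L, errorRate = 0,
    alignLen = 60L, clipLen = 60L,
    # expression / phasing
    nGenes = 200L, aigNear = 0.5, aigBg = 0.05, nearDist = 1e5,
    aigLfc = 1.5, exprMean = 30, nReplicates = 3L,
    ladFraction = 0.4,
    nPhaseSets = 200L, readsPerSet = 30L, hapNoise = 0,
    cgrHaplotype = "H2")
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# deterministic annotation layout: one gap, one segdup and one
# high-coverage window per chromosome
.simAnnotation <- function(cfg) {
  ch <- cfg$chroms
  mk <- function(fracStart, len) {
    do.call(rbind, lapply(seq_len(nrow(ch)), function(k)
      data.frame(chrom = ch$name[k],
                 start = round(ch$length[k] * fracStart),
                 end = round(ch$length[k] * fracStart) + len)))
  }
  list(gaps = mk(0.40, cfg$gapLength),
       segdups = mk(0.70, cfg$segdupLength),
       highCov = mk(0.85, cfg$windowSize))
}

# sample breakpoints on bin boundaries avoiding filter-trigger zones;
# an optional region confines them (chromothripsis shatter region)
.sampleBreakpoints <- function(cfg, ann, chrom, n, region = NULL) {
  L <- cfg$chroms$length[cfg$chroms$name == chrom]
  bins <- seq(cfg$binSize, L - cfg$binSize, by = cfg$binSize)
  if (!is.null(region))
    bins <- bins[bins >= region[1] & bins < region[2]]
  bad <- rep(FALSE, length(bins))
  forbid <- function(tab, margin) {
    t <- tab[tab$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(t)))
      bad[bins >= t$start[k] - margin & bins < t$end[k] + margin] <<- TRUE
  }
  forbid(ann$gaps, 20000 + cfg$binSize)
  forbid(ann$segdups, 5000 + cfg$binSize)
  forbid(ann$highCov, 5000 + cfg$binSize)
  bad[bins < cfg$endMargin | bins > L - cfg$endMargin] <- TRUE
  cand <- bins[!bad]
  picked <- numeric(0)
  while (length(picked) < n && length(cand)) {
    p <- cand[sample.int(length(cand), 1L)]
    picked <- c(picked, p)
    cand <- cand[abs(cand - p) >= cfg$minSpacing]
  }
  if (length(picked) < n)
    stop("cannot place ", n, " breakpoints on ", chrom,
         " under the spacing constraints")
  sort(picked)
}

# adjacency joining two oriented fragments at a junction
.junctionAdjacency <- function(f1, o1, f2, o2) {
  b1 <- if (o1 == "forward") list(pos = f1$end, side = "tail")
        else list(pos = f1$start, side = "head")
  b2 <- if (o2 == "forward") list(pos = f2$start, side = "head")
        else list(pos = f2$end, side = "tail")
  data.frame(chrom1 = f1$chrom, pos1 = b1$pos, side1 = b1$side,
             chrom2 = f2$chrom, pos2 = b2$pos, side2 = b2$side)
}

# TRUE when two consecutive oriented fragments are plain reference
# continuation (no junction exists there)
.isReferenceContinuation <- function(f1, o1, f2, o2) {
  (f1$chrom == f2$chrom) &&
    ((o1 == "forward" && o2 == "forward" && f1$end == f2$start) ||
       (o1 == "inverted" && o2 == "inverted" && f2$end == f1$start))
}

#' Simulate a complex germline rearrangement
#'
#' Chromoplexy mode builds a cyclic balanced exchange among
#' \code{cpChroms} chromosomes (one breakpoint each, head of one joined to
#' the tail of the next, no loss). Chromothripsis mode shatters
#' \code{ctChroms} chromosomes with clustered breakpoints, deletes internal
#' fragments with probability \code{deletionProb}, and rejoins the
#' remainder in random order and orientation, exchanging material between
#' the shattered chromosomes; telomeric fragments stay at the derivative
#' ends.
#'
#' @param cfg \code{\link{simConfig}} list
#' @param seed optional RNG seed
#' @return ground-truth list: \code{genome}, \code{annotation},
#'   \code{fragments}, \code{layouts}, \code{deleted} (fragment ids),
#'   \code{adjacencies} (the true novel-adjacency set), \code{breakpoints},
#'   \code{config}
#' @export
simulateRearrangement <- function(cfg = simConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ann <- .simAnnotation(cfg)
  genome <- GenomeModel(cfg$chroms, gaps = ann$gaps, segdups = ann$segdups)
  if (cfg$mode == "chromoplexy") {
    k <- min(cfg$cpChroms, nrow(cfg$chroms))
    use <- cfg$chroms$name[seq_len(k)]
    bps <- do.call(rbind, lapply(use, function(ch)
      data.frame(chrom = ch, pos = .sampleBreakpoints(cfg, ann, ch, 1L))))
    frags <- makeFragments(genome, bps)
    assign <- lapply(seq_len(k), function(i) {
      j <- if (i == k) 1L else i + 1L
      headFrag <- frags[frags$chrom == use[i] & frags$tel5, , drop = FALSE]
      tailFrag <- frags[frags$chrom == use[j] & frags$tel3, , drop = FALSE]
      data.frame(fragment = c(headFrag$id, tailFrag$id),
                 orientation = "forward")
    })
    deleted <- character(0)
    bpAll <- bps
  } else {
    use <- cfg$chroms$name[seq_len(min(cfg$ctChroms, nrow(cfg$chroms)))]
    per <- ceiling(cfg$ctBreakpoints / length(use))
    if (per == 0L) use <- character(0)   # no shattering: wild-type truth
    bpAll <- do.call(rbind, lapply(use, function(ch) {
      L <- cfg$chroms$length[cfg$chroms$name == ch]
      span <- max(cfg$shatterFrac * L, per * cfg$minSpacing * 1.5)
      lo <- cfg$endMargin +
        stats::runif(1) * max(0, L - 2 * cfg$endMargin - span)
      data.frame(chrom = ch,
                 pos = .sampleBreakpoints(cfg, ann, ch, per,
                                          region = c(lo, lo + span)))
    }))
    if (is.null(bpAll))
      bpAll <- data.frame(chrom = character(), pos = numeric())
    frags <- makeFragments(genome, bpAll)
    firstIds <- vapply(use, function(ch)
      frags$id[frags$chrom == ch & frags$tel5], character(1))
    lastIds <- vapply(use, function(ch)
      frags$id[frags$chrom == ch & frags$tel3], character(1))
    midIds <- frags$id[frags$chrom %in% use &
                         !(frags$id %in% c(firstIds, lastIds))]
    del <- stats::runif(length(midIds)) < cfg$deletionProb
    deleted <- midIds[del]
    keep <- midIds[!del]
    assign <- list()
    ok <- TRUE
    for (try in seq_len(if (length(use)) 200L else 0L)) {
      ordKeep <- sample(keep)
      orient <- sample(c("forward", "inverted"), length(keep),
                       replace = TRUE)
      cut <- sort(sample(0:length(keep), length(use) - 1L, replace = TRUE))
      groups <- split(seq_along(ordKeep),
                      findInterval(seq_along(ordKeep), cut + 0.5) + 1L)
      assign <- lapply(seq_along(use), function(i) {
        mid <- groups[[as.character(i)]]
        rows <- data.frame(fragment = firstIds[i], orientation = "forward")
        if (!is.null(mid) && length(mid))
          rows <- rbind(rows, data.frame(fragment = ordKeep[mid],
                                         orientation = orient[mid]))
        rbind(rows, data.frame(fragment = lastIds[i],
                               orientation = "forward"))
      })
      ok <- TRUE
      for (a in assign) for (t in seq_len(nrow(a) - 1L)) {
        f1 <- frags[frags$id == a$fragment[t], ]
        f2 <- frags[frags$id == a$fragment[t + 1L], ]
        if (.isReferenceContinuation(f1, a$orientation[t], f2,
                                     a$orientation[t + 1L])) ok <- FALSE
      }
      if (ok) break
    }
    if (!ok) stop("failed to draw a junction-consistent rejoining")
  }
  layouts <- lapply(seq_along(assign), function(i) {
    f <- assign[[i]]
    m <- match(f$fragment, frags$id)
    f$chrom <- frags$chrom[m]; f$start <- frags$start[m]
    f$end <- frags$end[m]
    canonicalizeLayout(list(name = paste0("der", i), fragments = f,
                            completeness = "complete",
                            sourceAdjacencies = character(0)))
  })
  adjRows <- list()
  for (ly in layouts) {
    f <- ly$fragments
    for (t in seq_len(max(0L, nrow(f) - 1L))) {
      f1 <- frags[frags$id == f$fragment[t], ]
      f2 <- frags[frags$id == f$fragment[t + 1L], ]
      adjRows[[length(adjRows) + 1L]] <-
        .junctionAdjacency(f1, f$orientation[t], f2, f$orientation[t + 1L])
    }
  }
  adjacencies <- if (length(adjRows))
    newAdjacencies(do.call(rbind, adjRows), genome)
  else newAdjacencies(data.frame(chrom1 = character(), pos1 = numeric(),
                                 side1 = character(), chrom2 = character(),
                                 pos2 = numeric(), side2 = character()))
  adjacencies$support <- rep(round(cfg$meanCoverage / 2), nrow(adjacencies))
  adjacencies$curated <- rep(TRUE, nrow(adjacencies))
  list(genome = genome, annotation = ann, fragments = frags,
       layouts = layouts, deleted = deleted, adjacencies = adjacencies,
       breakpoints = bpAll, config = cfg)
}

# clean random trans adjacency avoiding filter-trigger zones
.randomCleanAdjacency <- function(cfg, ann, chromPair = NULL) {
  ch <- if (is.null(chromPair))
    sample(cfg$chroms$name, 2L) else chromPair
  p1 <- .sampleBreakpoints(cfg, ann, ch[1], 1L) +
    sample.int(1000L, 1L)
  p2 <- .sampleBreakpoints(cfg, ann, ch[2], 1L) +
    sample.int(1000L, 1L)
  data.frame(chrom1 = ch[1], pos1 = p1, side1 = sample(c("tail", "head"), 1),
             chrom2 = ch[2], pos2 = p2, side2 = sample(c("tail", "head"), 1))
}

#' Emit noisy caller output and a decoy cohort sample
#'
#' True adjacencies receive Gaussian positional jitter per caller and are
#' dropped at the configured false-negative rate. The long-read call set
#' additionally carries \code{fpPerClass} planted false positives of every
#' filterable class: low read support, breakends in high-coverage windows,
#' near assembly gaps, inside segmental duplications, and calls shared with
#' a decoy second sample. Short-read calls carry precision flags; precise
#' calls are emitted without jitter (base-exact breakends).
#'
#' @param truth result of \code{\link{simulateRearrangement}}
#' @param seed optional RNG seed
#' @return list: \code{long}, \code{short}, \code{decoy} (adjacency
#'   data.frames; planted FPs carry a \code{planted} column), and
#'   \code{coverage} (\linkS4class{CoverageTrack})
#' @export
emitCalls <- function(truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$config
  ann <- truth$annotation
  genome <- truth$genome
  jit <- function(df, sd) {
    if (nrow(df) == 0L || sd <= 0) return(df)
    df$pos1 <- pmax(0, round(df$pos1 + stats::rnorm(nrow(df), 0, sd)))
    df$pos2 <- pmax(0, round(df$pos2 + stats::rnorm(nrow(df), 0, sd)))
    df
  }
  true <- truth$adjacencies
  keepL <- stats::runif(nrow(true)) >= cfg$fnRate
  keepS <- stats::runif(nrow(true)) >= cfg$fnRate
  long <- jit(true[keepL, , drop = FALSE], cfg$jitterSd)
  long$caller <- "longread"
  long$support <- pmax(3, round(stats::rnorm(nrow(long),
                                             cfg$meanCoverage / 2, 2)))
  long$planted <- "true"
  short <- true[keepS, , drop = FALSE]
  short$caller <- "shortread"
  short$support <- NA_real_
  short$precise <- stats::runif(nrow(short)) < cfg$preciseRate
  impr <- !short$precise
  short[impr, ] <- jit(short[impr, , drop = FALSE], cfg$jitterSd * 3)
  short$planted <- "true"

  mkFp <- function(class, n, place) {
    if (n == 0L) return(NULL)
    rows <- lapply(seq_len(n), function(k) {
      a <- place(k)
      a$support <- pmax(3, round(stats::rnorm(1, cfg$meanCoverage / 2, 2)))
      a$planted <- class
      a
    })
    do.call(rbind, rows)
  }
  fp <- list()
  fp$low <- mkFp("fp_low_support", cfg$fpPerClass, function(k)
    .randomCleanAdjacency(cfg, ann))
  if (!is.null(fp$low)) fp$low$supportOverride <- 1
  fp$high <- mkFp("fp_high_coverage", cfg$fpPerClass, function(k) {
    a <- .randomCleanAdjacency(cfg, ann)
    hc <- ann$highCov[sample.int(nrow(ann$highCov), 1L), ]
    a$chrom1 <- hc$chrom
    a$pos1 <- hc$start + round(cfg$windowSize / 2)
    a
  })
  fp$gap <- mkFp("fp_near_gap", cfg$fpPerClass, function(k) {
    a <- .randomCleanAdjacency(cfg, ann)
    g <- ann$gaps[sample.int(nrow(ann$gaps), 1L), ]
    a$chrom1 <- g$chrom
    a$pos1 <- g$end + sample.int(5000L, 1L)
    a
  })
  fp$segdup <- mkFp("fp_segdup", cfg$fpPerClass, function(k) {
    a <- .randomCleanAdjacency(cfg, ann)
    s <- ann$segdups[sample.int(nrow(ann$segdups), 1L), ]
    a$chrom1 <- s$chrom
    a$pos1 <- s$start + round(cfg$segdupLength / 2)
    a
  })
  fp$cohort <- mkFp("fp_cohort", cfg$fpPerClass, function(k)
    .randomCleanAdjacency(cfg, ann))

  fp <- Filter(Negate(is.null), fp)
  fpAll <- do.call(rbind, lapply(fp, function(d) {
    d$caller <- "longread"
    if (!is.null(d$supportOverride)) {
      d$support <- d$supportOverride
      d$supportOverride <- NULL
    }
    d
  }))
  cols <- c("chrom1", "pos1", "side1", "chrom2", "pos2", "side2",
            "caller", "support", "planted")
  long <- long[, cols]
  if (!is.null(fpAll)) long <- rbind(long, fpAll[, cols])
  long <- newAdjacencies(long, genome)
  decoy <- fp$cohort
  if (is.null(decoy)) {
    decoy <- long[0, ]
  } else {
    decoy$pos1 <- decoy$pos1 + round(stats::rnorm(nrow(decoy), 0, cfg$jitterSd))
    decoy$pos2 <- decoy$pos2 + round(stats::rnorm(nrow(decoy), 0, cfg$jitterSd))
    decoy$caller <- "longread"
    decoy <- newAdjacencies(decoy[, cols], genome)
  }
  short <- newAdjacencies(short, genome)

  # coverage track: baseline around the genome mean, designated
  # high-coverage windows, and halved coverage over deleted fragments
  win <- list()
  for (k in seq_len(nrow(cfg$chroms))) {
    st <- seq(0, cfg$chroms$length[k] - 1, by = cfg$windowSize)
    win[[k]] <- data.frame(chrom = cfg$chroms$name[k], start = st,
                           end = pmin(st + cfg$windowSize,
                                      cfg$chroms$length[k]))
  }
  win <- do.call(rbind, win)
  win$coverage <- pmax(1, stats::rnorm(nrow(win), cfg$meanCoverage, 1.5))
  for (k in seq_len(nrow(ann$highCov))) {
    hc <- ann$highCov[k, ]
    sel <- win$chrom == hc$chrom & win$start >= hc$start & win$end <= hc$end
    win$coverage[sel] <- cfg$highCovValue
  }
  for (fid in truth$deleted) {
    f <- truth$fragments[truth$fragments$id == fid, ]
    sel <- win$chrom == f$chrom & win$start >= f$start & win$end <= f$end
    win$coverage[sel] <- win$coverage[sel] / 2
  }
  coverage <- CoverageTrack(win, windowSize = cfg$windowSize,
                            genomeMean = cfg$meanCoverage)
  list(long = long, short = short, decoy = decoy, coverage = coverage)
}

#' Simulate the two-allele Hi-C contact map
#'
#' The expected map is a 50/50 (configurable) overlay of a wild-type allele
#' and the rearranged allele: cis contacts decay as (1 + d)^-alpha in bin
#' distance d along each allele's own chromosome arrangement, trans
#' contacts sit at a small constant, and deleted fragments contribute
#' nothing from the rearranged allele. Counts are Poisson-sampled at the
#' configured depth in reference coordinates.
#'
#' @param truth result of \code{\link{simulateRearrangement}}
#' @param seed optional RNG seed
#' @return \code{ContactMatrix}
#' @export
emitHic <- function(truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$config
  cm0 <- ContactMatrix(cfg$chroms, cfg$binSize)
  tab <- chromTable(cm0)
  n <- sum(tab$nbins)
  chromId <- rep(seq_len(nrow(tab)), tab$nbins)
  # derivative coordinates of every reference bin (NA = deleted / WT-only)
  derId <- rep(NA_integer_, n)
  derPos <- rep(NA_real_, n)
  for (di in seq_along(truth$layouts)) {
    br <- layoutBinRanges(cm0, truth$layouts[[di]])
    for (r in seq_len(nrow(br))) {
      ref <- (br$refStartBin[r] + 1L):br$refEndBin[r]
      out <- br$startBin[r]:(br$endBin[r] - 1L)
      if (br$orientation[r] == "inverted") out <- rev(out)
      derId[ref] <- di
      derPos[ref] <- out
    }
  }
  rearranged <- unique(unlist(lapply(truth$layouts, function(ly)
    unique(ly$fragments$chrom))))
  wtOnly <- which(!(tab$name[chromId] %in% rearranged))
  derId[wtOnly] <- -chromId[wtOnly]   # untouched chroms: identity layout
  derPos[wtOnly] <- seq_len(n)[wtOnly]
  base <- function(sameGroup, dist) {
    ifelse(sameGroup, (1 + dist)^(-cfg$alpha), cfg$transLevel)
  }
  gpos <- seq_len(n) - 1L
  sameWt <- outer(chromId, chromId, "==")
  dWt <- abs(outer(gpos, gpos, "-"))
  lamWt <- base(sameWt, dWt)
  sameDer <- outer(derId, derId, function(a, b) !is.na(a) & !is.na(b) & a == b)
  bothDer <- outer(!is.na(derId), !is.na(derId), "&")
  dDer <- abs(outer(derPos, derPos, "-"))
  dDer[is.na(dDer)] <- 0
  lamDer <- ifelse(bothDer, base(sameDer, dDer), 0)
  lam <- cfg$hicDepth * (cfg$wtFraction * lamWt +
                           (1 - cfg$wtFraction) * lamDer)
  ut <- which(upper.tri(lam, diag = TRUE), arr.ind = TRUE)
  counts <- stats::rpois(nrow(ut), lam[ut])
  keep <- counts > 0
  ContactMatrix(cfg$chroms, cfg$binSize,
                entries = data.frame(i = ut[keep, 1] - 1L,
                                     j = ut[keep, 2] - 1L,
                                     count = counts[keep]))
}

.randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate <- function(s, rate) {
  if (rate <= 0 || !nzchar(s)) return(s)
  v <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

# reads for one junction with planted homology h, untemplated insertion u
# and reciprocal-junction offset d; returns a read data.frame
.junctionReadSet <- function(a, h, u, d, cfg) {
  A <- cfg$alignLen; C <- cfg$clipLen
  W <- 400L  # local context half-window
  ins <- if (u > 0) .randSeq(u) else ""
  sA <- .randSeq(2L * W)   # reference context [pos1 - W, pos1 + W)
  sB <- .randSeq(2L * W)
  at <- function(s, lo, n) substr(s, lo + 1L, lo + n)  # 0-based local
  put <- function(s, lo, repl) {
    substr(s, lo + 1L, lo + nchar(repl)) <- repl
    s
  }
  # homology: the last h bases entering the junction on the source side
  # equal the h bases the target aligner can extend through
  if (h > 0) {
    srcH <- if (a$side1 == "tail") at(sA, W - h, h)
            else .revcomp(at(sA, W, h))
    if (a$side2 == "head") sB <- put(sB, W - h, srcH)
    else sB <- put(sB, W, .revcomp(srcH))
  }
  exitSeq <- function(n) {
    if (a$side2 == "head") at(sB, W, n) else .revcomp(at(sB, W - n, n))
  }
  approachSeq <- function(n) {   # derivative sequence entering the junction
    if (a$side1 == "tail") at(sA, W - n, n)
    else .revcomp(at(sA, W, n))
  }
  rows <- list()
  addRead <- function(id, chrom, pos, cigar, seqc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, chrom = chrom, pos = pos, mapq = 60L, cigar = cigar,
      seq = .mutate(seqc, cfg$errorRate), stringsAsFactors = FALSE)
  }
  # 1. junction-crossing reads at the source breakend
  crossClip <- paste0(ins, exitSeq(C - u))
  for (r in seq_len(cfg$junctionDepth)) {
    if (a$side1 == "tail") {
      addRead(sprintf("%s_src_%d", a$id, r), a$chrom1, a$pos1 - A,
              sprintf("%dM%dS", A, C), paste0(at(sA, W - A, A), crossClip))
    } else {
      addRead(sprintf("%s_src_%d", a$id, r), a$chrom1, a$pos1,
              sprintf("%dS%dM", C, A),
              paste0(.revcomp(crossClip), at(sA, W, A)))
    }
  }
  # 2. reciprocal-junction reads at the source locus: the other derivative
  # allele's junction at the same breakpoint, offset by the local InDel d
  recClip <- .randSeq(C)
  for (r in seq_len(cfg$junctionDepth)) {
    if (a$side1 == "tail") {
      # L group clips at pos1; R group at pos1 + d
      addRead(sprintf("%s_rec_%d", a$id, r), a$chrom1, a$pos1 + d,
              sprintf("%dS%dM", C, A),
              paste0(recClip, at(sA, W + d, A)))
    } else {
      # R group clips at pos1; L group at pos1 - d
      addRead(sprintf("%s_rec_%d", a$id, r), a$chrom1, a$pos1 - d - A,
              sprintf("%dM%dS", A, C),
              paste0(at(sA, W - d - A, A), recClip))
    }
  }
  # 3. target-side reads, clips shifted through the homology as a local
  # aligner would place them
  tgtClip <- paste0(approachSeq(C - u), ins)
  for (r in seq_len(cfg$junctionDepth)) {
    if (a$side2 == "head") {
      addRead(sprintf("%s_tgt_%d", a$id, r), a$chrom2, a$pos2 - h,
              sprintf("%dS%dM", C, A),
              paste0(tgtClip, at(sB, W - h, A)))
    } else {
      addRead(sprintf("%s_tgt_%d", a$id, r), a$chrom2, a$pos2 + h - A,
              sprintf("%dM%dS", A, C),
              paste0(at(sB, W + h - A, A), .revcomp(tgtClip)))
    }
  }
  do.call(rbind, rows)
}

#' Simulate soft-clipped junction reads
#'
#' For every adjacency a microhomology length, an untemplated insertion
#' length and a reciprocal-junction InDel offset are planted. Local
#' sequence context is generated around each breakend (junction-local only;
#' whole-genome sequence is out of scope) with the homology constraint
#' enforced between the two sides. Emitted reads: the junction-crossing
#' group clipped at the source breakend, the reciprocal-allele group offset
#' by the InDel at the same locus, and the target-side group whose clip
#' positions shift through the homology exactly as a local aligner would
#' place them. Note that when several adjacencies share a breakpoint
#' coordinate (consecutive derivative junctions), their read groups overlap
#' at that locus, as they do in real data; use
#' \code{\link{simulateJunctions}} for isolated, exactly recoverable
#' junctions.
#'
#' @param truth result of \code{\link{simulateRearrangement}}, or any list
#'   with \code{adjacencies} and \code{config}
#' @param seed optional RNG seed
#' @return list: \code{reads} (data.frame suitable for
#'   \code{\link{fetchClipped}}), \code{planted} (per-adjacency truth:
#'   \code{homology}, \code{insertion}, \code{indel}, \code{blunt})
#' @export
emitJunctionReads <- function(truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$config
  adj <- truth$adjacencies
  readRows <- list()
  planted <- list()
  for (k in seq_len(nrow(adj))) {
    a <- adj[k, ]
    h <- sample(cfg$homologyRange, 1L)
    u <- if (length(cfg$insertionRange) == 1L) cfg$insertionRange
         else sample(cfg$insertionRange, 1L)
    if (u > 0) h <- 0L  # one junction mechanism at a time
    d <- sample(cfg$indelRange, 1L)
    readRows[[k]] <- .junctionReadSet(a, h, u, d, cfg)
    planted[[k]] <- data.frame(adjacency_id = a$id, homology = h,
                               insertion = u, indel = d,
                               blunt = (h == 0L && u == 0L))
  }
  list(reads = do.call(rbind, readRows),
       planted = do.call(rbind, planted))
}

#' Simulate isolated junctions for signature analysis
#'
#' Generates \code{n} junctions at well-separated loci (every breakpoint
#' coordinate used exactly once, far beyond the clipped-read fetch window)
#' with random breakend sides, then emits planted reads via the junction
#' read model. This is the controlled setting in which the signature
#' pipeline recovers every planted (homology, insertion, InDel) exactly.
#'
#' @param n number of junctions
#' @param cfg \code{\link{simConfig}}
#' @param seed optional RNG seed
#' @return as \code{\link{emitJunctionReads}}, plus \code{adjacencies}
#' @export
simulateJunctions <- function(n = 100L, cfg = simConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spacing <- 50000
  adj <- data.frame(
    chrom1 = "chrA", pos1 = 100000 + (seq_len(n) - 1L) * spacing,
    side1 = sample(c("tail", "head"), n, replace = TRUE),
    chrom2 = "chrB", pos2 = 100000 + (seq_len(n) - 1L) * spacing,
    side2 = sample(c("tail", "head"), n, replace = TRUE),
    id = sprintf("junc%04d", seq_len(n)))
  out <- emitJunctionReads(list(adjacencies = adj, config = cfg))
  out$adjacencies <- adj
  out
}

#' Simulate feature tracks, expression and phase-set read labels
#'
#' Emits a TAD partition, alternating A/B compartments, LADs covering the
#' configured genome fraction, a sparse repeat track, genes with planted
#' allelic-imbalance effects that are frequent near breakpoints
#' (\code{aigNear} within \code{nearDist}) and rare elsewhere
#' (\code{aigBg}), per-replicate allele-specific read counts, and
#' haplotagged breakpoint-classified reads for the phase-set vote.
#'
#' @param truth result of \code{\link{simulateRearrangement}}
#' @param seed optional RNG seed
#' @return list: \code{tads}, \code{compartments}, \code{lads},
#'   \code{repeats}, \code{genes}, \code{allelicCounts}, \code{haplotags}
#' @export
emitTracksAndExpression <- function(truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$config
  ch <- cfg$chroms
  tile <- function(meanLen, labels = NULL, coverFrac = 1) {
    out <- list()
    for (k in seq_len(nrow(ch))) {
      pos <- 0
      i <- 0L
      while (pos < ch$length[k]) {
        len <- round(stats::runif(1, 0.5, 1.5) * meanLen)
        end <- min(pos + len, ch$length[k])
        i <- i + 1L
        lab <- if (is.null(labels)) sprintf("%s_%d", ch$name[k], i)
               else labels[(i - 1L) %% length(labels) + 1L]
        out[[length(out) + 1L]] <- data.frame(chrom = ch$name[k],
                                              start = pos, end = end,
                                              label = lab)
        pos <- end
      }
    }
    do.call(rbind, out)
  }
  tads <- tile(1e6)
  compartments <- tile(2e6, labels = c("A", "B"))
  ladBlock <- 1e6
  lads <- do.call(rbind, lapply(seq_len(nrow(ch)), function(k) {
    step <- ladBlock / cfg$ladFraction
    starts <- seq(0, ch$length[k] - ladBlock, by = step)
    data.frame(chrom = ch$name[k], start = starts,
               end = starts + ladBlock, label = "LAD")
  }))
  nRep <- 60L
  repeats <- do.call(rbind, lapply(seq_len(nrow(ch)), function(k) {
    st <- sort(sample.int(ch$length[k] - 1000L, nRep))
    data.frame(chrom = ch$name[k], start = st, end = st + 1000L,
               label = sample(c("LINE", "SINE", "LTR"), nRep,
                              replace = TRUE))
  }))
  genes <- do.call(rbind, lapply(seq_len(nrow(ch)), function(k) {
    n <- ceiling(cfg$nGenes / nrow(ch))
    data.frame(chrom = ch$name[k],
               tss = sort(sample.int(ch$length[k] - 1L, n)))
  }))
  genes$gene <- sprintf("gene%04d", seq_len(nrow(genes)))
  dist <- breakpointDistance(genes, truth$breakpoints, mode = "bp")
  pAig <- ifelse(dist <= cfg$nearDist, cfg$aigNear, cfg$aigBg)
  genes$aig <- stats::runif(nrow(genes)) < pAig
  genes <- genes[, c("gene", "chrom", "tss", "aig")]
  counts <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
    lfc <- if (genes$aig[g]) sample(c(-1, 1), 1) * cfg$aigLfc else 0
    do.call(rbind, lapply(seq_len(cfg$nReplicates), function(r)
      data.frame(gene = genes$gene[g], replicate = paste0("rep", r),
                 cgr = stats::rpois(1, cfg$exprMean * 2^lfc),
                 wt = stats::rpois(1, cfg$exprMean))))
  }))
  counts$total <- counts$cgr + counts$wt
  cgrHap <- cfg$cgrHaplotype
  wtHap <- setdiff(c("H1", "H2"), cgrHap)
  haplotags <- do.call(rbind, lapply(seq_len(cfg$nPhaseSets), function(s) {
    n <- cfg$readsPerSet
    cls <- sample(c("WT", "CGR"), n, replace = TRUE)
    hap <- ifelse(cls == "CGR", cgrHap, wtHap)
    flip <- stats::runif(n) < cfg$hapNoise
    hap[flip] <- ifelse(hap[flip] == "H1", "H2", "H1")
    data.frame(phaseSet = sprintf("ps%04d", s),
               read = sprintf("ps%04d_r%03d", s, seq_len(n)),
               haplotype = hap, bpClass = cls)
  }))
  list(tads = tads, compartments = compartments, lads = lads,
       repeats = repeats, genes = genes, allelicCounts = counts,
       haplotags = haplotags)
}

#' Simulate an incomplete-reconstruction scaffold group
#'
#' Emulates the situation where sequencing evidence is missing between
#' scaffolds: one chromosome is cut into \code{nScaffolds} fragments, the
#' middle fragments are placed in random order and orientation on the
#' rearranged allele, and a Hi-C map is simulated. Each fragment is
#' returned as a single-fragment scaffold; the Hi-C map is the only
#' evidence of their true arrangement.
#'
#' @param nScaffolds number of scaffolds (2..5)
#' @param chromLength chromosome length in bp
#' @param seed optional RNG seed
#' @param ... further \code{\link{simConfig}} overrides (e.g.
#'   \code{hicDepth})
#' @return list: \code{truth} (the rearrangement ground truth),
#'   \code{matrix} (\code{ContactMatrix}), \code{scaffolds}
#'   (single-fragment layouts), \code{genome}
#' @export
simulateScaffoldGroup <- function(nScaffolds = 5L, chromLength = 5e6,
                                  seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- simConfig(chroms = data.frame(name = "chrA", length = chromLength),
                   mode = "chromothripsis", ctChroms = 1L,
                   ctBreakpoints = nScaffolds - 1L, deletionProb = 0,
                   minSpacing = chromLength / (2 * nScaffolds),
                   endMargin = chromLength / (2 * nScaffolds), ...)
  truth <- simulateRearrangement(cfg)
  hic <- emitHic(truth)
  wtTruth <- truth
  wtTruth$layouts <- list()
  control <- emitHic(wtTruth)   # independent wild-type control sample
  fr <- truth$fragments
  scaffolds <- lapply(seq_len(nrow(fr)), function(k) list(
    name = paste0("scaffold", k),
    fragments = data.frame(fragment = fr$id[k], chrom = fr$chrom[k],
                           start = fr$start[k], end = fr$end[k],
                           orientation = "forward"),
    completeness = "scaffold"))
  list(truth = truth, matrix = hic, control = control,
       scaffolds = scaffolds, genome = truth$genome)
}

#' Write a full simulation to disk
#'
#' Serializes the ground truth and every observable file produced by the
#' emitters; identical seeds give byte-identical output trees.
#'
#' @param dir output directory (created)
#' @param seed RNG seed for the whole simulation
#' @param cfg \code{\link{simConfig}}
#' @return invisible list of everything generated
#' @export
writeSimulation <- function(dir, seed, cfg = simConfig()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  set.seed(seed)
  truth <- simulateRearrangement(cfg)
  calls <- emitCalls(truth)
  hic <- emitHic(truth)
  jr <- emitJunctionReads(truth)
  tx <- emitTracksAndExpression(truth)
  g <- truth$genome
  utils::write.table(data.frame(name = g@chroms$name,
                                length = g@chroms$length),
                     file.path(dir, "genome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeBedDf <- function(df, path, label = FALSE) {
    cols <- if (label) df[, c("chrom", "start", "end", "label")]
            else df[, c("chrom", "start", "end")]
    utils::write.table(cols, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  writeBedDf(truth$annotation$gaps, file.path(dir, "gaps.bed"))
  writeBedDf(truth$annotation$segdups, file.path(dir, "segdups.bed"))
  writeBedpe(calls$long, file.path(dir, "calls_long.bedpe"))
  writeBedpe(calls$short, file.path(dir, "calls_short.bedpe"))
  writeBedpe(calls$decoy, file.path(dir, "calls_decoy.bedpe"))
  win <- calls$coverage@windows
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(win)),
               start = GenomicRanges::start(win) - 1L,
               end = GenomicRanges::end(win),
               coverage = sprintf("%.4f", S4Vectors::mcols(win)$coverage)),
    file.path(dir, "coverage.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeCoo(hic, file.path(dir, "matrix.coo"))
  writeSam(jr$reads, chromLengths(g), file.path(dir, "junctions.sam"))
  for (nm in c("tads", "compartments", "lads", "repeats"))
    writeBedDf(tx[[nm]], file.path(dir, "tracks", paste0(nm, ".bed")),
               label = TRUE)
  utils::write.table(tx$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tx$allelicCounts,
                     file.path(dir, "allelic_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tx$haplotags, file.path(dir, "haplotags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  layoutTable(truth$layouts, file.path(dir, "layouts.tsv"))
  truthMeta <- list(seed = seed, mode = cfg$mode,
                    deleted = truth$deleted,
                    nAdjacencies = nrow(truth$adjacencies))
  writeLines(jsonlite::toJSON(truthMeta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "truth.json"))
  invisible(list(truth = truth, calls = calls, hic = hic, junctions = jr,
                 tracks = tx))
}
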