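#' Read a labeled feature track from BED
#'
#' @param path BED file; column 4 is the feature label when present
#' @param collapseSubcompartments collapse labels such as A1/A2 and
#'   B1/B2/B3 to A and B
#' @return data.frame \code{chrom}, \code{start}, \code{end}, \code{label}
#'   (0-based half-open)
#' @export
readFeatureBed <- function(path, collapseSubcompartments = FALSE) {
  tab <- readBed(path)
  lab <- if ("name" %in% names(tab)) as.character(tab$name) else
    rep("feature", nrow(tab))
  if (collapseSubcompartments) lab <- toupper(substr(lab, 1, 1))
  data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
             label = lab)
}

.trackGRanges <- function(track, labels = NULL) {
  t <- track
  if (!is.null(labels)) t <- t[t$label %in% labels, , drop = FALSE]
  if (nrow(t) == 0L) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(t$chrom, IRanges::IRanges(t$start + 1L, t$end))
  S4Vectors::mcols(gr)$label <- t$label
  gr
}

#' Genome fraction covered by a feature, excluding assembly gaps
#'
#' The expected-by-chance baseline for breakpoint enrichment: the summed
#' feature length divided by the summed chromosome length, both with gap
#' bases removed.
#'
#' @param track feature data.frame (see \code{\link{readFeatureBed}});
#'   labels may be restricted with \code{labels}
#' @param genome \linkS4class{GenomeModel}
#' @param labels optional subset of track labels
#' @return fraction in [0, 1]
#' @export
expectedFraction <- function(track, genome, labels = NULL) {
  feat <- GenomicRanges::reduce(.trackGRanges(track, labels),
                                ignore.strand = TRUE)
  gaps <- GenomicRanges::reduce(genome@gaps)
  featNoGap <- GenomicRanges::setdiff(feat, gaps, ignore.strand = TRUE)
  gapWidth <- sum(GenomicRanges::width(gaps))
  denom <- sum(genome@chroms$length) - gapWidth
  sum(GenomicRanges::width(featNoGap)) / denom
}

#' Feature label at breakpoint positions
#'
#' @param track labeled feature data.frame
#' @param chrom,pos breakpoint coordinates (0-based)
#' @param genome optional \linkS4class{GenomeModel}; positions inside
#'   assembly gaps get NA
#' @param uncovered label for positions covered by no interval (default NA)
#' @return character vector of labels
#' @export
featureLabelAt <- function(track, chrom, pos, genome = NULL,
                           uncovered = NA_character_) {
  gr <- .trackGRanges(track)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  out <- rep(uncovered, length(pos))
  if (length(gr)) {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, gr, select = "first"))
    got <- !is.na(hits)
    out[got] <- S4Vectors::mcols(gr)$label[hits[got]]
  }
  if (!is.null(genome) && length(genome@gaps))
    out[.insideIntervals(chrom, pos, genome@gaps)] <- NA_character_
  out
}

#' Fast fraction of breakpoints inside a feature
#'
#' Vectorized interval-membership lookup (precomputable index) used inside
#' permutation loops, where building range objects per draw would dominate
#' the run time. Equivalent to counting non-NA matches of
#' \code{\link{featureLabelAt}} against the feature.
#'
#' @param track labeled feature data.frame, or an index from
#'   \code{\link{featureIndex}}
#' @param breakpoints data.frame \code{chrom}, \code{pos}
#' @return fraction of breakpoints falling inside the feature intervals
#' @export
inFeatureFraction <- function(track, breakpoints) {
  idx <- if (inherits(track, "featureIndex")) track else featureIndex(track)
  hit <- 0L
  n <- nrow(breakpoints)
  for (ch in unique(breakpoints$chrom)) {
    p <- breakpoints$pos[breakpoints$chrom == ch]
    d <- idx[[ch]]
    if (is.null(d)) next
    k <- findInterval(p, d$start)
    hit <- hit + sum(k >= 1L & p < d$end[pmax(k, 1L)])
  }
  hit / n
}

#' @rdname inFeatureFraction
#' @export
featureIndex <- function(track) {
  out <- lapply(split(track, track$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    list(start = d$start, end = d$end)
  })
  class(out) <- "featureIndex"
  out
}

#' Boundary positions of a TAD partition
#'
#' Internal boundaries between consecutive TADs (interval junction points).
#'
#' @param tads TAD data.frame (\code{chrom}, \code{start}, \code{end})
#' @return data.frame \code{chrom}, \code{pos}
#' @export
tadBoundaries <- function(tads) {
  out <- lapply(split(tads, tads$chrom), function(d) {
    b <- sort(unique(c(d$start, d$end)))
    b <- b[b > min(d$start) & b < max(d$end)]
    if (!length(b)) return(NULL)
    data.frame(chrom = d$chrom[1], pos = b)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(chrom = character(), pos = numeric())
  rownames(res) <- NULL
  res
}

#' Annotate breakpoints against chromatin-feature tracks
#'
#' @param breakpoints data.frame \code{chrom}, \code{pos}
#' @param tads,compartments,lads,repeats optional feature data.frames
#' @param genome optional \linkS4class{GenomeModel} (gap positions give NA)
#' @param boundaryPad TAD-boundary window (bp, each side)
#' @return breakpoints with columns \code{inBoundary}, \code{compartment},
#'   \code{inLad}, \code{repeatClass} as available
#' @export
annotateBreakpoints <- function(breakpoints, tads = NULL,
                                compartments = NULL, lads = NULL,
                                repeats = NULL, genome = NULL,
                                boundaryPad = 50000) {
  out <- breakpoints
  inGap <- if (!is.null(genome) && length(genome@gaps))
    .insideIntervals(out$chrom, out$pos, genome@gaps) else
    rep(FALSE, nrow(out))
  if (!is.null(tads)) {
    tb <- tadBoundaries(tads)
    out$inBoundary <- vapply(seq_len(nrow(out)), function(k) {
      any(tb$chrom == out$chrom[k] &
            abs(tb$pos - out$pos[k]) <= boundaryPad)
    }, logical(1))
    out$inBoundary[inGap] <- NA
  }
  if (!is.null(compartments))
    out$compartment <- featureLabelAt(compartments, out$chrom, out$pos,
                                      genome)
  if (!is.null(lads)) {
    lab <- featureLabelAt(lads, out$chrom, out$pos, genome,
                          uncovered = "nonLAD")
    out$inLad <- ifelse(is.na(lab), NA, lab != "nonLAD")
  }
  if (!is.null(repeats))
    out$repeatClass <- featureLabelAt(repeats, out$chrom, out$pos, genome,
                                      uncovered = "none")
  out
}

#' Classify fusion types induced by novel adjacencies
#'
#' Each adjacency fuses two loci; the unordered pair of their feature
#' labels (e.g. A-A / A-B / B-B compartment fusions, or LAD / non-LAD
#' fusions) is tallied. Adjacencies with an unannotatable breakend are
#' excluded and counted separately.
#'
#' @param adjacencies adjacency data.frame
#' @param track labeled feature data.frame
#' @param genome optional \linkS4class{GenomeModel}
#' @param uncovered label for uncovered positions (e.g. \code{"nonLAD"})
#' @return \code{list(counts = table, nExcluded =)}
#' @export
classifyFusions <- function(adjacencies, track, genome = NULL,
                            uncovered = NA_character_) {
  l1 <- featureLabelAt(track, adjacencies$chrom1, adjacencies$pos1, genome,
                       uncovered)
  l2 <- featureLabelAt(track, adjacencies$chrom2, adjacencies$pos2, genome,
                       uncovered)
  ok <- !is.na(l1) & !is.na(l2)
  pair <- vapply(which(ok), function(k)
    paste(sort(c(l1[k], l2[k])), collapse = "-"), character(1))
  list(counts = table(pair), nExcluded = sum(!ok))
}

#' Random-offset breakpoint null (coordinate shift with wrap-around)
#'
#' All coordinates on the same chromosome are shifted by one uniformly drawn
#' offset; coordinates shifted past the chromosome end re-enter at the other
#' side, preserving within-chromosome pairwise distances modulo the
#' chromosome length. Configurations placing any coordinate inside an
#' assembly gap are rejected and redrawn whole.
#'
#' @param breakpoints data.frame \code{chrom}, \code{pos}
#' @param genome \linkS4class{GenomeModel}
#' @param maxTries rejection-sampling cap
#' @param gapIdx precomputed gap index (internal speed-up for permutation
#'   loops); defaults to indexing \code{genome}'s gaps
#' @return shifted breakpoints data.frame
#' @export
nullShift <- function(breakpoints, genome, maxTries = 1000L,
                      gapIdx = NULL) {
  lens <- chromLengths(genome)
  if (is.null(gapIdx)) gapIdx <- .gapIndex(genome)
  chroms <- unique(breakpoints$chrom)
  sel <- lapply(chroms, function(ch) which(breakpoints$chrom == ch))
  pos <- breakpoints$pos
  for (try in seq_len(maxTries)) {
    newPos <- pos
    for (i in seq_along(chroms)) {
      L <- lens[[chroms[i]]]
      off <- sample.int(L, 1L) - 1L
      newPos[sel[[i]]] <- (pos[sel[[i]]] + off) %% L
    }
    bad <- FALSE
    for (i in seq_along(chroms)) {
      g <- gapIdx[[chroms[i]]]
      if (is.null(g)) next
      p <- newPos[sel[[i]]]
      k <- findInterval(p, g$start)
      if (any(k >= 1L & p < g$end[pmax(k, 1L)])) { bad <- TRUE; break }
    }
    if (!bad) {
      shifted <- breakpoints
      shifted$pos <- newPos
      return(shifted)
    }
  }
  stop("could not find a gap-free configuration in ", maxTries,
       " tries (chromosome fully gapped?)")
}

# precomputed per-chromosome gap bounds (0-based half-open, sorted) for
# fast rejection checks inside tight permutation loops
.gapIndex <- function(genome) {
  if (length(genome@gaps) == 0L) return(list())
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(genome@gaps)),
                  start = GenomicRanges::start(genome@gaps) - 1L,
                  end = GenomicRanges::end(genome@gaps))
  lapply(split(d, d$chrom), function(x) {
    x <- x[order(x$start), , drop = FALSE]
    list(start = x$start, end = x$end)
  })
}

#' Rewire-connections null (permute breakend pairing)
#'
#' Keeps every breakend coordinate but permutes which second breakends the
#' first breakends connect to, altering fusion pairings while conserving
#' the coordinate multiset. Used for fusion-type statistics.
#'
#' @param adjacencies adjacency data.frame
#' @return adjacency data.frame with permuted connections
#' @export
nullRewire <- function(adjacencies) {
  n <- nrow(adjacencies)
  if (n < 2L) return(adjacencies)
  perm <- sample.int(n)
  out <- adjacencies
  out[, c("chrom2", "pos2", "side2")] <-
    adjacencies[perm, c("chrom2", "pos2", "side2")]
  .withSpan(out)
}

#' Expression-permutation null
#'
#' Permutes the assignment of expression values (all non-coordinate
#' columns) to genes while gene coordinates stay fixed.
#'
#' @param genes gene table with coordinate columns \code{gene},
#'   \code{chrom}, \code{tss} and arbitrary expression columns
#' @return permuted gene table
#' @export
nullExpression <- function(genes) {
  fixed <- intersect(c("gene", "chrom", "tss", "start", "end", "strand"),
                     names(genes))
  vary <- setdiff(names(genes), fixed)
  perm <- sample.int(nrow(genes))
  out <- genes
  out[, vary] <- genes[perm, vary, drop = FALSE]
  out
}

#' Right-sided empirical test
#'
#' The p-value is the fraction of null statistics greater than or equal to
#' the observed one, exactly as defined for the empirical background
#' models: p = #(null >= observed) / n_iter, with no pseudocount (p = 0 is
#' possible) and no multiple-testing adjustment.
#'
#' @param observed observed statistic
#' @param nullGenerator function(k) returning the k-th null statistic, or a
#'   numeric vector of precomputed null values
#' @param nIter number of null configurations
#' @param name statistic name
#' @param expected optional expected-by-chance baseline to report
#' @return object of class \code{EmpiricalTestResult}: list with
#'   \code{statistic}, \code{observed}, \code{null}, \code{p},
#'   \code{expected}, \code{nIter}
#' @export
empiricalTest <- function(observed, nullGenerator, nIter = 1000L,
                          name = "statistic", expected = NA_real_) {
  nulls <- if (is.function(nullGenerator))
    vapply(seq_len(nIter), function(k) nullGenerator(k), numeric(1))
  else nullGenerator
  stopifnot(length(nulls) == nIter)
  structure(list(statistic = name, observed = observed, null = nulls,
                 p = sum(nulls >= observed) / nIter,
                 expected = expected, nIter = nIter),
            class = "EmpiricalTestResult")
}

#' @exportS3Method base::print
print.EmpiricalTestResult <- function(x, ...) {
  cat("Empirical test:", x$statistic, "\n observed:", x$observed,
      if (!is.na(x$expected)) paste(" expected:", signif(x$expected, 3)),
      "\n right-sided p =", x$p, "(", x$nIter, "null configurations )\n")
  invisible(x)
}

.tadIndexAt <- function(tads, chrom, pos) {
  vapply(seq_along(pos), function(k) {
    d <- tads[tads$chrom == chrom[k], , drop = FALSE]
    hit <- which(d$start <= pos[k] & pos[k] < d$end)
    if (length(hit)) {
      ord <- order(d$start)
      match(hit[1], ord)
    } else NA_integer_
  }, integer(1))
}

#' Distance of gene TSS to the nearest breakpoint
#'
#' In bp mode the distance is \code{min |tss - pos|} over breakpoints on
#' the gene's chromosome (most 5' TSS supplied by the caller); in TAD-unit
#' mode it is the number of TADs separating the TSS from the nearest
#' breakpoint (0 = same TAD). Genes on chromosomes without breakpoints get
#' \code{Inf} (unaffected).
#'
#' @param genes data.frame \code{gene}, \code{chrom}, \code{tss}
#' @param breakpoints data.frame \code{chrom}, \code{pos}
#' @param mode \code{"bp"} or \code{"tad_units"}
#' @param tads TAD partition (required for TAD units)
#' @return numeric distances
#' @export
breakpointDistance <- function(genes, breakpoints, mode = c("bp",
                                                            "tad_units"),
                               tads = NULL) {
  mode <- match.arg(mode)
  if (mode == "bp") {
    out <- rep(Inf, nrow(genes))
    for (ch in unique(genes$chrom)) {
      p <- sort(breakpoints$pos[breakpoints$chrom == ch])
      if (!length(p)) next
      sel <- which(genes$chrom == ch)
      tss <- genes$tss[sel]
      k <- findInterval(tss, p)
      dLeft <- ifelse(k >= 1L, tss - p[pmax(k, 1L)], Inf)
      dRight <- ifelse(k < length(p), p[pmin(k + 1L, length(p))] - tss, Inf)
      out[sel] <- pmin(dLeft, dRight)
    }
    out
  } else {
    stopifnot(!is.null(tads))
    gi <- .tadIndexAt(tads, genes$chrom, genes$tss)
    vapply(seq_len(nrow(genes)), function(k) {
      sel <- breakpoints$chrom == genes$chrom[k]
      if (!any(sel)) return(Inf)
      bi <- .tadIndexAt(tads, breakpoints$chrom[sel], breakpoints$pos[sel])
      if (is.na(gi[k]) || all(is.na(bi))) return(NA_real_)
      min(abs(bi - gi[k]), na.rm = TRUE)
    }, numeric(1))
  }
}

#' AIG fraction versus breakpoint distance, with empirical null envelope
#'
#' Bins informative genes by the distance of their (most 5') TSS to the
#' nearest breakpoint and reports the fraction of allelic imbalance genes
#' per bin, together with a null envelope (5th/50th/95th percentiles) and
#' per-bin right-sided empirical p-values from either the breakpoint-shift
#' null or the expression-permutation null.
#'
#' @param genes data.frame \code{gene}, \code{chrom}, \code{tss},
#'   \code{aig} (logical); only informative genes should be passed
#' @param breakpoints data.frame \code{chrom}, \code{pos}
#' @param genome \linkS4class{GenomeModel}
#' @param breaks distance bin edges; \code{Inf} as last edge collects genes
#'   on unaffected chromosomes
#' @param mode \code{"bp"} or \code{"tad_units"}
#' @param tads TAD partition for TAD-unit mode
#' @param null \code{"shift"} or \code{"expression"}
#' @param nIter number of null configurations
#' @return data.frame per bin: \code{bin}, \code{n}, \code{fraction},
#'   \code{q05}, \code{q50}, \code{q95}, \code{p}
#' @export
aigDistanceCurve <- function(genes, breakpoints, genome,
                             breaks = c(0, 1e5, 2e5, 5e5, 1e6, Inf),
                             mode = c("bp", "tad_units"), tads = NULL,
                             null = c("shift", "expression"),
                             nIter = 1000L) {
  mode <- match.arg(mode)
  null <- match.arg(null)
  binStats <- function(g, bp) {
    d <- breakpointDistance(g, bp, mode = mode, tads = tads)
    bin <- cut(d, breaks = breaks, right = FALSE, include.lowest = FALSE)
    lev <- levels(bin)
    bin <- as.character(bin)
    bin[is.infinite(d)] <- "unaffected"
    lev <- c(lev, "unaffected")
    t(vapply(lev, function(b) {
      sel <- !is.na(bin) & bin == b
      c(n = sum(sel),
        fraction = if (any(sel)) mean(g$aig[sel]) else NA_real_)
    }, numeric(2)))
  }
  obs <- binStats(genes, breakpoints)
  nullFrac <- matrix(NA_real_, nrow = nIter, ncol = nrow(obs))
  for (it in seq_len(nIter)) {
    stat <- if (null == "shift")
      binStats(genes, nullShift(breakpoints, genome))
    else binStats(nullExpression(genes), breakpoints)
    nullFrac[it, ] <- stat[, "fraction"]
  }
  qs <- apply(nullFrac, 2, function(v)
    stats::quantile(v, c(0.05, 0.5, 0.95), na.rm = TRUE, names = FALSE))
  p <- vapply(seq_len(nrow(obs)), function(k) {
    if (is.na(obs[k, "fraction"])) return(NA_real_)
    v <- nullFrac[, k]
    sum(!is.na(v) & v >= obs[k, "fraction"]) / nIter
  }, numeric(1))
  data.frame(bin = rownames(obs), n = obs[, "n"],
             fraction = obs[, "fraction"],
             q05 = qs[1, ], q50 = qs[2, ], q95 = qs[3, ], p = p,
             row.names = NULL)
}

#' Classify adjacencies by TAD relationship
#'
#' Each adjacency is assigned one class: breakends in the same TAD, in
#' neighboring TADs, spanning at least one full TAD, or on different
#' chromosomes (trans). Breakends outside any TAD give NA (reported).
#'
#' @param adjacencies adjacency data.frame
#' @param tads TAD partition data.frame
#' @return \code{list(classes = character vector, counts = table,
#'   nNA =)}
#' @export
intraTadClassification <- function(adjacencies, tads) {
  classes <- vapply(seq_len(nrow(adjacencies)), function(k) {
    a <- adjacencies[k, ]
    if (a$chrom1 != a$chrom2) return("trans")
    idx <- .tadIndexAt(tads, c(a$chrom1, a$chrom2), c(a$pos1, a$pos2))
    if (anyNA(idx)) return(NA_character_)
    d <- abs(idx[2] - idx[1])
    if (d == 0L) "same_tad" else if (d == 1L) "neighboring_tads"
    else "spanning"
  }, character(1))
  list(classes = classes, counts = table(classes),
       nNA = sum(is.na(classes)))
}
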