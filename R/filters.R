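#' Novel-adjacency call filters
#'
#' Rule-based filters that remove likely false-positive novel-adjacency
#' calls. Each filter partitions its input into \code{kept} and
#' \code{removed}; removed calls carry a \code{filter_reason} column.
#'
#' \itemize{
#'   \item \code{filterSupport}: drops calls supported by fewer reads than
#'     \code{frac} of the genome-wide mean alignment coverage (lenient 5%
#'     default). Calls with missing support (typically short-read calls,
#'     whose callers report no comparable count) pass through.
#'   \item \code{filterHighCoverage}: drops calls with a breakend in a
#'     window whose coverage exceeds \code{factor} times the genome mean.
#'   \item \code{filterNearGaps}: drops calls with a breakend closer than
#'     \code{dist} to an assembly gap (distance 0 when inside).
#'   \item \code{filterSegdup}: drops calls with a breakend inside an
#'     annotated segmental duplication.
#' }
#'
#' @param calls adjacency data.frame (see \code{\link{newAdjacencies}})
#' @param coverage \linkS4class{CoverageTrack}
#' @param frac support threshold as a fraction of mean coverage
#' @return \code{list(kept =, removed =)}, a partition of the input
#' @name adjacencyFilters
NULL

.partition <- function(calls, removeMask, reason) {
  removed <- calls[removeMask, , drop = FALSE]
  if (nrow(removed)) removed$filter_reason <- reason
  list(kept = calls[!removeMask, , drop = FALSE], removed = removed)
}

#' @rdname adjacencyFilters
#' @export
filterSupport <- function(calls, coverage, frac = 0.05) {
  gm <- genomeMeanCoverage(coverage)
  if (gm <= 0) stop("genome-wide mean coverage must be > 0")
  thr <- frac * gm
  drop <- !is.na(calls$support) & calls$support < thr
  .partition(calls, drop, "low_support")
}

#' @rdname adjacencyFilters
#' @param factor high-coverage multiple of the genome mean
#' @export
filterHighCoverage <- function(calls, coverage, factor = 3.0) {
  if (nrow(calls) == 0L) return(.partition(calls, logical(0), "high_coverage"))
  thr <- factor * genomeMeanCoverage(coverage)
  c1 <- coverageAt(coverage, calls$chrom1, calls$pos1)
  c2 <- coverageAt(coverage, calls$chrom2, calls$pos2)
  .partition(calls, c1 > thr | c2 > thr, "high_coverage")
}

#' @rdname adjacencyFilters
#' @param genome \linkS4class{GenomeModel} with gap/segdup intervals
#' @param dist minimum distance to a gap in bp
#' @export
filterNearGaps <- function(calls, genome, dist = 10000) {
  if (nrow(calls) == 0L) return(.partition(calls, logical(0), "near_gap"))
  d1 <- .distanceToIntervals(calls$chrom1, calls$pos1, genome@gaps)
  d2 <- .distanceToIntervals(calls$chrom2, calls$pos2, genome@gaps)
  .partition(calls, d1 < dist | d2 < dist, "near_gap")
}

#' @rdname adjacencyFilters
#' @export
filterSegdup <- function(calls, genome) {
  if (nrow(calls) == 0L) return(.partition(calls, logical(0), "segdup"))
  in1 <- .insideIntervals(calls$chrom1, calls$pos1, genome@segdups)
  in2 <- .insideIntervals(calls$chrom2, calls$pos2, genome@segdups)
  .partition(calls, in1 | in2, "segdup")
}

#' Cohort filter: remove adjacencies shared between samples
#'
#' Adjacencies from all samples are clustered by single linkage, where two
#' calls link when the chromosome pair matches, both sides match, and both
#' breakend distances are within \code{cutoff}. Clusters containing calls
#' from more than one sample are removed everywhere (shared calls are
#' enriched in artifacts and population polymorphisms, not the
#' patient-specific rearrangement).
#'
#' @param callsets named list of adjacency data.frames, one per sample
#' @param cutoff breakend distance cutoff in bp
#' @return named list of \code{list(kept =, removed =)} per sample
#' @export
filterCohort <- function(callsets, cutoff = 1000) {
  if (length(callsets) < 2L) {
    warning("cohort filter needs >= 2 samples; returning input unchanged")
    return(lapply(callsets, function(x) .partition(x, rep(FALSE, nrow(x)),
                                                   "cohort_shared")))
  }
  all <- do.call(rbind, lapply(names(callsets), function(s) {
    x <- callsets[[s]]
    if (nrow(x) == 0L) return(NULL)
    data.frame(sample = s, idx = seq_len(nrow(x)),
               key = paste(x$chrom1, x$side1, x$chrom2, x$side2),
               pos1 = x$pos1, pos2 = x$pos2, stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0L)
    return(lapply(callsets, function(x) .partition(x, rep(FALSE, nrow(x)),
                                                   "cohort_shared")))
  edges <- integer(0)
  for (k in unique(all$key)) {
    g <- which(all$key == k)
    if (length(g) < 2L) next
    cmb <- utils::combn(g, 2L)
    d <- pmax(abs(all$pos1[cmb[1, ]] - all$pos1[cmb[2, ]]),
              abs(all$pos2[cmb[1, ]] - all$pos2[cmb[2, ]]))
    ok <- d <= cutoff
    if (any(ok)) edges <- c(edges, as.integer(cmb[, ok, drop = FALSE]))
  }
  gr <- igraph::make_graph(edges, n = nrow(all), directed = FALSE)
  comp <- igraph::components(gr)$membership
  nSamples <- tapply(all$sample, comp, function(s) length(unique(s)))
  shared <- comp %in% as.integer(names(nSamples)[nSamples > 1L])
  out <- list()
  for (s in names(callsets)) {
    x <- callsets[[s]]
    mask <- rep(FALSE, nrow(x))
    hit <- all$idx[all$sample == s & shared]
    mask[hit] <- TRUE
    out[[s]] <- .partition(x, mask, "cohort_shared")
  }
  out
}

#' Merge long-read and short-read call sets
#'
#' Calls from the two technologies are paired when both breakends lie within
#' \code{matchDist} of each other and the sides agree. For a matched pair
#' the short-read call is chosen as representative when its caller flagged
#' it precise, otherwise the long-read call is used (long reads place
#' imprecise junctions more reliably; precise short-read breakends are
#' base-exact). Unmatched calls pass through. The output column
#' \code{tech} records \code{"both"}, \code{"longread"} or
#' \code{"shortread"}.
#'
#' @param longCalls,shortCalls filtered adjacency data.frames
#' @param matchDist maximum breakend distance for a technology match (bp)
#' @return adjacency data.frame with a \code{tech} column
#' @export
mergeTechnologies <- function(longCalls, shortCalls, matchDist = 1000) {
  lc <- longCalls; sc <- shortCalls
  usedS <- rep(FALSE, nrow(sc))
  rows <- vector("list", nrow(lc))
  keyL <- paste(lc$chrom1, lc$side1, lc$chrom2, lc$side2)
  keyS <- paste(sc$chrom1, sc$side1, sc$chrom2, sc$side2)
  for (i in seq_len(nrow(lc))) {
    cand <- which(!usedS & keyS == keyL[i] &
                    abs(sc$pos1 - lc$pos1[i]) <= matchDist &
                    abs(sc$pos2 - lc$pos2[i]) <= matchDist)
    if (length(cand)) {
      d <- abs(sc$pos1[cand] - lc$pos1[i]) + abs(sc$pos2[cand] - lc$pos2[i])
      j <- cand[which.min(d)]
      usedS[j] <- TRUE
      rep <- if (isTRUE(sc$precise[j])) sc[j, , drop = FALSE]
             else lc[i, , drop = FALSE]
      rep$tech <- "both"
      rows[[i]] <- rep
    } else {
      rep <- lc[i, , drop = FALSE]
      rep$tech <- "longread"
      rows[[i]] <- rep
    }
  }
  rest <- sc[!usedS, , drop = FALSE]
  if (nrow(rest)) rest$tech <- "shortread"
  out <- rbind(do.call(rbind, rows), rest)
  if (is.null(out)) out <- rest
  rownames(out) <- NULL
  out
}

#' Split calls into large-scale and small-scale sets
#'
#' Large-scale calls are trans adjacencies plus cis adjacencies whose span
#' strictly exceeds \code{minSpan}; the remainder is small-scale. Only
#' large-scale calls are prominent in Hi-C maps and drive the
#' reconstruction; selected small-scale calls can be re-attached afterwards
#' with \code{\link{attachSmallScale}}.
#'
#' @param calls adjacency data.frame
#' @param minSpan span threshold in bp (strict)
#' @return \code{list(large =, small =)}
#' @export
selectLargeScale <- function(calls, minSpan = 100000) {
  big <- is.infinite(calls$span) | calls$span > minSpan
  list(large = calls[big, , drop = FALSE],
       small = calls[!big, , drop = FALSE])
}

#' Attach small-scale calls anchored at curated breakpoints
#'
#' Small-scale calls (span 1--100 kb) are appended to the curated set when
#' at least one of their breakends lies within \code{tol} of an anchor point
#' (any breakend) of the curated large-scale calls.
#'
#' @param largeCurated curated large-scale adjacency data.frame
#' @param smallCalls small-scale adjacency data.frame
#' @param tol anchor matching tolerance in bp
#' @return the curated set with matching small-scale calls appended
#' @export
attachSmallScale <- function(largeCurated, smallCalls, tol = 50) {
  if (nrow(smallCalls) == 0L) return(largeCurated)
  anchors <- rbind(
    data.frame(chrom = largeCurated$chrom1, pos = largeCurated$pos1),
    data.frame(chrom = largeCurated$chrom2, pos = largeCurated$pos2))
  inSpan <- is.finite(smallCalls$span) &
    smallCalls$span >= 1000 & smallCalls$span <= 100000
  nearAnchor <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      any(anchors$chrom == chrom[i] & abs(anchors$pos - pos[i]) <= tol)
    }, logical(1))
  }
  hit <- inSpan & (nearAnchor(smallCalls$chrom1, smallCalls$pos1) |
                     nearAnchor(smallCalls$chrom2, smallCalls$pos2))
  add <- smallCalls[hit, , drop = FALSE]
  if (nrow(add)) add$curated <- TRUE
  out <- rbind(largeCurated[, intersect(names(largeCurated), names(add)),
                            drop = FALSE],
               add[, intersect(names(largeCurated), names(add)),
                   drop = FALSE])
  if (nrow(smallCalls) && !nrow(add)) out <- largeCurated
  rownames(out) <- NULL
  out
}
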