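#' Snap near-identical breakpoints to a common coordinate
#'
#' Complementary breakpoints from different novel adjacencies that lie
#' within \code{tol} of each other on the same chromosome are adjusted to
#' fit exactly, so that fragment boundaries coincide and very small spurious
#' fragments are avoided. Groups are formed by single linkage (a chain of
#' sub-tolerance steps merges) and snapped to the leftmost coordinate of the
#' group.
#'
#' @param adjacencies adjacency data.frame
#' @param tol snapping distance in bp (strict: distances below \code{tol}
#'   are merged)
#' @return \code{list(adjacencies =, breakpoints =)} where
#'   \code{breakpoints} is a data.frame of distinct snapped coordinates
#'   (\code{chrom}, \code{pos})
#' @export
simplifyBreakpoints <- function(adjacencies, tol = 50) {
  adj <- adjacencies
  ends <- rbind(data.frame(k = seq_len(nrow(adj)), side = 1L,
                           chrom = adj$chrom1, pos = adj$pos1),
                data.frame(k = seq_len(nrow(adj)), side = 2L,
                           chrom = adj$chrom2, pos = adj$pos2))
  for (ch in unique(ends$chrom)) {
    sel <- which(ends$chrom == ch)
    p <- ends$pos[sel]
    o <- order(p)
    ps <- p[o]
    grp <- cumsum(c(1L, diff(ps) >= tol))
    rep <- tapply(ps, grp, min)[grp]
    ends$pos[sel[o]] <- rep
  }
  adj$pos1[ends$k[ends$side == 1L]] <- ends$pos[ends$side == 1L]
  adj$pos2[ends$k[ends$side == 2L]] <- ends$pos[ends$side == 2L]
  adj <- .withSpan(adj)
  bp <- unique(data.frame(chrom = ends$chrom, pos = ends$pos))
  bp <- bp[order(bp$chrom, bp$pos), , drop = FALSE]
  rownames(bp) <- NULL
  list(adjacencies = adj, breakpoints = bp)
}

#' Cut reference chromosomes into fragments at breakpoints
#'
#' @param genome \linkS4class{GenomeModel}
#' @param breakpoints data.frame with \code{chrom}, \code{pos} (0-based)
#' @return fragment data.frame: \code{id}, \code{chrom}, \code{start},
#'   \code{end}, \code{tel5}, \code{tel3}; fragments tile each chromosome
#' @export
makeFragments <- function(genome, breakpoints) {
  out <- list()
  for (k in seq_len(nrow(genome@chroms))) {
    nm <- genome@chroms$name[k]
    L <- genome@chroms$length[k]
    bp <- sort(unique(breakpoints$pos[breakpoints$chrom == nm]))
    degenerate <- bp <= 0 | bp >= L
    if (any(degenerate)) {
      warning("ignoring degenerate breakpoint(s) at chromosome bounds on ", nm)
      bp <- bp[!degenerate]
    }
    bounds <- c(0, bp, L)
    for (f in seq_len(length(bounds) - 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = nm, start = bounds[f], end = bounds[f + 1L],
        tel5 = bounds[f] == 0, tel3 = bounds[f + 1L] == L)
    }
  }
  fr <- do.call(rbind, out)
  fr$id <- sprintf("%s:%d-%d", fr$chrom, as.integer(fr$start),
                   as.integer(fr$end))
  fr[, c("id", "chrom", "start", "end", "tel5", "tel3")]
}

# map a breakend to its graph node ("<fragId>.5p"/"<fragId>.3p"); telomeric
# sides carry no node
.breakendNode <- function(fragments, chrom, pos, side) {
  if (side == "tail") {
    hit <- which(fragments$chrom == chrom & fragments$end == pos)
    if (length(hit) != 1L)
      stop("breakend ", chrom, ":", pos, " (tail) matches no fragment boundary")
    if (fragments$tel3[hit])
      stop("breakend ", chrom, ":", pos, " targets a telomeric side: no node")
    paste0(fragments$id[hit], ".3p")
  } else {
    hit <- which(fragments$chrom == chrom & fragments$start == pos)
    if (length(hit) != 1L)
      stop("breakend ", chrom, ":", pos, " (head) matches no fragment boundary")
    if (fragments$tel5[hit])
      stop("breakend ", chrom, ":", pos, " targets a telomeric side: no node")
    paste0(fragments$id[hit], ".5p")
  }
}

#' Build the reconstruction graph
#'
#' Every fragment contributes a 5' and a 3' node (telomeric sides excluded);
#' the two nodes of a fragment are implicitly connected. Each novel
#' adjacency adds an edge: a \code{tail} breakend attaches to the 3' node of
#' the fragment ending at its position, a \code{head} breakend to the 5'
#' node of the fragment starting there. Nodes receiving more than one edge
#' are reported as conflicts and must be resolved before traversal.
#'
#' @param fragments fragment data.frame from \code{\link{makeFragments}}
#' @param adjacencies adjacency data.frame whose breakends coincide exactly
#'   with fragment boundaries (run \code{\link{simplifyBreakpoints}} first)
#' @return \code{list(fragments =, edges =, conflicts =)}; \code{edges} has
#'   columns \code{node1}, \code{node2}, \code{adjId}
#' @export
buildGraph <- function(fragments, adjacencies) {
  edges <- if (nrow(adjacencies)) {
    do.call(rbind, lapply(seq_len(nrow(adjacencies)), function(i) {
      a <- adjacencies[i, ]
      data.frame(
        node1 = .breakendNode(fragments, a$chrom1, a$pos1, a$side1),
        node2 = .breakendNode(fragments, a$chrom2, a$pos2, a$side2),
        adjId = a$id, stringsAsFactors = FALSE)
    }))
  } else data.frame(node1 = character(), node2 = character(),
                    adjId = character())
  nodeUse <- table(c(edges$node1, edges$node2))
  confNodes <- names(nodeUse)[nodeUse > 1L]
  conflicts <- do.call(rbind, lapply(confNodes, function(nd) {
    ids <- edges$adjId[edges$node1 == nd | edges$node2 == nd]
    data.frame(node = nd, adjIds = paste(sort(ids), collapse = ","))
  }))
  if (is.null(conflicts))
    conflicts <- data.frame(node = character(), adjIds = character())
  list(fragments = fragments, edges = edges, conflicts = conflicts)
}

#' Resolve multi-edge conflicts by evidence ranking
#'
#' At every node carrying more than one adjacency edge, the edge that ranks
#' highest under the lexicographic key (supported by both technologies,
#' strand concordant with the Hi-C pattern, Hi-C score, adjacency id) is
#' kept; the others are removed from the graph and logged. Explicit
#' overrides pin a winning adjacency per node regardless of the key.
#'
#' @param graph result of \code{\link{buildGraph}}
#' @param evidence data.frame with columns \code{adjId}, \code{bothTech}
#'   (logical), \code{strandConcordant} (logical), \code{hicScore} (numeric)
#' @param overrides optional named character vector: node name -> adjacency
#'   id to keep
#' @return the graph with at most one edge per node, plus \code{removed}
#'   (data.frame of dropped edges with the conflicted node)
#' @export
resolveConflicts <- function(graph, evidence, overrides = NULL) {
  edges <- graph$edges
  removedLog <- list()
  repeat {
    use <- table(c(edges$node1, edges$node2))
    confNodes <- sort(names(use)[use > 1L])
    if (length(confNodes) == 0L) break
    nd <- confNodes[[1L]]
    at <- which(edges$node1 == nd | edges$node2 == nd)
    if (!is.null(overrides) && nd %in% names(overrides)) {
      keep <- at[edges$adjId[at] == overrides[[nd]]]
      if (length(keep) != 1L)
        stop("override for node ", nd, " names no present adjacency")
    } else {
      ev <- evidence[match(edges$adjId[at], evidence$adjId), , drop = FALSE]
      if (anyNA(ev$adjId))
        stop("missing evidence for adjacency: ",
             paste(edges$adjId[at][is.na(ev$adjId)], collapse = ", "))
      key <- order(ev$bothTech, ev$strandConcordant, ev$hicScore,
                   ev$adjId, decreasing = TRUE)
      top <- key[1L]
      if (length(key) > 1L) {
        nxt <- key[2L]
        if (ev$bothTech[top] == ev$bothTech[nxt] &&
            ev$strandConcordant[top] == ev$strandConcordant[nxt] &&
            ev$hicScore[top] == ev$hicScore[nxt] &&
            ev$adjId[top] == ev$adjId[nxt])
          stop("exact evidence tie at node ", nd,
               ": pin a choice via 'overrides'")
      }
      keep <- at[top]
    }
    drop <- setdiff(at, keep)
    rem <- edges[drop, , drop = FALSE]
    rem$conflictNode <- nd
    removedLog[[length(removedLog) + 1L]] <- rem
    edges <- edges[-drop, , drop = FALSE]
  }
  removed <- if (length(removedLog)) do.call(rbind, removedLog)
             else cbind(edges[0, ], conflictNode = character(0))
  graph$edges <- edges
  graph$conflicts <- graph$conflicts[0, ]
  graph$removed <- removed
  graph
}

#' Traverse the reconstruction graph into derivative layouts
#'
#' Every maximal path of the conflict-free graph is emitted once. A path
#' entered through a fragment's 5' node lists the fragment forward, through
#' its 3' node inverted. Paths with telomeres at both ends are complete
#' derivative chromosomes; others are scaffolds. Fragments without any
#' adjacency edge are whole (unrearranged) chromosomes when telomeric at
#' both ends, and singletons -- candidates for deleted material --
#' otherwise. Cycles are emitted as circular scaffolds with a warning.
#' Layout direction is canonicalized so the first fragment has the smaller
#' (chromosome, start); the output does not depend on fragment input order.
#'
#' @param graph conflict-free graph (see \code{\link{resolveConflicts}})
#' @return \code{list(layouts =, singletons =)}. Each layout is a list with
#'   \code{name}, \code{fragments} (data.frame: \code{fragment},
#'   \code{chrom}, \code{start}, \code{end}, \code{orientation}) and
#'   \code{completeness} (\code{"complete"}, \code{"scaffold"} or
#'   \code{"circular"}).
#' @export
traverseGraph <- function(graph) {
  fr <- graph$fragments
  fr <- fr[order(fr$chrom, fr$start), , drop = FALSE]
  edges <- graph$edges
  use <- table(c(edges$node1, edges$node2))
  if (any(use > 1L)) stop("graph has unresolved conflicts")
  partner <- c(stats::setNames(edges$node2, edges$node1),
               stats::setNames(edges$node1, edges$node2))
  edgeOf <- c(stats::setNames(edges$adjId, edges$node1),
              stats::setNames(edges$adjId, edges$node2))
  hasEdge <- function(node) !is.na(partner[node]) & node %in% names(partner)
  fragEdgeCount <- vapply(fr$id, function(id)
    sum(c(paste0(id, ".5p"), paste0(id, ".3p")) %in% names(partner)),
    integer(1))

  layouts <- list()
  singles <- list()
  visited <- character(0)

  walk <- function(fragId, entryEnd) {
    rows <- list()
    srcAdj <- character(0)
    repeat {
      o <- if (entryEnd == "5p") "forward" else "inverted"
      rows[[length(rows) + 1L]] <- data.frame(fragment = fragId,
                                              orientation = o)
      visited <<- c(visited, fragId)
      exitEnd <- if (entryEnd == "5p") "3p" else "5p"
      exitNode <- paste0(fragId, ".", exitEnd)
      if (!(exitNode %in% names(partner)))
        return(list(rows = do.call(rbind, rows), srcAdj = srcAdj,
                    circular = FALSE))
      nxt <- partner[[exitNode]]
      srcAdj <- c(srcAdj, edgeOf[[exitNode]])
      nxtFrag <- sub("\\.(5p|3p)$", "", nxt)
      nxtEnd <- sub("^.*\\.", "", nxt)
      if (nxtFrag %in% vapply(rows, function(r) r$fragment, character(1)))
        return(list(rows = do.call(rbind, rows), srcAdj = srcAdj,
                    circular = TRUE))
      fragId <- nxtFrag
      entryEnd <- nxtEnd
    }
  }

  freeEnd <- function(fragId, end) {
    node <- paste0(fragId, ".", end)
    tel <- if (end == "5p") fr$tel5[fr$id == fragId] else
      fr$tel3[fr$id == fragId]
    tel || !(node %in% names(partner))
  }

  # fragments with no adjacency edges
  for (i in seq_len(nrow(fr))) {
    id <- fr$id[i]
    if (fragEdgeCount[[id]] > 0L) next
    visited <- c(visited, id)
    if (fr$tel5[i] && fr$tel3[i]) {
      layouts[[length(layouts) + 1L]] <- list(
        fragments = data.frame(fragment = id, orientation = "forward"),
        completeness = "complete", sourceAdjacencies = character(0))
    } else {
      singles[[length(singles) + 1L]] <- fr[i, , drop = FALSE]
    }
  }

  # paths: start from free ends, in canonical fragment order
  for (i in seq_len(nrow(fr))) {
    id <- fr$id[i]
    if (id %in% visited || fragEdgeCount[[id]] == 0L) next
    entry <- if (freeEnd(id, "5p")) "5p" else if (freeEnd(id, "3p")) "3p"
             else next
    w <- walk(id, entry)
    layouts[[length(layouts) + 1L]] <- list(
      fragments = w$rows,
      completeness = if (w$circular) "circular" else NA,
      sourceAdjacencies = w$srcAdj)
  }
  # leftover: pure cycles (no free end anywhere)
  for (i in seq_len(nrow(fr))) {
    id <- fr$id[i]
    if (id %in% visited || fragEdgeCount[[id]] == 0L) next
    warning("circular path detected; emitted as circular scaffold")
    w <- walk(id, "5p")
    layouts[[length(layouts) + 1L]] <- list(
      fragments = w$rows, completeness = "circular",
      sourceAdjacencies = w$srcAdj)
  }

  # decorate, classify completeness, canonicalize direction
  layouts <- lapply(layouts, function(ly) {
    m <- match(ly$fragments$fragment, fr$id)
    ly$fragments$chrom <- fr$chrom[m]
    ly$fragments$start <- fr$start[m]
    ly$fragments$end <- fr$end[m]
    n <- nrow(ly$fragments)
    first <- ly$fragments[1, ]; last <- ly$fragments[n, ]
    telStart <- if (first$orientation == "forward") fr$tel5[m[1]] else
      fr$tel3[m[1]]
    telEnd <- if (last$orientation == "forward") fr$tel3[m[n]] else
      fr$tel5[m[n]]
    if (is.na(ly$completeness))
      ly$completeness <- if (telStart && telEnd) "complete" else "scaffold"
    ly
  })
  layouts <- lapply(layouts, canonicalizeLayout)
  ord <- order(vapply(layouts, function(ly) ly$fragments$chrom[1],
                      character(1)),
               vapply(layouts, function(ly) ly$fragments$start[1], numeric(1)))
  layouts <- layouts[ord]
  for (k in seq_along(layouts)) layouts[[k]]$name <- paste0("der", k)
  singletons <- if (length(singles)) do.call(rbind, singles) else fr[0, ]
  rownames(singletons) <- NULL
  list(layouts = layouts, singletons = singletons)
}

#' Canonicalize layout direction
#'
#' A linear layout and its whole reversal (with all orientations flipped)
#' describe the same derivative chromosome; the emitted direction is the one
#' whose first fragment has the smaller (chromosome, start).
#'
#' @param layout a layout list (see \code{\link{traverseGraph}})
#' @export
canonicalizeLayout <- function(layout) {
  f <- layout$fragments
  n <- nrow(f)
  if (n > 0) {
    a <- c(f$chrom[1], sprintf("%015.0f", f$start[1]))
    b <- c(f$chrom[n], sprintf("%015.0f", f$start[n]))
    rev_first <- paste(b, collapse = "\r")
    fwd_first <- paste(a, collapse = "\r")
    if (rev_first < fwd_first) {
      f <- f[rev(seq_len(n)), , drop = FALSE]
      f$orientation <- ifelse(f$orientation == "forward", "inverted",
                              "forward")
      rownames(f) <- NULL
      layout$fragments <- f
      layout$sourceAdjacencies <- rev(layout$sourceAdjacencies)
    }
  }
  rownames(layout$fragments) <- NULL
  layout
}

#' Classify singleton fragments by relative coverage
#'
#' Singleton fragments (no junction evidence) are candidates for deleted
#' material. With per-fragment mean coverage normalized to a genome mean of
#' 1, a ratio at or below \code{lo} marks a deletion, at or above \code{hi}
#' retained-but-unplaced material, anything between (or missing) is
#' ambiguous.
#'
#' @param singletons fragment data.frame
#' @param coverageRatio numeric vector (parallel to \code{singletons}) of
#'   normalized fragment coverage; NA allowed
#' @param lo,hi classification thresholds
#' @return character vector of classes
#' @export
classifySingletons <- function(singletons, coverageRatio,
                               lo = 0.6, hi = 0.85) {
  vapply(coverageRatio, function(r) {
    if (is.na(r)) "ambiguous"
    else if (r <= lo) "deleted"
    else if (r >= hi) "retained_unplaced"
    else "ambiguous"
  }, character(1))
}

#' Emit derivative-chromosome sequences and junction table
#'
#' Concatenates fragment sequences per layout, reverse-complementing
#' inverted fragments, and reports junction coordinates (prefix sums of
#' fragment lengths).
#'
#' @param refSeqs named \code{DNAStringSet} (or named character) of
#'   reference chromosome sequences
#' @param layouts list of layouts (see \code{\link{traverseGraph}})
#' @return \code{list(seqs = DNAStringSet, junctions = data.frame)} with
#'   junction positions as 0-based offsets into the derivative sequence
#' @export
emitCustomGenome <- function(refSeqs, layouts) {
  if (!methods::is(refSeqs, "DNAStringSet"))
    refSeqs <- Biostrings::DNAStringSet(refSeqs)
  seqs <- character(0)
  jrows <- list()
  for (ly in layouts) {
    parts <- character(nrow(ly$fragments))
    for (i in seq_len(nrow(ly$fragments))) {
      f <- ly$fragments[i, ]
      chromSeq <- refSeqs[[f$chrom]]
      if (f$end > length(chromSeq))
        stop("fragment ", f$fragment, " beyond sequence length")
      s <- Biostrings::subseq(chromSeq, start = f$start + 1L, end = f$end)
      if (f$orientation == "inverted")
        s <- Biostrings::reverseComplement(s)
      parts[i] <- as.character(s)
    }
    seqs[[ly$name]] <- paste(parts, collapse = "")
    lens <- ly$fragments$end - ly$fragments$start
    if (nrow(ly$fragments) > 1L) {
      jrows[[length(jrows) + 1L]] <- data.frame(
        derivative = ly$name,
        junction = seq_len(nrow(ly$fragments) - 1L),
        pos = cumsum(lens)[-length(lens)])
    }
  }
  junctions <- if (length(jrows)) do.call(rbind, jrows)
               else data.frame(derivative = character(),
                               junction = integer(), pos = numeric())
  list(seqs = Biostrings::DNAStringSet(seqs), junctions = junctions)
}

#' Count junction-spanning reads
#'
#' A read supports a junction when one contiguous alignment covers the
#' interval \code{[pos - window, pos + window]}; split alignments do not
#' count.
#'
#' @param alignments data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open aligned reference span per record), e.g. from
#'   \code{\link{readSamAlignments}}
#' @param junctions junction table from \code{\link{emitCustomGenome}}
#' @param window half-window in bp
#' @return the junction table with an \code{nSpanning} column
#' @export
junctionSupport <- function(alignments, junctions, window = 100) {
  junctions$nSpanning <- vapply(seq_len(nrow(junctions)), function(k) {
    j <- junctions[k, ]
    sum(alignments$chrom == j$derivative &
          alignments$start <= j$pos - window &
          alignments$end >= j$pos + window)
  }, numeric(1))
  junctions
}

#' Serialize layouts as a TSV table
#'
#' One row per fragment: derivative name, rank, reference coordinates,
#' orientation, completeness and the adjacency joining it to the next
#' fragment.
#'
#' @param layouts list of layouts
#' @param path output file; when NULL the data.frame is returned only
#' @return the layout table, invisibly when written
#' @export
layoutTable <- function(layouts, path = NULL) {
  rows <- lapply(layouts, function(ly) {
    n <- nrow(ly$fragments)
    src <- c(ly$sourceAdjacencies, rep(NA_character_, n))[seq_len(n)]
    data.frame(derivative = ly$name, rank = seq_len(n),
               chrom = ly$fragments$chrom,
               start = ly$fragments$start, end = ly$fragments$end,
               orientation = ly$fragments$orientation,
               completeness = ly$completeness,
               source_adjacency = src)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
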