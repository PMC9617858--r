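#' Local alignment under the junction-analysis scoring scheme
#'
#' Smith-Waterman local alignment scoring +2 per match, -1 per mismatch,
#' -1 for the first column of a gap and -0.1 for each additional gap
#' column. Ties on the optimal score are broken towards the lowest start in
#' \code{a}, then in \code{b}. Written directly (rather than through a
#' general aligner) because the blunt/homology calls depend on exact start
#' positions under exactly this scheme.
#'
#' @param a,b character strings over A, C, G, T, N
#' @param match,mismatch,gapOpen,gapExtend scoring parameters; gapOpen is
#'   the cost of the first gap column, gapExtend of each following column
#' @return \code{list(score =, aStart =, bStart =, length =)} with 1-based
#'   start positions and the aligned length in \code{a}; score 0 and NA
#'   starts when no positive-scoring alignment exists
#' @export
localAlign <- function(a, b, match = 2, mismatch = -1,
                       gapOpen = -1, gapExtend = -0.1) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  empty <- list(score = 0, aStart = NA_integer_, bStart = NA_integer_,
                length = 0L)
  if (n == 0L || m == 0L) return(empty)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)   # gap in a (consume b)
  F <- matrix(NEG, n + 1L, m + 1L)   # gap in b (consume a)
  # start-of-alignment bookkeeping for tie-breaking
  SH <- array(NA_integer_, c(n + 1L, m + 1L, 2L))
  SE <- array(NA_integer_, c(n + 1L, m + 1L, 2L))
  SF <- array(NA_integer_, c(n + 1L, m + 1L, 2L))
  better <- function(s1, st1, s2, st2) {
    # TRUE when (s1, st1) beats (s2, st2): higher score, then earlier start
    if (s1 > s2 + 1e-12) return(TRUE)
    if (s1 < s2 - 1e-12) return(FALSE)
    if (is.na(st2[1])) return(TRUE)
    if (is.na(st1[1])) return(FALSE)
    (st1[1] < st2[1]) || (st1[1] == st2[1] && st1[2] < st2[2])
  }
  bestScore <- 0
  bestStart <- c(NA_integer_, NA_integer_)
  bestEnd <- c(NA_integer_, NA_integer_)
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      # E: gap in a
      op <- H[i, j - 1L] + gapOpen
      ex <- E[i, j - 1L] + gapExtend
      if (better(op, SH[i, j - 1L, ], ex, SE[i, j - 1L, ])) {
        E[i, j] <- op; SE[i, j, ] <- SH[i, j - 1L, ]
      } else {
        E[i, j] <- ex; SE[i, j, ] <- SE[i, j - 1L, ]
      }
      # F: gap in b
      op <- H[i - 1L, j] + gapOpen
      ex <- F[i - 1L, j] + gapExtend
      if (better(op, SH[i - 1L, j, ], ex, SF[i - 1L, j, ])) {
        F[i, j] <- op; SF[i, j, ] <- SH[i - 1L, j, ]
      } else {
        F[i, j] <- ex; SF[i, j, ] <- SF[i - 1L, j, ]
      }
      s <- if (av[i - 1L] == bv[j - 1L] && av[i - 1L] != "N") match
           else mismatch
      diag <- H[i - 1L, j - 1L] + s
      diagStart <- if (H[i - 1L, j - 1L] == 0 && is.na(SH[i - 1L, j - 1L, 1]))
        c(i - 1L, j - 1L) else SH[i - 1L, j - 1L, ]
      best <- diag; bst <- diagStart
      if (better(E[i, j], SE[i, j, ], best, bst)) {
        best <- E[i, j]; bst <- SE[i, j, ]
      }
      if (better(F[i, j], SF[i, j, ], best, bst)) {
        best <- F[i, j]; bst <- SF[i, j, ]
      }
      if (best <= 0) {
        H[i, j] <- 0
        SH[i, j, ] <- c(NA_integer_, NA_integer_)
      } else {
        H[i, j] <- best
        SH[i, j, ] <- bst
      }
      if (better(H[i, j], SH[i, j, ], bestScore, bestStart) &&
          H[i, j] > 0) {
        bestScore <- H[i, j]
        bestStart <- SH[i, j, ]
        bestEnd <- c(i - 1L, j - 1L)
      }
    }
  }
  if (bestScore <= 0) return(empty)
  list(score = bestScore, aStart = bestStart[1], bStart = bestStart[2],
       length = bestEnd[1] - bestStart[1] + 1L)
}

#' Majority-vote consensus of equal-length sequences
#'
#' Per-column majority base; ties and uncovered columns give N. Positions
#' may be padded with \code{"N"} or \code{"-"} (both ignored as votes).
#'
#' @param seqs character vector of equal-length sequences
#' @return consensus string
#' @export
consensusSeq <- function(seqs) {
  seqs <- seqs[nzchar(seqs)]
  if (length(seqs) == 0L) return("")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  apply(mat, 2, function(col) {
    col <- col[!col %in% c("N", "-")]
    if (length(col) == 0L) return("N")
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) "N" else names(tab)[1]
  }) |> paste(collapse = "")
}

# parse soft-clip structure of reads; reads is a data.frame with columns
# id, chrom, pos (0-based aligned start), mapq, cigar, seq
.clipInfo <- function(reads) {
  ops <- GenomicAlignments::explodeCigarOps(reads$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(reads$cigar)
  refLen <- vapply(seq_along(ops), function(k)
    sum(lens[[k]][ops[[k]] %in% c("M", "D", "N", "=", "X")]), numeric(1))
  leftClip <- vapply(seq_along(ops), function(k) {
    if (ops[[k]][1] == "S") lens[[k]][1] else 0L
  }, numeric(1))
  rightClip <- vapply(seq_along(ops), function(k) {
    L <- length(ops[[k]])
    if (ops[[k]][L] == "S") lens[[k]][L] else 0L
  }, numeric(1))
  data.frame(reads,
             alignedStart = reads$pos,
             alignedEnd = reads$pos + refLen,
             leftClip = leftClip, rightClip = rightClip)
}

#' Fetch soft-clipped reads around a breakend
#'
#' Reads with at least \code{minClip} soft-clipped bases and mapping
#' quality at least \code{minMapq} are collected around the called
#' position and separated by which side of the breakpoint their alignment
#' lies on: the L group aligns to the left (clipped on its right, at the
#' junction), the R group to the right (clipped on its left). Each side's
#' search window starts at \code{startWindow} and doubles while that side
#' is empty, capped at \code{maxWindow}.
#'
#' @param reads data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (0-based aligned start), \code{mapq}, \code{cigar}, \code{seq}
#' @param chrom,pos breakend location (0-based)
#' @param startWindow,maxWindow window schedule in bp
#' @param minClip,minMapq read filters
#' @return \code{list(L =, R =)} of annotated read data.frames (possibly
#'   empty)
#' @export
fetchClipped <- function(reads, chrom, pos, startWindow = 10,
                         maxWindow = 10000, minClip = 10, minMapq = 20) {
  info <- .clipInfo(reads)
  info <- info[info$chrom == chrom & info$mapq >= minMapq, , drop = FALSE]
  Lcand <- info[info$rightClip >= minClip, , drop = FALSE]
  Rcand <- info[info$leftClip >= minClip, , drop = FALSE]
  pick <- function(cand, clipPos) {
    w <- startWindow
    repeat {
      hit <- cand[abs(clipPos(cand) - pos) <= w, , drop = FALSE]
      if (nrow(hit) > 0L || w >= maxWindow) return(hit)
      w <- min(w * 2, maxWindow)
    }
  }
  list(L = pick(Lcand, function(d) d$alignedEnd),
       R = pick(Rcand, function(d) d$alignedStart))
}

#' InDel size at an aligned breakpoint
#'
#' The signed genomic distance between the median clip positions of the L
#' and R read groups (R minus L): positive values indicate lost material,
#' negative gained. Requires at least \code{minReads} reads clipped at one
#' identical reference position on each side, otherwise NA.
#'
#' @param L,R read groups from \code{\link{fetchClipped}}
#' @param minReads support threshold per side
#' @return signed InDel size in bp, or NA
#' @export
indelSize <- function(L, R, minReads = 3L) {
  if (nrow(L) == 0L || nrow(R) == 0L) return(NA_real_)
  okL <- max(table(L$alignedEnd)) >= minReads
  okR <- max(table(R$alignedStart)) >= minReads
  if (!okL || !okR) return(NA_real_)
  stats::median(R$alignedStart) - stats::median(L$alignedEnd)
}

# consensus of the +/- flank bases of a read group around its median clip
# position; side "L" reads clip on the right (aligned | clipped), side "R"
# on the left (clipped | aligned)
.groupConsensus <- function(grp, side, flank = 25L) {
  if (nrow(grp) == 0L) return(list(aligned = "", clipped = ""))
  clipPos <- if (side == "L") grp$alignedEnd else grp$alignedStart
  med <- stats::median(clipPos)
  grp <- grp[clipPos == med, , drop = FALSE]
  aligned <- character(0); clipped <- character(0)
  for (k in seq_len(nrow(grp))) {
    seqc <- grp$seq[k]
    nL <- grp$leftClip[k]; nR <- grp$rightClip[k]
    len <- nchar(seqc)
    core <- substr(seqc, nL + 1L, len - nR)
    if (side == "L") {
      al <- substr(core, max(1L, nchar(core) - flank + 1L), nchar(core))
      cl <- substr(seqc, len - nR + 1L, min(len, len - nR + flank))
    } else {
      al <- substr(core, 1L, min(flank, nchar(core)))
      cl <- substr(seqc, max(1L, nL - flank + 1L), nL)
    }
    pad <- function(s, left) {
      d <- flank - nchar(s)
      if (d <= 0L) return(s)
      ns <- strrep("N", d)
      if (left) paste0(ns, s) else paste0(s, ns)
    }
    aligned <- c(aligned, pad(al, left = (side == "L")))
    clipped <- c(clipped, pad(cl, left = (side == "R")))
  }
  list(aligned = consensusSeq(aligned), clipped = consensusSeq(clipped))
}

# longer clipped consensus (up to `len` bases) for insertion measurement
.clippedConsensusLong <- function(grp, side, len = 50L) {
  if (nrow(grp) == 0L) return("")
  clipPos <- if (side == "L") grp$alignedEnd else grp$alignedStart
  med <- stats::median(clipPos)
  grp <- grp[clipPos == med, , drop = FALSE]
  out <- character(0)
  for (k in seq_len(nrow(grp))) {
    seqc <- grp$seq[k]
    nL <- grp$leftClip[k]; nR <- grp$rightClip[k]
    slen <- nchar(seqc)
    cl <- if (side == "L")
      substr(seqc, slen - nR + 1L, min(slen, slen - nR + len))
    else substr(seqc, max(1L, nL - len + 1L), nL)
    d <- len - nchar(cl)
    if (d > 0L) cl <- if (side == "L") paste0(cl, strrep("N", d))
                      else paste0(strrep("N", d), cl)
    out <- c(out, cl)
  }
  consensusSeq(out)
}

.revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Junction homology and untemplated insertion
#'
#' Implements the consensus-alignment junction signature: the 50 bp source
#' consensus (25 aligned + 25 clipped around the median clip position,
#' read in the direction crossing the junction) is locally aligned to the
#' 25 bp aligned consensus at the target breakend. A perfect alignment
#' (the whole target matched without mismatch or gap) starting at query
#' position 26 marks a blunt junction; a start at 26 - h marks h bases of
#' junction homology (the aligner extends target alignments through the
#' homologous stretch, shifting clips accordingly). Imperfect alignments
#' are re-examined with a 50 bp clipped-only consensus to measure the
#' untemplated insertion as the offset of the best alignment start. The
#' combined homology is homology + insertion length.
#'
#' @param sourceGroup clipped read group at the source breakend (the group
#'   whose clipped tails cross the junction: L for a \code{tail} breakend,
#'   R for \code{head})
#' @param targetGroup clipped read group at the target breakend
#' @param sourceSide,targetSide breakend sides (\code{"tail"}/\code{"head"})
#' @param flank consensus flank length (25)
#' @return list with \code{homology}, \code{insertion}, \code{combined},
#'   \code{blunt}, \code{qc}
#' @export
junctionHomology <- function(sourceGroup, targetGroup, sourceSide,
                             targetSide, flank = 25L) {
  na <- list(homology = NA_real_, insertion = NA_real_,
             combined = NA_real_, blunt = NA, qc = "no_reads")
  if (nrow(sourceGroup) == 0L || nrow(targetGroup) == 0L) return(na)
  sSide <- if (sourceSide == "tail") "L" else "R"
  tSide <- if (targetSide == "head") "R" else "L"
  src <- .groupConsensus(sourceGroup, sSide, flank)
  tgt <- .groupConsensus(targetGroup, tSide, flank)
  if (sSide == "L") {
    q <- paste0(src$aligned, src$clipped)
  } else {
    q <- .revcomp(paste0(src$clipped, src$aligned))
  }
  t25 <- if (tSide == "R") tgt$aligned else .revcomp(tgt$aligned)
  if (nchar(q) < 2L * flank || nchar(t25) < flank) {
    na$qc <- "short_consensus"
    return(na)
  }
  aln <- localAlign(q, t25)
  perfect <- !is.na(aln$aStart) &&
    abs(aln$score - 2 * flank) < 1e-9 && aln$length == flank
  if (perfect) {
    shift <- (flank + 1L) - aln$aStart
    if (shift >= 0L) {
      h <- shift
      return(list(homology = h, insertion = 0, combined = h,
                  blunt = (h == 0), qc = "ok"))
    }
  }
  clipLong <- if (sSide == "L")
    .clippedConsensusLong(sourceGroup, "L", 2L * flank)
  else .revcomp(.clippedConsensusLong(sourceGroup, "R", 2L * flank))
  aln2 <- localAlign(clipLong, t25)
  if (is.na(aln2$aStart)) {
    na$qc <- "unalignable"
    return(na)
  }
  ins <- aln2$aStart - 1L
  list(homology = 0, insertion = ins, combined = ins,
       blunt = FALSE, qc = "ok")
}

#' Per-junction signature table
#'
#' Runs the clipped-read fetch, InDel, and homology analyses for each
#' curated adjacency and returns a tidy table.
#'
#' @param reads clipped-read data.frame (see \code{\link{fetchClipped}}),
#'   e.g. from \code{\link{readSamReads}}
#' @param adjacencies adjacency data.frame
#' @param minReads InDel support threshold per side
#' @return data.frame: \code{adjacency_id}, \code{indel}, \code{homology},
#'   \code{insertion}, \code{combined}, \code{blunt}, \code{n_L},
#'   \code{n_R}, \code{qc}
#' @export
junctionSignatures <- function(reads, adjacencies, minReads = 3L) {
  rows <- lapply(seq_len(nrow(adjacencies)), function(k) {
    a <- adjacencies[k, ]
    g1 <- fetchClipped(reads, a$chrom1, a$pos1)
    g2 <- fetchClipped(reads, a$chrom2, a$pos2)
    ind <- indelSize(g1$L, g1$R, minReads = minReads)
    srcGrp <- if (a$side1 == "tail") g1$L else g1$R
    tgtGrp <- if (a$side2 == "head") g2$R else g2$L
    hom <- junctionHomology(srcGrp, tgtGrp, a$side1, a$side2)
    data.frame(adjacency_id = a$id, indel = ind,
               homology = hom$homology, insertion = hom$insertion,
               combined = hom$combined, blunt = hom$blunt,
               n_L = nrow(g1$L), n_R = nrow(g1$R), qc = hom$qc)
  })
  do.call(rbind, rows)
}
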