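#' Number of telomere-bearing outer ends of a scaffold
#'
#' @param layout a layout list
#' @param genome \linkS4class{GenomeModel}
#' @return integer 0, 1 or 2
#' @export
scaffoldTelomericEnds <- function(layout, genome) {
  f <- layout$fragments
  n <- nrow(f)
  len <- chromLengths(genome)
  isTel <- function(row, sideOut) {
    # sideOut: which derivative end of the fragment faces outward
    if (row$orientation == "forward") {
      if (sideOut == "left") row$start == 0 else row$end == len[[row$chrom]]
    } else {
      if (sideOut == "left") row$end == len[[row$chrom]] else row$start == 0
    }
  }
  sum(isTel(f[1, ], "left"), isTel(f[n, ], "right"))
}

#' Group scaffolds into derivative chromosomes by shared ectopic Hi-C signal
#'
#' Two scaffolds are linked when any fragment of one and any fragment of the
#' other share a grid tile flagged as ectopic (fragment pairs with ectopic
#' interactions sit on the same derivative chromosome); groups are the
#' connected components of this relation. Singleton scaffolds pass through
#' as their own groups.
#'
#' @param scaffolds list of layouts
#' @param x \code{ContactMatrix}
#' @param decay \code{DecayModel} fitted on \code{x}
#' @param genome \linkS4class{GenomeModel} (for telomere accounting)
#' @param threshold,minBins ectopic flag parameters, see
#'   \code{\link{ectopicScore}}
#' @return list of groups: each a list with \code{members} (scaffold
#'   indices), \code{scaffolds}, \code{telomericEnds} and \code{evidence}
#'   (data.frame of flagged tile pairs)
#' @export
groupScaffolds <- function(scaffolds, x, decay, genome,
                           threshold = 3.0, minBins = 4L) {
  allIds <- unlist(lapply(scaffolds, function(s) s$fragments$fragment))
  if (anyDuplicated(allIds))
    stop("fragment present in two scaffolds: ",
         paste(unique(allIds[duplicated(allIds)]), collapse = ", "))
  nS <- length(scaffolds)
  bins <- lapply(scaffolds, function(s) {
    br <- layoutBinRanges(x, s)
    br[, c("fragment", "refStartBin", "refEndBin")]
  })
  edges <- integer(0)
  evidence <- list()
  if (nS >= 2L) for (a in 1:(nS - 1L)) for (b in (a + 1L):nS) {
    linked <- FALSE
    for (i in seq_len(nrow(bins[[a]]))) for (j in seq_len(nrow(bins[[b]]))) {
      ra <- bins[[a]][i, ]; rb <- bins[[b]][j, ]
      es <- ectopicScore(x, decay,
                         c(ra$refStartBin, ra$refEndBin),
                         c(rb$refStartBin, rb$refEndBin),
                         threshold = threshold, minBins = minBins)
      if (es$flag) {
        linked <- TRUE
        evidence[[length(evidence) + 1L]] <- data.frame(
          scaffold1 = a, scaffold2 = b,
          fragment1 = ra$fragment, fragment2 = rb$fragment,
          score = es$score)
      }
    }
    if (linked) edges <- c(edges, a, b)
  }
  g <- igraph::make_graph(edges, n = nS, directed = FALSE)
  comp <- igraph::components(g)$membership
  ev <- if (length(evidence)) do.call(rbind, evidence)
        else data.frame(scaffold1 = integer(), scaffold2 = integer(),
                        fragment1 = character(), fragment2 = character(),
                        score = numeric())
  lapply(sort(unique(comp)), function(cid) {
    mem <- which(comp == cid)
    list(members = mem,
         scaffolds = scaffolds[mem],
         telomericEnds = sum(vapply(scaffolds[mem], scaffoldTelomericEnds,
                                    numeric(1), genome = genome)),
         evidence = ev[ev$scaffold1 %in% mem & ev$scaffold2 %in% mem, ,
                       drop = FALSE])
  })
}

.reverseLayoutFragments <- function(f) {
  f <- f[rev(seq_len(nrow(f))), , drop = FALSE]
  f$orientation <- ifelse(f$orientation == "forward", "inverted", "forward")
  rownames(f) <- NULL
  f
}

# orient a one-telomere scaffold so its telomeric end faces the given side
.orientTelomereOut <- function(layout, genome, side) {
  f <- layout$fragments
  n <- nrow(f)
  len <- chromLengths(genome)
  leftTel <- if (f$orientation[1] == "forward") f$start[1] == 0 else
    f$end[1] == len[[f$chrom[1]]]
  want <- side == "left"
  if (leftTel != want) f <- .reverseLayoutFragments(f)
  f
}

#' Enumerate candidate derivative layouts of a scaffold group
#'
#' For a group with exactly two telomere-bearing scaffolds, those two fix
#' the ends of the derivative chromosome (oriented telomere-outward); all
#' orders and both orientations of the remaining scaffolds are enumerated,
#' giving (N-2)! * 2^(N-2) candidates. Groups with another telomere count,
#' or more than \code{maxComponents} members, are rejected.
#'
#' @param group a group from \code{\link{groupScaffolds}}
#' @param genome \linkS4class{GenomeModel}
#' @param maxComponents enumeration cap on the number of scaffolds
#' @return list of candidate layouts (each with \code{name},
#'   \code{fragments}, \code{completeness}, and \code{order}/\code{flips}
#'   bookkeeping)
#' @export
enumerateLayouts <- function(group, genome, maxComponents = 5L) {
  sc <- group$scaffolds
  N <- length(sc)
  if (N > maxComponents)
    stop("group has ", N, " scaffolds; enumeration limited to ",
         maxComponents, " components")
  telCount <- vapply(sc, scaffoldTelomericEnds, numeric(1), genome = genome)
  telIdx <- which(telCount >= 1L)
  if (length(telIdx) != 2L || group$telomericEnds != 2L)
    stop("permutation requires exactly two telomeric scaffold ends, found ",
         group$telomericEnds)
  key <- vapply(sc, function(s)
    paste(s$fragments$chrom[1], sprintf("%015.0f", s$fragments$start[1])),
    character(1))
  telIdx <- telIdx[order(key[telIdx])]
  left <- telIdx[1]; right <- telIdx[2]
  mid <- setdiff(seq_len(N), telIdx)
  leftFr <- .orientTelomereOut(sc[[left]], genome, "left")
  rightFr <- .orientTelomereOut(sc[[right]], genome, "right")
  perms <- if (length(mid) == 0L) list(integer(0)) else .permutations(mid)
  out <- list()
  for (p in perms) {
    nMid <- length(p)
    for (mask in seq_len(max(1L, 2L^nMid)) - 1L) {
      flips <- if (nMid) as.logical(bitwAnd(bitwShiftR(mask, seq_len(nMid) - 1L),
                                            1L)) else logical(0)
      parts <- list(leftFr)
      for (t in seq_along(p)) {
        f <- sc[[p[t]]]$fragments
        if (flips[t]) f <- .reverseLayoutFragments(f)
        parts[[length(parts) + 1L]] <- f
      }
      parts[[length(parts) + 1L]] <- rightFr
      out[[length(out) + 1L]] <- list(
        name = sprintf("candidate%03d", length(out) + 1L),
        fragments = do.call(rbind, parts),
        completeness = "complete",
        order = c(left, p, right), flips = flips)
    }
  }
  out
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
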