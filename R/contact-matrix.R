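#' @importFrom Matrix sparseMatrix tril triu
NULL

#' Construct a contact matrix
#'
#' @param chroms data.frame with columns \code{name} and \code{length} (bp),
#'   in display order.
#' @param binSize bin width in bp.
#' @param entries data.frame with columns \code{i}, \code{j} (0-based global
#'   bin indices) and \code{count}. Entries with \code{j < i} are mirrored
#'   into the upper triangle with a warning; duplicate cells are summed.
#' @return \linkS4class{ContactMatrix}
#' @export
ContactMatrix <- function(chroms, binSize, entries = NULL) {
  nbins <- ceiling(chroms$length / binSize)
  tab <- data.frame(name = as.character(chroms$name),
                    length = as.numeric(chroms$length),
                    nbins = as.integer(nbins),
                    offset = cumsum(c(0L, as.integer(nbins)))[seq_along(nbins)])
  n <- sum(tab$nbins)
  if (is.null(entries) || nrow(entries) == 0L) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  } else {
    if (any(entries$count < 0)) stop("negative contact count")
    i <- entries$i; j <- entries$j
    if (any(i >= n | j >= n | i < 0 | j < 0)) stop("bin index out of range")
    flip <- j < i
    if (any(flip)) {
      warning(sum(flip), " lower-triangle entries normalized to upper triangle")
      tmp <- i[flip]; i[flip] <- j[flip]; j[flip] <- tmp
    }
    m <- Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = entries$count,
                              dims = c(n, n))
  }
  new("ContactMatrix", binSize = binSize, chroms = tab,
      mat = methods::as(m, "CsparseMatrix"))
}

#' @rdname ContactMatrix
#' @param x,object a \code{ContactMatrix}
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname ContactMatrix
#' @export
setMethod("binSize", "ContactMatrix", function(x) x@binSize)

#' @rdname ContactMatrix
#' @export
setGeneric("chromTable", function(x) standardGeneric("chromTable"))
#' @rdname ContactMatrix
#' @export
setMethod("chromTable", "ContactMatrix", function(x) x@chroms)

#' Total signal (sum over unique cells, upper triangle)
#' @param x \code{ContactMatrix}
#' @export
contactSum <- function(x) sum(x@mat@x)

#' Dense symmetric matrix of a \code{ContactMatrix}
#' @param x \code{ContactMatrix}
#' @return base dense matrix, symmetrized
#' @export
denseContacts <- function(x) {
  m <- as.matrix(x@mat)
  d <- diag(m)
  m <- m + t(m)
  diag(m) <- d
  m
}

#' Sparse upper-triangle entries as a data.frame (0-based bins)
#' @param x \code{ContactMatrix}
#' @export
contactEntries <- function(x) {
  tm <- methods::as(x@mat, "TsparseMatrix")
  keep <- tm@x != 0
  out <- data.frame(i = tm@i[keep], j = tm@j[keep], count = tm@x[keep])
  out[order(out$i, out$j), , drop = FALSE]
}

#' Read / write sparse COO contact-matrix text files
#'
#' The format is plain text: comment lines starting with \code{#} carry a
#' JSON header \code{{"bin_size": ..., "chroms": [{"name","length"}, ...]}},
#' followed by whitespace-separated \code{bin_i bin_j count} rows with
#' 0-based global bin indices. \code{readCoo(writeCoo(m))} is the identity.
#'
#' @param path file path
#' @return \code{ContactMatrix} for \code{readCoo}; the path, invisibly,
#'   for \code{writeCoo}.
#' @export
readCoo <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) == 0L) stop("missing COO header")
  meta <- jsonlite::fromJSON(paste(sub("^#\\s*", "", hdr), collapse = ""))
  if (is.null(meta$bin_size) || is.null(meta$chroms))
    stop("COO header must declare bin_size and chroms")
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  entries <- if (length(body)) {
    f <- utils::read.table(text = body, col.names = c("i", "j", "count"))
    f
  } else NULL
  ContactMatrix(data.frame(name = meta$chroms$name,
                           length = meta$chroms$length),
                binSize = meta$bin_size, entries = entries)
}

#' @rdname readCoo
#' @param x \code{ContactMatrix} to write
#' @export
writeCoo <- function(x, path) {
  meta <- list(bin_size = x@binSize,
               chroms = data.frame(name = x@chroms$name,
                                   length = x@chroms$length))
  hdr <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  ent <- contactEntries(x)
  body <- sprintf("%d %d %s", ent$i, ent$j,
                  format(ent$count, trim = TRUE, scientific = FALSE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Bin arithmetic
#'
#' \code{binOf} maps 0-based genomic positions to 0-based global bin
#' indices. \code{fragmentBins} maps a fragment to the whole bins it covers:
#' the start is rounded up to the next bin start and the end rounded down,
#' so partially covered bins are excluded; a fragment covering no whole bin
#' is flagged \code{subBin}.
#'
#' @param x \code{ContactMatrix}
#' @param chrom,pos chromosome names and 0-based positions
#' @return \code{binOf}: integer global bins. \code{fragmentBins}: list with
#'   \code{startBin}, \code{endBin} (global, end exclusive) and
#'   \code{subBin}.
#' @export
binOf <- function(x, chrom, pos) {
  tab <- x@chroms
  k <- match(chrom, tab$name)
  if (anyNA(k)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(k)]), collapse = ", "))
  as.integer(tab$offset[k] + floor(pos / x@binSize))
}

#' @rdname binOf
#' @param start,end fragment bounds, 0-based half-open
#' @export
fragmentBins <- function(x, chrom, start, end) {
  tab <- x@chroms
  k <- match(chrom, tab$name)
  if (anyNA(k)) stop("unknown chromosome")
  sb <- ceiling(start / x@binSize)
  eb <- floor(end / x@binSize)
  list(startBin = as.integer(tab$offset[k] + sb),
       endBin = as.integer(tab$offset[k] + eb),
       subBin = eb <= sb)
}

#' Extract a dense tile of the contact map
#'
#' @param x \code{ContactMatrix}
#' @param rowBins,colBins integer vectors \code{c(start, end)} of global
#'   0-based bins, end exclusive
#' @param invertRows,invertCols reverse the corresponding axis (used for
#'   inverted fragments)
#' @return dense numeric matrix of the requested block
#' @export
extractTile <- function(x, rowBins, colBins,
                        invertRows = FALSE, invertCols = FALSE) {
  if (rowBins[2] <= rowBins[1] || colBins[2] <= colBins[1])
    stop("sub-bin fragment: tile has no whole bin")
  full <- denseContacts(x)
  ri <- (rowBins[1] + 1L):rowBins[2]
  ci <- (colBins[1] + 1L):colBins[2]
  tile <- full[ri, ci, drop = FALSE]
  if (invertRows) tile <- tile[rev(seq_len(nrow(tile))), , drop = FALSE]
  if (invertCols) tile <- tile[, rev(seq_len(ncol(tile))), drop = FALSE]
  tile
}

#' Fit a distance-decay background model
#'
#' The expected cis contact count at bin distance d is the mean over all cis
#' bin pairs at that distance (zeros included), smoothed to be nonincreasing
#' by isotonic regression and floored at a small positive value. The trans
#' expectation is the mean over all trans pairs.
#'
#' @param x \code{ContactMatrix}
#' @return object of class \code{DecayModel} with elements \code{expected}
#'   (vector indexed by distance 0..maxD), \code{trans} and \code{floor}
#' @export
fitDecay <- function(x) {
  tab <- x@chroms
  if (contactSum(x) == 0) stop("empty matrix: cannot fit decay")
  ent <- contactEntries(x)
  chromOf <- function(bin) findInterval(bin, tab$offset)
  ci <- chromOf(ent$i); cj <- chromOf(ent$j)
  cis <- ci == cj
  maxD <- max(tab$nbins) - 1L
  sums <- rep(0, maxD + 1L)
  if (any(cis)) {
    d <- ent$j[cis] - ent$i[cis]
    agg <- tapply(ent$count[cis], d, sum)
    sums[as.integer(names(agg)) + 1L] <- agg
  }
  npairs <- rep(0, maxD + 1L)
  for (nb in tab$nbins) {
    d <- 0:(nb - 1L)
    npairs[d + 1L] <- npairs[d + 1L] + (nb - d)
  }
  y <- ifelse(npairs > 0, sums / npairs, 0)
  # isotonic (nonincreasing) smoothing
  fit <- -stats::isoreg(seq_along(y), -y)$yf
  nTot <- sum(tab$nbins)
  nCisPairs <- sum(tab$nbins * (tab$nbins + 1) / 2)
  nTransPairs <- nTot * (nTot + 1) / 2 - nCisPairs
  transSum <- sum(ent$count[!cis])
  trans <- if (nTransPairs > 0) transSum / nTransPairs else 0
  floorVal <- max(min(fit[fit > 0], Inf) * 1e-3, 1e-12)
  structure(list(expected = pmax(fit, floorVal), trans = trans,
                 floor = floorVal),
            class = "DecayModel")
}

#' Expected contact count at bin distances under a decay model
#' @param decay \code{DecayModel}
#' @param d integer bin distances
#' @export
decayExpected <- function(decay, d) {
  e <- decay$expected
  idx <- pmin(d + 1L, length(e))
  e[idx]
}

#' Ectopic-signal score of a grid tile
#'
#' Scores a tile (a pair of bin ranges) by the mean observed/expected ratio
#' under a fitted decay model; the expectation is distance-dependent for cis
#' tiles and the trans constant for trans tiles. The tile is flagged ectopic
#' when the score reaches \code{threshold} and at least \code{minBins} cells
#' are nonzero. Used to decide whether two fragments are adjacent on the
#' same derivative chromosome.
#'
#' @param x \code{ContactMatrix}
#' @param decay \code{DecayModel} fitted on \code{x}
#' @param rowBins,colBins global 0-based bin ranges \code{c(start, end)},
#'   end exclusive
#' @param threshold observed/expected flag threshold
#' @param minBins minimum number of nonzero cells
#' @return \code{list(score =, flag =, nNonzero =)}
#' @export
ectopicScore <- function(x, decay, rowBins, colBins,
                         threshold = 3.0, minBins = 4L) {
  if (rowBins[2] <= rowBins[1] || colBins[2] <= colBins[1])
    return(list(score = 0, flag = FALSE, nNonzero = 0L))
  tile <- extractTile(x, rowBins, colBins)
  tab <- x@chroms
  chromOf <- function(bin) findInterval(bin, tab$offset)
  cisTile <- chromOf(rowBins[1]) == chromOf(colBins[1])
  if (cisTile) {
    dm <- abs(outer((rowBins[1] + 1L):rowBins[2],
                    (colBins[1] + 1L):colBins[2], "-"))
    expd <- matrix(decayExpected(decay, as.integer(dm)), nrow = nrow(dm))
  } else {
    expd <- matrix(max(decay$trans, decay$floor),
                   nrow = nrow(tile), ncol = ncol(tile))
  }
  score <- mean(tile / expd)
  list(score = score,
       flag = score >= threshold && sum(tile > 0) >= minBins,
       nNonzero = sum(tile > 0))
}

#' Breakpoint grid over a contact map
#'
#' Spans a 2D grid across the Hi-C map with grid lines at the breakpoint
#' coordinates (rounded up to bin starts), partitioning every chromosome
#' into consecutive bin ranges. All cells of the resulting 2D partition can
#' then be screened for ectopic signal.
#'
#' @param x \code{ContactMatrix}
#' @param breakpoints data.frame with \code{chrom} and \code{pos} (0-based)
#' @return data.frame of grid fragments: \code{chrom}, \code{startBp},
#'   \code{endBp}, \code{startBin}, \code{endBin} (global, end exclusive)
#' @export
gridPartition <- function(x, breakpoints) {
  tab <- x@chroms
  out <- list()
  for (k in seq_len(nrow(tab))) {
    nm <- tab$name[k]
    bp <- sort(unique(breakpoints$pos[breakpoints$chrom == nm]))
    lines <- unique(pmin(pmax(ceiling(bp / x@binSize), 0L), tab$nbins[k]))
    lines <- lines[lines > 0 & lines < tab$nbins[k]]
    bounds <- c(0L, lines, tab$nbins[k])
    for (f in seq_len(length(bounds) - 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = nm,
        startBp = bounds[f] * x@binSize,
        endBp = min(bounds[f + 1L] * x@binSize, tab$length[k]),
        startBin = as.integer(tab$offset[k] + bounds[f]),
        endBin = as.integer(tab$offset[k] + bounds[f + 1L]))
    }
  }
  grid <- do.call(rbind, out)
  grid$fragment <- seq_len(nrow(grid))
  grid
}

#' Subtract a scaled control map
#'
#' The control is scaled to carry 50% of the overall sample signal (the
#' wild-type allele is expected to contribute roughly half of the Hi-C
#' signal), with the main diagonal -- or the main and first subdiagonal --
#' excluded from the scaling-factor computation. Negative values after
#' subtraction are clipped to zero.
#'
#' @param sample,control \code{ContactMatrix} objects on the same bin table
#' @param exclude diagonals excluded from the scaling sums
#' @param weight fraction of the sample signal the control is scaled to
#' @return \code{ContactMatrix} of \code{max(sample - f * control, 0)}
#' @export
subtractControl <- function(sample, control,
                            exclude = c("main_diag", "main_and_first"),
                            weight = 0.5) {
  exclude <- match.arg(exclude)
  if (!identical(sample@chroms$nbins, control@chroms$nbins))
    stop("sample and control must share the bin table")
  k0 <- if (exclude == "main_diag") 1L else 2L
  offSum <- function(m) sum(Matrix::triu(m, k = k0)@x)
  sS <- offSum(sample@mat)
  sC <- offSum(control@mat)
  if (sC == 0) stop("control has no off-diagonal signal")
  f <- weight * sS / sC
  diff <- sample@mat - f * control@mat
  diff@x <- pmax(diff@x, 0)
  out <- sample
  out@mat <- methods::as(Matrix::drop0(diff), "CsparseMatrix")
  out
}
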