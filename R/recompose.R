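#' Bin ranges of layout fragments in the recomposed map
#'
#' Computes, for each bin-aligned fragment of a layout, its bin range in the
#' recomposed coordinate system (prefix sums of retained fragment bin
#' counts). Sub-bin fragments are excluded.
#'
#' @param x source \code{ContactMatrix}
#' @param layout a layout list
#' @return data.frame: \code{fragment}, \code{orientation}, \code{startBin},
#'   \code{endBin} (0-based, end exclusive, local to the derivative),
#'   \code{refStartBin}, \code{refEndBin} (global bins in the source)
#' @export
layoutBinRanges <- function(x, layout) {
  f <- layout$fragments
  rows <- list()
  cursor <- 0L
  for (i in seq_len(nrow(f))) {
    fb <- fragmentBins(x, f$chrom[i], f$start[i], f$end[i])
    if (fb$subBin) next
    nb <- fb$endBin - fb$startBin
    rows[[length(rows) + 1L]] <- data.frame(
      fragment = f$fragment[i], orientation = f$orientation[i],
      startBin = cursor, endBin = cursor + nb,
      refStartBin = fb$startBin, refEndBin = fb$endBin)
    cursor <- cursor + nb
  }
  if (!length(rows))
    return(data.frame(fragment = character(), orientation = character(),
                      startBin = integer(), endBin = integer(),
                      refStartBin = integer(), refEndBin = integer()))
  do.call(rbind, rows)
}

#' Recompose a Hi-C map along derivative layouts
#'
#' Cuts the contact map at all fragment boundaries and reorders/reorients
#' rows and columns according to the reconstruction: block (p, q) of the
#' output equals the source block of fragments p and q with axis reversals
#' matching inverted fragments. Fragment starts are rounded up and ends
#' rounded down to whole bins; fragments smaller than one bin are dropped
#' with a warning. Total signal is conserved over the retained bins.
#'
#' @param x source \code{ContactMatrix}
#' @param layouts list of layouts (see \code{\link{traverseGraph}}); each
#'   needs a \code{name}
#' @return \code{ContactMatrix} whose chromosomes are the derivative
#'   chromosomes
#' @export
recompose <- function(x, layouts) {
  n <- sum(x@chroms$nbins)
  map <- rep(NA_integer_, n)
  outChroms <- list()
  cursor <- 0L
  droppedAny <- FALSE
  for (ly in layouts) {
    br <- layoutBinRanges(x, ly)
    if (nrow(br) < nrow(ly$fragments)) droppedAny <- TRUE
    for (i in seq_len(nrow(br))) {
      ref <- (br$refStartBin[i] + 1L):br$refEndBin[i]   # 1-based source
      if (any(!is.na(map[ref])))
        stop("overlapping fragments across layouts: copy gains unsupported")
      out <- br$startBin[i]:(br$endBin[i] - 1L) + cursor  # 0-based output
      if (br$orientation[i] == "inverted") out <- rev(out)
      map[ref] <- out
    }
    nb <- if (nrow(br)) max(br$endBin) else 0L
    outChroms[[length(outChroms) + 1L]] <- data.frame(
      name = ly$name, length = nb * x@binSize)
    cursor <- cursor + nb
  }
  if (droppedAny)
    warning("sub-bin fragments dropped from the recomposition")
  outTab <- do.call(rbind, outChroms)
  outTab <- outTab[outTab$length > 0, , drop = FALSE]
  ent <- contactEntries(x)
  mi <- map[ent$i + 1L]; mj <- map[ent$j + 1L]
  keep <- !is.na(mi) & !is.na(mj)
  ii <- pmin(mi[keep], mj[keep]); jj <- pmax(mi[keep], mj[keep])
  ContactMatrix(outTab, x@binSize,
                entries = data.frame(i = ii, j = jj,
                                     count = ent$count[keep]))
}

#' Inverse layouts of a recomposition
#'
#' For a set of bin-aligned, loss-free layouts over the source genome,
#' returns layouts expressed in derivative coordinates whose recomposition
#' maps the derivative matrix back onto the source chromosomes
#' (\code{recompose(recompose(x, L), invertLayouts(x, L))} recovers
#' \code{x} restricted to retained bins).
#'
#' @param x source \code{ContactMatrix}
#' @param layouts the layouts used for the forward recomposition
#' @return list of inverse layouts, one per source chromosome touched
#' @export
invertLayouts <- function(x, layouts) {
  pieces <- list()
  for (ly in layouts) {
    br <- layoutBinRanges(x, ly)
    for (i in seq_len(nrow(br))) {
      ref <- br[i, ]
      chromIdx <- findInterval(ref$refStartBin, x@chroms$offset)
      pieces[[length(pieces) + 1L]] <- data.frame(
        srcChrom = x@chroms$name[chromIdx],
        srcStartBin = ref$refStartBin - x@chroms$offset[chromIdx],
        fragment = ref$fragment,
        chrom = ly$name,
        start = ref$startBin * x@binSize,
        end = ref$endBin * x@binSize,
        orientation = ref$orientation)
    }
  }
  df <- do.call(rbind, pieces)
  chromOrder <- intersect(x@chroms$name, unique(df$srcChrom))
  lapply(stats::setNames(chromOrder, chromOrder), function(nm) {
    d <- df[df$srcChrom == nm, , drop = FALSE]
    d <- d[order(d$srcStartBin), , drop = FALSE]
    list(name = d$srcChrom[1],
         fragments = data.frame(fragment = d$fragment, chrom = d$chrom,
                                start = d$start, end = d$end,
                                orientation = d$orientation),
         completeness = "complete")
  })
}
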