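#' Construct a genome model
#'
#' @param chroms data.frame with columns \code{name} and \code{length}, or a
#'   named numeric vector of chromosome lengths.
#' @param gaps,segdups data.frame with columns \code{chrom}, \code{start},
#'   \code{end} in 0-based half-open coordinates (BED convention), or a
#'   \code{GRanges}. \code{NULL} means none.
#' @return A \linkS4class{GenomeModel}.
#' @export
GenomeModel <- function(chroms, gaps = NULL, segdups = NULL) {
  if (is.numeric(chroms) && !is.null(names(chroms)))
    chroms <- data.frame(name = names(chroms), length = as.numeric(chroms))
  chroms <- data.frame(name = as.character(chroms$name),
                       length = as.numeric(chroms$length))
  new("GenomeModel", chroms = chroms,
      gaps = .asIntervalGRanges(gaps),
      segdups = .asIntervalGRanges(segdups))
}

.asIntervalGRanges <- function(x) {
  if (is.null(x)) return(GenomicRanges::GRanges())
  if (methods::is(x, "GRanges")) return(x)
  if (nrow(x) == 0L) return(GenomicRanges::GRanges())
  # BED 0-based half-open -> 1-based closed
  GenomicRanges::GRanges(as.character(x$chrom),
                         IRanges::IRanges(x$start + 1L, x$end))
}

#' @rdname GenomeModel
#' @param genome a \code{GenomeModel}
#' @export
chromLengths <- function(genome) {
  stats::setNames(genome@chroms$length, genome@chroms$name)
}

#' @rdname GenomeModel
#' @export
chromNames <- function(genome) genome@chroms$name

#' Read a two-column chromosome table (name, length)
#'
#' @param path TSV with columns \code{name} and \code{length} (header
#'   optional; detected).
#' @param gaps,segdups optional BED paths passed to \code{\link{readBed}}.
#' @return \linkS4class{GenomeModel}
#' @export
readGenomeTsv <- function(path, gaps = NULL, segdups = NULL) {
  first <- readLines(path, n = 1L)
  header <- grepl("name", first, fixed = TRUE)
  tab <- utils::read.table(path, header = header, sep = "\t",
                           col.names = if (!header) c("name", "length"),
                           stringsAsFactors = FALSE)
  GenomeModel(tab,
              gaps = if (!is.null(gaps)) readBed(gaps),
              segdups = if (!is.null(segdups)) readBed(segdups))
}

#' Read a BED file of intervals
#'
#' Minimal three-plus-column BED reader; coordinates stay in the returned
#' data.frame as 0-based half-open. Extra columns are kept by position
#' (\code{name}, \code{score}).
#'
#' @param path BED file path
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   and any extras present.
#' @export
readBed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           comment.char = "#")
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4L) names(tab)[4] <- "name"
  if (ncol(tab) >= 5L) names(tab)[5] <- "score"
  tab
}

# distance (bases strictly between) from 0-based positions to nearest
# interval of a GRanges on the same chromosome; 0 when inside, Inf when the
# chromosome carries no interval.
.distanceToIntervals <- function(chrom, pos, gr) {
  if (length(gr) == 0L) return(rep(Inf, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  d <- rep(Inf, length(pos))
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(q, gr))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

# TRUE where 0-based position lies inside an interval
.insideIntervals <- function(chrom, pos, gr) {
  if (length(gr) == 0L) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  suppressWarnings(IRanges::overlapsAny(q, gr))
}
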