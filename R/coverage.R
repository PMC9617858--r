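#' Construct a coverage track
#'
#' @param windows data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and \code{coverage}, or a \code{GRanges} with a
#'   \code{coverage} column.
#' @param windowSize window width in bp (default 10 kb).
#' @param genomeMean genome-wide mean alignment coverage; defaults to the
#'   mean over windows.
#' @return \linkS4class{CoverageTrack}
#' @export
CoverageTrack <- function(windows, windowSize = 10000, genomeMean = NULL) {
  if (!methods::is(windows, "GRanges")) {
    gr <- GenomicRanges::GRanges(windows$chrom,
                                 IRanges::IRanges(windows$start + 1L,
                                                  windows$end))
    S4Vectors::mcols(gr)$coverage <- windows$coverage
    windows <- gr
  }
  if (is.null(genomeMean))
    genomeMean <- mean(S4Vectors::mcols(windows)$coverage)
  new("CoverageTrack", windowSize = windowSize, windows = windows,
      genomeMean = genomeMean)
}

#' Read a coverage BED (chrom, start, end, coverage)
#' @param path BED path; fourth column is mean coverage per window
#' @param windowSize window width in bp
#' @return \linkS4class{CoverageTrack}
#' @export
readCoverageBed <- function(path, windowSize = 10000) {
  tab <- readBed(path)
  names(tab)[4] <- "coverage"
  CoverageTrack(tab, windowSize = windowSize)
}

#' @rdname CoverageTrack
#' @param track a \code{CoverageTrack}
#' @export
genomeMeanCoverage <- function(track) track@genomeMean

#' Window coverage at 0-based positions
#'
#' @param track \linkS4class{CoverageTrack}
#' @param chrom,pos vectors of chromosome names and 0-based positions
#' @return numeric coverage per position
#' @export
coverageAt <- function(track, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, track@windows))
  out <- rep(NA_real_, length(pos))
  out[S4Vectors::queryHits(hits)] <-
    S4Vectors::mcols(track@windows)$coverage[S4Vectors::subjectHits(hits)]
  if (anyNA(out))
    stop("breakend position outside all coverage windows: ",
         paste(paste0(chrom, ":", pos)[is.na(out)], collapse = ", "))
  out
}
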