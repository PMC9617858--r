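#' Read SAM records
#'
#' Thin wrappers over Rsamtools (the SAM is converted to a temporary BAM
#' and scanned). \code{readSamReads} returns per-read fields needed by the
#' junction-signature analysis; \code{readSamAlignments} returns the
#' contiguous aligned reference span of every record, as needed for
#' junction-spanning read counting.
#'
#' @param path SAM file
#' @return data.frame; coordinates 0-based (\code{pos} = aligned start,
#'   \code{end} exclusive)
#' @export
readSamReads <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(r$pos)
  data.frame(id = r$qname[keep],
             flag = r$flag[keep],
             chrom = as.character(r$rname[keep]),
             pos = r$pos[keep] - 1L,
             mapq = r$mapq[keep],
             cigar = r$cigar[keep],
             seq = as.character(r$seq[keep]),
             stringsAsFactors = FALSE)
}

#' @rdname readSamReads
#' @export
readSamAlignments <- function(path) {
  reads <- readSamReads(path)
  if (nrow(reads) == 0L)
    return(data.frame(id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      mapq = numeric(), flag = integer()))
  refLen <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  data.frame(id = reads$id, chrom = reads$chrom,
             start = reads$pos, end = reads$pos + refLen,
             mapq = reads$mapq, flag = reads$flag)
}

#' Write reads as a minimal SAM file
#'
#' @param reads data.frame with \code{id}, \code{chrom}, \code{pos}
#'   (0-based), \code{mapq}, \code{cigar}, \code{seq} and optional
#'   \code{flag}
#' @param chromLengths named vector of reference lengths for the header
#' @param path output file
#' @export
writeSam <- function(reads, chromLengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths),
                   as.integer(chromLengths)))
  flag <- if (is.null(reads$flag)) rep(0L, nrow(reads)) else reads$flag
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                 reads$id, flag, reads$chrom, as.integer(reads$pos) + 1L,
                 as.integer(reads$mapq), reads$cigar, reads$seq)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
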