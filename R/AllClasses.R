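#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width distance findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

#' Reference genome model
#'
#' Holds the coordinate universe used throughout the package: ordered
#' chromosome names and lengths plus two interval sets that drive call
#' filtering, assembly gaps and segmental duplications. All user-facing
#' coordinates are 0-based half-open; interval sets are stored internally as
#' 1-based closed \link[GenomicRanges]{GRanges} (converted at the readers).
#'
#' @slot chroms data.frame with columns \code{name} and \code{length} (bp).
#' @slot gaps \code{GRanges} of assembly gaps.
#' @slot segdups \code{GRanges} of segmental duplications.
#' @export
setClass("GenomeModel",
  representation(
    chroms = "data.frame",
    gaps = "GRanges",
    segdups = "GRanges"
  )
)

setValidity("GenomeModel", function(object) {
  ch <- object@chroms
  if (!all(c("name", "length") %in% names(ch)))
    return("chroms must have columns 'name' and 'length'")
  if (anyDuplicated(ch$name)) return("duplicated chromosome names")
  if (any(ch$length <= 0)) return("chromosome lengths must be > 0")
  for (gr in list(object@gaps, object@segdups)) {
    if (length(gr) == 0L) next
    nm <- as.character(GenomicRanges::seqnames(gr))
    if (!all(nm %in% ch$name)) return("interval on unknown chromosome")
    len <- ch$length[match(nm, ch$name)]
    if (any(GenomicRanges::start(gr) < 1) || any(GenomicRanges::end(gr) > len))
      return("interval outside chromosome bounds")
  }
  TRUE
})

#' Per-window alignment coverage track
#'
#' Mean alignment coverage in non-overlapping genomic windows (default 10 kb)
#' plus the genome-wide mean, as used by the support and high-coverage call
#' filters.
#'
#' @slot windowSize window width in bp.
#' @slot windows \code{GRanges} with a \code{coverage} metadata column.
#' @slot genomeMean genome-wide mean alignment coverage.
#' @export
setClass("CoverageTrack",
  representation(
    windowSize = "numeric",
    windows = "GRanges",
    genomeMean = "numeric"
  )
)

setValidity("CoverageTrack", function(object) {
  if (length(object@windowSize) != 1L || object@windowSize <= 0)
    return("windowSize must be a single positive number")
  if (is.null(S4Vectors::mcols(object@windows)$coverage))
    return("windows must carry a 'coverage' metadata column")
  if (any(S4Vectors::mcols(object@windows)$coverage < 0))
    return("coverage must be >= 0")
  TRUE
})

#' Binned symmetric Hi-C contact matrix
#'
#' Sparse upper-triangle storage of a genome-wide raw-count contact map at a
#' fixed bin size. Chromosomes are laid out consecutively; \code{chroms}
#' records per-chromosome bin offsets. Queries are symmetric: entry (j, i)
#' returns entry (i, j).
#'
#' @slot binSize bin width in bp.
#' @slot chroms data.frame with columns \code{name}, \code{length},
#'   \code{nbins}, \code{offset} (0-based global bin offset).
#' @slot mat upper-triangular \code{dgCMatrix} of counts.
#' @export
setClass("ContactMatrix",
  representation(
    binSize = "numeric",
    chroms = "data.frame",
    mat = "Matrix"
  )
)

setValidity("ContactMatrix", function(object) {
  ch <- object@chroms
  need <- c("name", "length", "nbins", "offset")
  if (!all(need %in% names(ch)))
    return("chroms must have columns name, length, nbins, offset")
  n <- sum(ch$nbins)
  if (!all(dim(object@mat) == c(n, n)))
    return("matrix dimension does not match total bin count")
  tri <- Matrix::tril(object@mat, k = -1L)
  if (length(tri@x) && any(tri@x != 0))
    return("entries must lie in the upper triangle (i <= j)")
  if (any(object@mat@x < 0)) return("counts must be >= 0")
  TRUE
})

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel:", nrow(object@chroms), "chromosomes,",
      format(sum(object@chroms$length), big.mark = ","), "bp;",
      length(object@gaps), "gaps,", length(object@segdups), "segdups\n")
})

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack:", length(object@windows), "windows of",
      object@windowSize, "bp; genome mean", round(object@genomeMean, 2), "\n")
})

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix:", nrow(object@chroms), "chromosomes,",
      sum(object@chroms$nbins), "bins of", object@binSize, "bp;",
      "total signal", format(contactSum(object)), "\n")
})
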