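#' Novel-adjacency tables
#'
#' A novel adjacency is a pair of oriented breakends created by a
#' rearrangement. The package represents a call set as a data.frame with the
#' columns below; all constructors canonicalize breakend order so that
#' \code{bnd1 <= bnd2} under (chromosome order, position).
#'
#' \describe{
#'   \item{id}{call identifier}
#'   \item{chrom1, pos1, side1}{first breakend; \code{pos} 0-based;
#'     \code{side} is \code{"tail"} (the reference segment ending at
#'     \code{pos} is fused) or \code{"head"} (the segment starting at
#'     \code{pos} is fused)}
#'   \item{chrom2, pos2, side2}{second breakend}
#'   \item{caller}{\code{"longread"} or \code{"shortread"}}
#'   \item{support}{read support (NA allowed for short-read calls)}
#'   \item{precise}{logical precision flag (short-read calls)}
#'   \item{span}{\code{abs(pos1 - pos2)} in cis, \code{Inf} in trans}
#'   \item{curated}{logical curation flag}
#' }
#'
#' @param df data.frame with at least \code{chrom1, pos1, side1, chrom2,
#'   pos2, side2}; missing optional columns are filled with defaults.
#' @param genome \linkS4class{GenomeModel} providing the chromosome order
#'   used for canonicalization; validated against when supplied.
#' @return canonicalized adjacency data.frame
#' @export
newAdjacencies <- function(df, genome = NULL) {
  n <- nrow(df)
  if (is.null(df$id)) df$id <- sprintf("adj%04d", seq_len(n))
  if (is.null(df$caller)) df$caller <- rep("longread", n)
  if (is.null(df$support)) df$support <- rep(NA_real_, n)
  if (is.null(df$precise)) df$precise <- rep(NA, n)
  if (is.null(df$curated)) df$curated <- rep(FALSE, n)
  if (!is.null(genome)) {
    for (k in 1:2) {
      ch <- df[[paste0("chrom", k)]]
      bad <- !(ch %in% chromNames(genome))
      if (any(bad))
        stop("breakend chromosome not in genome: ",
             paste(unique(ch[bad]), collapse = ", "))
      len <- chromLengths(genome)[ch]
      p <- df[[paste0("pos", k)]]
      if (any(p < 0 | p >= len))
        stop("breakend position outside chromosome bounds")
    }
  }
  if (!all(unlist(df[c("side1", "side2")]) %in% c("tail", "head")))
    stop("breakend side must be 'tail' or 'head'")
  canonicalizeAdjacencies(df, genome)
}

#' @rdname newAdjacencies
#' @export
canonicalizeAdjacencies <- function(df, genome = NULL) {
  if (nrow(df) == 0L) return(.withSpan(df))
  ord <- if (is.null(genome)) sort(unique(c(df$chrom1, df$chrom2)))
         else chromNames(genome)
  r1 <- match(df$chrom1, ord)
  r2 <- match(df$chrom2, ord)
  swap <- r2 < r1 | (r1 == r2 & df$pos2 < df$pos1)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "pos1", "side1")]
    df[swap, c("chrom1", "pos1", "side1")] <-
      df[swap, c("chrom2", "pos2", "side2")]
    df[swap, c("chrom2", "pos2", "side2")] <- tmp
  }
  .withSpan(df)
}

.withSpan <- function(df) {
  df$span <- ifelse(df$chrom1 == df$chrom2, abs(df$pos2 - df$pos1), Inf)
  rownames(df) <- NULL
  df
}

#' Read novel adjacencies from a BEDPE file
#'
#' Expects 10+ columns: chrom1 start1 end1 chrom2 start2 end2 name score
#' strand1 strand2, optionally followed by \code{key=value} annotation
#' columns (\code{caller}, \code{support}, \code{precise}). The breakend
#' position is the BEDPE start; strand \code{"+"} maps to side \code{"tail"}
#' and \code{"-"} to \code{"head"}.
#'
#' @param path BEDPE file
#' @param genome \linkS4class{GenomeModel} used for validation and breakend
#'   canonicalization
#' @param caller default caller label when no \code{caller=} column present
#' @return canonicalized adjacency data.frame (see \code{\link{newAdjacencies}})
#' @export
readBedpe <- function(path, genome, caller = "longread") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(newAdjacencies(data.frame(chrom1 = character(), pos1 = numeric(),
                                     side1 = character(), chrom2 = character(),
                                     pos2 = numeric(), side2 = character())))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1L) f <- strsplit(lines[[i]], " +")[[1]]
    if (length(f) < 10L)
      stop("malformed BEDPE line ", i, ": expected >= 10 fields, got ",
           length(f))
    pos <- suppressWarnings(as.numeric(f[c(2, 5)]))
    if (anyNA(pos)) stop("malformed BEDPE line ", i, ": non-numeric start")
    if (!all(f[c(9, 10)] %in% c("+", "-")))
      stop("malformed BEDPE line ", i, ": bad strand")
    extra <- f[-(1:10)]
    kv <- extra[grepl("=", extra, fixed = TRUE)]
    ann <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
    data.frame(chrom1 = f[1], pos1 = pos[1],
               side1 = ifelse(f[9] == "+", "tail", "head"),
               chrom2 = f[4], pos2 = pos[2],
               side2 = ifelse(f[10] == "+", "tail", "head"),
               id = f[7],
               caller = if ("caller" %in% names(ann)) ann[["caller"]] else caller,
               support = if ("support" %in% names(ann))
                 as.numeric(ann[["support"]]) else NA_real_,
               precise = if ("precise" %in% names(ann))
                 tolower(ann[["precise"]]) %in% c("true", "1", "yes") else NA,
               stringsAsFactors = FALSE)
  })
  newAdjacencies(do.call(rbind, rows), genome)
}

#' Write novel adjacencies as BEDPE
#'
#' Inverse of \code{\link{readBedpe}}: sides map back to strands
#' (tail = \code{"+"}, head = \code{"-"}) and caller/support/precise are
#' emitted as \code{key=value} columns.
#'
#' @param calls adjacency data.frame
#' @param path output file
#' @export
writeBedpe <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(calls) == 0L) return(invisible(path))
  s2c <- function(s) ifelse(s == "tail", "+", "-")
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t.\t%s\t%s\tcaller=%s\tsupport=%s\tprecise=%s",
    calls$chrom1, as.integer(calls$pos1), as.integer(calls$pos1) + 1L,
    calls$chrom2, as.integer(calls$pos2), as.integer(calls$pos2) + 1L,
    calls$id, s2c(calls$side1), s2c(calls$side2), calls$caller,
    ifelse(is.na(calls$support), ".", format(calls$support, trim = TRUE)),
    ifelse(is.na(calls$precise), ".", tolower(as.character(calls$precise))))
  writeLines(lines, con)
  invisible(path)
}
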